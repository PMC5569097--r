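test_that("gradient field is linear in r2, constant in r1, and on (0, 1]", {
  dims <- lattice_dims(10, 100)
  expect_equal(gradient_value(3, 100, dims), 1.0)
  expect_equal(gradient_value(7, 1, dims), 0.01)
  g <- gradient_field(dims)
  expect_equal(dim(g), c(10L, 100L))
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1L)))
  expect_true(all(diff(g[1, ]) > 0))
  expect_error(gradient_value(0, 5, dims), "out of range")
  expect_error(gradient_value(1, 101, dims), "out of range")
})

test_that("homogeneous fields are constant and range-checked", {
  dims <- lattice_dims(10, 10)
  for (lev in c(0.5, 0.1, 0)) {
    f <- make_homogeneous_ecm(dims, lev)
    expect_true(all(f$values == lev))
    expect_equal(dim(f$values), c(10L, 10L))
  }
  expect_error(make_homogeneous_ecm(dims, 1.2), "\\[0, 1\\]")
  expect_error(make_homogeneous_ecm(dims, -0.1), "\\[0, 1\\]")
})

test_that("heterogeneous field degenerates correctly at theta = 1 and 0", {
  dims <- lattice_dims(30, 40)
  # theta = 1: the noise term vanishes and the field is the pure sinusoid
  f1 <- make_heterogeneous_ecm(dims, theta = 1, seed = 7)
  r1 <- seq_len(30); r2 <- seq_len(40)
  sinusoid <- outer(sin(2 * pi * r1 / 25 + 3 * pi / 2),
                    sin(pi * r2 / 25 + pi / 2))
  expect_equal(f1$values, 0.5 + 0.5 * sinusoid)
  # theta = 0: the sinusoid amplitude is zero and the field is 1 - xi
  f0 <- make_heterogeneous_ecm(dims, theta = 0, seed = 7)
  set.seed(7)
  xi <- matrix(runif(30 * 40), 30, 40)
  expect_equal(f0$values, 1 - xi)
  expect_gt(length(unique(as.vector(f0$values))), 1000)  # speckled, not flat
  expect_error(make_heterogeneous_ecm(dims, theta = 1.5), "\\[0, 1\\]")
})

test_that("heterogeneous field values stay in [0, 1] across theta and seeds", {
  dims <- lattice_dims(8, 8)
  set.seed(42)
  thetas <- runif(10000)
  seeds <- sample.int(1e6, 10000)
  ok <- vapply(seq_along(thetas), function(i) {
    v <- make_heterogeneous_ecm(dims, thetas[i], seed = seeds[i])$values
    all(v >= 0) && all(v <= 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("spatial mean of the heterogeneous field is 0.5 for every theta", {
  dims <- lattice_dims(100, 300)
  for (theta in c(0, 0.25, 0.5, 0.75, 1)) {
    f <- make_heterogeneous_ecm(dims, theta, seed = 11)
    expect_lt(abs(mean(f$values) - 0.5), 0.02)
  }
})

test_that("same seed and descriptor regenerate a bit-identical field", {
  dims <- lattice_dims(20, 20)
  a <- make_heterogeneous_ecm(dims, 0.3, seed = 99)
  b <- make_heterogeneous_ecm(dims, 0.3, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$descriptor, b$descriptor)
  # seeded generation must not disturb the caller's RNG stream
  set.seed(5); x1 <- runif(3)
  set.seed(5); invisible(make_heterogeneous_ecm(dims, 0.3, seed = 99))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("ECM fields round-trip through the CSV + JSON writer", {
  dims <- lattice_dims(12, 15)
  f <- make_heterogeneous_ecm(dims, 0.4, seed = 3)
  path <- file.path(tempdir(), "field.csv")
  write_ecm_field(f, path)
  g <- read_ecm_field(path)
  expect_equal(g$values, f$values)
  expect_equal(g$descriptor$theta, 0.4)
  expect_equal(g$descriptor$generator, "heterogeneous")
  expect_equal(g$dims$S1, 12L)
})
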