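make_state <- function(cells, dims) {
  occ <- matrix(0L, dims$S1, dims$S2)
  occ[cbind(cells$r1, cells$r2)] <- cells$id
  structure(list(ecm = matrix(0.5, dims$S1, dims$S2), occ = occ,
                 cells = cells, dims = dims, mcs_elapsed = 0L),
            class = "ca_state")
}

test_that("cell distances honor the periodic minimal image and axial metrics", {
  dims <- lattice_dims(100, 50)
  cells <- data.frame(id = 1:3, phenotype = "A",
                      r1 = c(5, 100, 13), r2 = c(1, 1, 5),
                      r1_0 = c(5, 1, 10), r2_0 = c(1, 1, 1))
  st <- make_state(cells, dims)
  d_eu <- cell_distance(st)
  d_ax <- cell_distance(st, metric = "axial_r2")
  expect_equal(d_eu[1], 0)            # stationary
  expect_equal(d_ax[1], 0)
  expect_equal(d_eu[2], 1)            # wrapped one step across the seam
  expect_equal(d_ax[2], 0)
  expect_equal(d_eu[3], 5)            # 3-4-5 triangle
  expect_equal(d_ax[3], 4)
})

test_that("population summary computes d_p, d_max and within-run sd", {
  dims <- lattice_dims(100, 50)
  cells <- data.frame(id = 1:3, phenotype = c("A", "M", "A"),
                      r1 = c(1, 2, 3), r2 = c(2, 3, 4),
                      r1_0 = c(1, 2, 3), r2_0 = c(1, 1, 1))
  st <- make_state(cells, dims)  # distances 1, 2, 3
  s <- summarize_population(st)
  expect_equal(s$d_p, 2)
  expect_equal(s$d_max, 3)
  expect_equal(s$within_sd, 1)
  expect_equal(s$frac_M, 1 / 3)
  # degenerate single cell: d_p = d_max, sd undefined
  s1 <- summarize_population(make_state(cells[2, ], dims))
  expect_equal(s1$d_p, s1$d_max)
  expect_true(is.na(s1$within_sd))
  # stationary population
  cells0 <- transform(cells, r1 = r1_0, r2 = r2_0)
  s0 <- summarize_population(make_state(cells0, dims))
  expect_equal(c(s0$d_p, s0$d_max), c(0, 0))
  st_empty <- make_state(cells[0, ], dims)
  expect_error(summarize_population(st_empty), "empty")
})

test_that("replicate statistics give mean, sd and CV across runs", {
  r <- replicate_statistics(data.frame(d_p = c(10, 10, 10)))
  expect_equal(r$cv_between, 0)
  r2 <- replicate_statistics(data.frame(d_p = c(9, 11)))
  expect_equal(r2$mean_d_p, 10)
  expect_equal(r2$sd_between, sqrt(2), tolerance = 1e-12)
  expect_equal(r2$cv_between, sqrt(2) / 10, tolerance = 1e-12)
  expect_warning(rz <- replicate_statistics(data.frame(d_p = c(0, 0))),
                 "undefined")
  expect_true(is.na(rz$cv_between))
})

test_that("best-arm comparison is signed switching minus non-switching", {
  cmp <- compare_best(c(`0.5` = 38, `1` = 40), c(`0` = 35, `1` = 33))
  expect_equal(cmp$delta_d_p, 5)
  expect_equal(cmp$best_switching_setting, "1")
  expect_equal(cmp$best_nonswitching_setting, "0")
  same <- compare_best(c(a = 12, b = 15), c(x = 15, y = 12))
  expect_equal(same$delta_d_p, 0)
  cmp2 <- compare_best(c(`1` = 30), c(`0` = 35, `1` = 34),
                       switching_d_max = 50, nonswitching_d_max = c(60, 55))
  expect_equal(cmp2$delta_d_p, -5)
  expect_equal(cmp2$delta_d_max, -10)
})

test_that("density profile integrates to n_cells / S1", {
  p <- model_params(alpha = 1, beta = 1, c_M = 0.25, n_cells = 20,
                    mcs = 30, dims = lattice_dims(40, 60))
  s <- simulate_replicate(p, ecm_heterogeneous(0.5), seed = 8,
                          keep_state = TRUE)
  prof <- density_profile(attr(s, "state"))
  expect_length(prof, 60L)
  expect_equal(sum(prof), 20 / 40)
})

test_that("an unbiased walk started mid-lattice has zero mean r2 drift", {
  dims <- lattice_dims(60, 61)
  p <- model_params(c_M = 1, kappa = 0, delta = 0, switching = FALSE,
                    gamma = 0, n_cells = 50, mcs = 30, dims = dims)
  set.seed(9)
  disp <- unlist(lapply(1:40, function(r) {
    st <- initialize_state(p, ecm_homogeneous(0.2))
    # move the seeding column to the lattice center, away from boundaries
    st$occ <- matrix(0L, dims$S1, dims$S2)
    st$cells$r2 <- st$cells$r2_0 <- rep(31L, 50)
    st$occ[cbind(st$cells$r1, st$cells$r2)] <- st$cells$id
    st <- run_mcs(st, p)
    st$cells$r2 - st$cells$r2_0
  }))
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp)), 3 * se + 1e-9)
})
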