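test_that("initialization seeds the left column with the stated phenotype mix", {
  dims <- lattice_dims(100, 50)
  set.seed(1)
  # switching: half A, half M
  p <- model_params(alpha = 1, beta = 1, c_M = 0.25, n_cells = 50, dims = dims)
  st <- initialize_state(p, ecm_homogeneous(0.5))
  expect_equal(nrow(st$cells), 50L)
  expect_true(all(st$cells$r2 == 1L))
  expect_equal(anyDuplicated(st$cells$r1), 0L)
  expect_equal(sum(st$cells$phenotype == "M"), 25L)
  # non-switching mixes: gamma in {0, 0.3, 0.7, 1} -> 0, 15, 35, 50 M-cells
  for (gs in list(c(0, 0), c(0.3, 15), c(0.7, 35), c(1, 50))) {
    pn <- model_params(gamma = gs[1], switching = FALSE, c_M = 0.25,
                       n_cells = 50, dims = dims)
    stn <- initialize_state(pn, ecm_homogeneous(0.5))
    expect_equal(sum(stn$cells$phenotype == "M"), as.integer(gs[2]))
  }
  # population larger than the seeding column is rejected
  expect_error(model_params(n_cells = 101, dims = dims), "exceeds S1")
})

test_that("exclusion holds: a fully surrounded cell never moves", {
  dims <- lattice_dims(5, 5)
  p <- model_params(c_M = 1, kappa = 0, delta = 0, switching = FALSE,
                    gamma = 1, n_cells = 5, dims = dims)
  set.seed(2)
  st <- initialize_state(p, ecm_homogeneous(0))  # mu = 0: max move rate
  # rebuild occupancy: center cell 1 at (3,3), neighbors on all four sides
  st$occ[] <- 0L
  pos <- rbind(c(3, 3), c(2, 3), c(4, 3), c(3, 2), c(3, 4))
  st$cells$r1 <- st$cells$r1_0 <- pos[, 1]
  st$cells$r2 <- st$cells$r2_0 <- pos[, 2]
  st$occ[pos] <- 1:5
  for (i in 1:200) st <- step_cell(st, 1, p)
  expect_equal(c(st$cells$r1[1], st$cells$r2[1]), c(3, 3))
  check_state <- switchmig:::check_state
  expect_true(check_state(st))
})

test_that("boundaries: r1 wraps periodically, r2 reflects by aborting", {
  dims <- lattice_dims(4, 3)
  # kappa = 0 random walk, mu = 0 so moves almost always succeed
  p <- model_params(c_M = 1, kappa = 0, delta = 0, switching = FALSE,
                    gamma = 0, n_cells = 1, mcs = 1, dims = dims)
  set.seed(3)
  st0 <- initialize_state(p, ecm_homogeneous(0))
  seen <- list(r1 = integer(), r2 = integer())
  st <- st0
  for (i in 1:2000) {
    st <- step_cell(st, 1, p)
    seen$r1 <- c(seen$r1, st$cells$r1[1])
    seen$r2 <- c(seen$r2, st$cells$r2[1])
  }
  expect_true(all(seen$r1 %in% 1:4))        # never off-lattice
  expect_true(all(seen$r2 %in% 1:3))
  expect_setequal(unique(seen$r1), 1:4)     # wrap reaches every row
  expect_setequal(unique(seen$r2), 1:3)
})

test_that("cell count is conserved and occupancy stays consistent", {
  p <- model_params(alpha = 1, beta = 1, c_M = 0.25, kappa = 1,
                    n_cells = 30, mcs = 50, dims = lattice_dims(40, 80))
  set.seed(4)
  st <- initialize_state(p, ecm_heterogeneous(0.5))
  st <- run_mcs(st, p)
  expect_equal(nrow(st$cells), 30L)
  expect_equal(sum(st$occ != 0L), 30L)
  expect_true(switchmig:::check_state(st))
  expect_equal(st$mcs_elapsed, 50L)
})

test_that("ECM is non-increasing in time and untouched by pure-A populations", {
  dims <- lattice_dims(40, 80)
  # pure A population: no degradation anywhere, field bit-identical
  pA <- model_params(gamma = 0, switching = FALSE, c_M = 0.25, kappa = 1,
                     n_cells = 20, mcs = 50, dims = dims)
  set.seed(5)
  ecm <- make_heterogeneous_ecm(dims, 0.5, seed = 10)
  stA <- run_mcs(initialize_state(pA, ecm), pA)
  expect_identical(stA$ecm, ecm$values)
  # mixed switching population: mu never increases at any site
  pS <- model_params(alpha = 1, beta = 1, c_M = 0.25, kappa = 1,
                     n_cells = 20, mcs = 25, dims = dims)
  st <- initialize_state(pS, ecm)
  for (chunk in 1:4) {
    before <- st$ecm
    st <- run_mcs(st, pS, n_mcs = 5)
    expect_true(all(st$ecm <= before + 1e-15))
  }
  # delta = 0 also leaves the field untouched even with M-cells around
  p0 <- model_params(alpha = 1, beta = 1, c_M = 0.25, delta = 0,
                     n_cells = 20, mcs = 50, dims = dims)
  st0 <- run_mcs(initialize_state(p0, ecm), p0)
  expect_identical(st0$ecm, ecm$values)
})

test_that("non-switching populations never change phenotype", {
  p <- model_params(gamma = 0.5, switching = FALSE, c_M = 0.25, kappa = 1,
                    n_cells = 20, mcs = 100, dims = lattice_dims(40, 200))
  set.seed(6)
  st0 <- initialize_state(p, ecm_heterogeneous(0.5))
  st <- run_mcs(st0, p)
  expect_identical(st$cells$phenotype, st0$cells$phenotype)
})

test_that("run_mcs with zero steps is the identity and runs are reproducible", {
  p <- model_params(alpha = 1, beta = 1, c_M = 0.25, n_cells = 10,
                    mcs = 20, dims = lattice_dims(20, 50))
  set.seed(7)
  st <- initialize_state(p, ecm_heterogeneous(0.5))
  expect_identical(run_mcs(st, p, n_mcs = 0), st)
  a <- simulate_replicate(p, ecm_heterogeneous(0.5), seed = 123)
  b <- simulate_replicate(p, ecm_heterogeneous(0.5), seed = 123)
  expect_identical(a, b)
})

test_that("single-cell dynamics match exact Markov-chain enumeration", {
  # non-switching A-cell on a 1 x 3 strip, kappa = 0, 2 MCS (= 2 updates)
  n_rep <- 50000
  for (kappa in c(0, 1)) {
    T <- oracle_position_chain(3, kappa, mu = 0.5, c_X = 1)
    start <- c(1, 0, 0)
    exact <- as.numeric(start %*% T %*% T)
    emp <- empirical_joint(3, kappa, mu = 0.5, c_A = 1, c_M = 0.25,
                           alpha = 0, beta = 0, switching = FALSE,
                           n_updates = 2, n_rep = n_rep,
                           seed = 100 + kappa)[1:3]
    expect_matches_chain(emp, exact, n_rep)
  }
})

test_that("joint position-phenotype chain matches exact enumeration", {
  # switching cell on a 1 x 6 strip (12 joint states), delta = 0
  S2 <- 6; n_rep <- 50000
  for (kappa in c(0, 1)) {
    T <- oracle_joint_chain(S2, kappa, mu = 0.5, c_A = 1, c_M = 0.25,
                            alpha = 0.7, beta = 0.6)
    start <- numeric(2 * S2); start[1] <- 1  # A-cell at column 1
    exact <- start
    for (k in 1:5) exact <- as.numeric(exact %*% T)
    emp <- empirical_joint(S2, kappa, mu = 0.5, c_A = 1, c_M = 0.25,
                           alpha = 0.7, beta = 0.6, switching = TRUE,
                           n_updates = 5, n_rep = n_rep, seed = 200 + kappa)
    expect_matches_chain(emp, exact, n_rep)
  }
})
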