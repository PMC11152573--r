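test_that("equilibrium_split converts concentration ratios to amount fractions", {
  expect_equal(equilibrium_split(1, 0.5), 0.5)
  expect_equal(equilibrium_split(0, 0.5), 0)
  expect_equal(equilibrium_split(3, 0.5), 0.75)
  # monotone increasing in kp, bounded in [0, 1)
  kps <- c(0, 0.1, 0.5, 1, 2, 10, 100)
  f <- equilibrium_split(kps, 0.3)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  expect_error(equilibrium_split(-1, 0.5), "finite")
  expect_error(equilibrium_split(Inf, 0.5), "finite")
  expect_error(equilibrium_split(1, 0), "inside")
  expect_error(equilibrium_split(1, 1), "inside")
})

test_that("rate matrix conserves mass and has non-negative off-diagonals", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    ct <- random_construct()
    M <- build_rate_matrix(p, ct)
    expect_true(all(abs(colSums(M)) < 1e-12 * max(abs(M))))
    off <- M; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("intra-ER exchange equilibrates to the partition-set amount ratio", {
  # transport rates made negligible so the exchange pair dominates
  p <- model_params(k_a = 1e-9, k_b = 1e-9,
                    kp_erex = c(full_length = 4, tmd_only = 0.2))
  ct <- construct_spec("probe", kp_raft = 1, erex_class = "full_length")
  M <- build_rate_matrix(p, ct)
  traj <- solve_trajectory(M, c(1, 0, 0, 0, 0), c(0, 1))
  ratio <- unname(traj$states[2, "er_exit"] / traj$states[2, "er_bulk"])
  expect_equal(ratio, 4, tolerance = 1e-6)
})

test_that("a raft-excluded construct generates no Golgi efflux", {
  p <- model_params(k_a = 1, k_b = 2)
  ct <- construct_spec("excluded", kp_raft = 0, erex_class = "full_length")
  x0 <- initial_state("Golgi", p, ct)
  expect_equal(unname(x0), c(0, 0, 1, 0, 0))
  traj <- solve_trajectory(build_rate_matrix(p, ct), x0, c(0, 1, 4))
  expect_true(all(traj$states[, "post_golgi"] < 1e-9))
  fr <- residence_fractions(traj)
  expect_equal(fr$golgi_fraction, rep(1, 3), tolerance = 1e-9)
})

test_that("construct with an unresolvable ER-exit key is a configuration error", {
  p <- model_params(k_a = 1, k_b = 1)
  ct <- construct_spec("x", kp_raft = 1, erex_class = "full_length",
                       erex_key = "nonexistent")
  expect_error(build_rate_matrix(p, ct), "nonexistent")
})

test_that("initial_state places all mass in the hook organelle at equilibrium split", {
  p <- model_params(k_a = 1, k_b = 1, kp_erex = c(full_length = 1, tmd_only = 1))
  ct <- construct_spec("probe", kp_raft = 3, erex_class = "full_length")
  expect_equal(unname(initial_state("ER", p, ct, total = 1)),
               c(0.5, 0.5, 0, 0, 0))
  x <- initial_state("Golgi", p, ct, total = 1)
  expect_equal(unname(x[["golgi_raft"]]), 0.75)
  expect_equal(sum(x), 1)
  expect_error(initial_state("ER", p, ct, total = 0), "total")
})

test_that("trajectory solution matches an independent adaptive integrator", {
  set.seed(42)
  times <- c(0, 0.5, 1, 2)
  for (i in 1:10) {
    p <- random_params()
    ct <- random_construct()
    M <- build_rate_matrix(p, ct)
    x0 <- initial_state(sample(c("ER", "Golgi"), 1), p, ct)
    traj <- solve_trajectory(M, x0, times)
    ref <- oracle_states(M, x0, times)
    expect_lt(max(abs(traj$states - ref)), 1e-8)
    # mass conservation along the trajectory
    expect_true(all(abs(rowSums(traj$states) - sum(x0)) <= 1e-9 * sum(x0)))
  }
})

test_that("solve_trajectory returns the initial state at t = 0 and validates input", {
  p <- model_params(k_a = 1, k_b = 1)
  ct <- construct_spec("probe", 1, "full_length")
  M <- build_rate_matrix(p, ct)
  x0 <- initial_state("ER", p, ct)
  traj <- solve_trajectory(M, x0, 0)
  expect_identical(unname(traj$states[1, ]), unname(x0))
  bad <- M; bad[1, 1] <- bad[1, 1] + 1  # breaks column sums
  expect_error(solve_trajectory(bad, x0, c(0, 1)), "conserved|sum to zero")
  expect_error(solve_trajectory(M, x0, c(1, 0.5)), "sorted")
})

test_that("residence fractions sum to one and reach the absorbing state", {
  p <- model_params(k_a = 2, k_b = 2)
  ct <- construct_spec("probe", 1.8, "full_length")
  traj <- solve_trajectory(build_rate_matrix(p, ct),
                           initial_state("ER", p, ct), c(0, 1, 5, 40))
  fr <- residence_fractions(traj)
  expect_equal(fr$er_fraction[1], 1)
  sums <- fr$er_fraction + fr$golgi_fraction + fr$post_fraction
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(fr$post_fraction[4], 1, tolerance = 1e-6)
  empty <- traj; empty$states[] <- 0
  expect_error(residence_fractions(empty), "total")
})

test_that("reduced model obeys its closed-form identities", {
  p <- default_truth_params()
  ct <- default_construct_table()
  rates <- effective_rates(p, ct[["LAT"]])
  # Golgi release: half-life identity
  fr <- reduced_model_fractions(p, ct[["LAT"]], "Golgi", log(2) / rates[["beta"]])
  expect_equal(fr$golgi_fraction, 0.5, tolerance = 1e-12)
  # ER release with near-instant Golgi exit: Golgi stays empty
  fast <- model_params(k_a = p$k_a, k_b = 1e6, kp_erex = p$kp_erex)
  fr2 <- reduced_model_fractions(fast, ct[["LAT"]], "ER", c(0.5, 1, 2))
  expect_true(all(fr2$golgi_fraction < 2e-3))
})

test_that("confluent alpha == beta case is the removable-singularity limit", {
  # equal partition coefficients and equal rates force alpha == beta
  p <- model_params(k_a = 1.3, k_b = 1.3,
                    kp_erex = c(full_length = 2, tmd_only = 0.1))
  ct <- construct_spec("probe", kp_raft = 2, erex_class = "full_length")
  times <- c(0, 0.5, 1, 2, 4)
  fr <- reduced_model_fractions(p, ct, "ER", times)
  alpha <- effective_rates(p, ct)[["alpha"]]
  expect_equal(fr$golgi_fraction, alpha * times * exp(-alpha * times),
               tolerance = 1e-12)
  # continuous with a nearby non-degenerate parameter point
  p2 <- model_params(k_a = 1.3 * (1 + 1e-7), k_b = 1.3, kp_erex = p$kp_erex)
  fr2 <- reduced_model_fractions(p2, ct, "ER", times)
  expect_equal(fr$golgi_fraction, fr2$golgi_fraction, tolerance = 1e-5)
})

test_that("full ODE converges to the rapid-equilibrium closed form as exchange grows", {
  ct <- default_construct_table()
  times <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  errs <- vapply(c(1e2, 1e3, 1e4), function(ex) {
    p <- model_params(k_a = default_truth_params()$k_a,
                      k_b = default_truth_params()$k_b,
                      exchange_rate = ex)
    max(vapply(c("ER", "Golgi"), function(site) {
      full <- model_fractions(p, ct[["LAT"]], site, times, mode = "full_ode")
      red <- model_fractions(p, ct[["LAT"]], site, times, mode = "rapid_equilibrium")
      max(abs(as.matrix(full[-1]) - as.matrix(red[-1])))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("Golgi exit half-time decreases strictly with raft affinity", {
  p <- default_truth_params()
  kps <- c(0.2, 0.5, 1, 1.8, 3, 6)
  t_half <- vapply(kps, function(kp) {
    ct <- construct_spec("probe", kp_raft = kp, erex_class = "full_length")
    log(2) / effective_rates(p, ct)[["beta"]]
  }, numeric(1))
  expect_true(all(diff(t_half) < 0))
})
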