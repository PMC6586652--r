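# MCMC settings kept small here; the acceptance suite runs the full-size
# recovery experiment.

test_that("model configuration validates its priors", {
  expect_s3_class(buoyancy_model(), "buoyancy_model")
  expect_error(buoyancy_model(sd_in_scale = 0), "sd_in_scale")
  expect_error(buoyancy_model(p_shape1 = -1))
})

test_that("simulated series obey the stated process law", {
  # time scaling: doubling the gaps while halving the variance rate leaves
  # the terminal-increment law unchanged (closed-form variance oracle)
  m <- buoyancy_model()
  n <- 50
  v_theory <- 0.03^2 * 0.2 * (n - 1) + m$delta1_sd^2
  d1 <- replicate(300, simulate_drift_series(n, dt = 0.2, model = m,
    sd_delta = 0.03, seed = sample.int(1e6, 1))$delta[n])
  d2 <- replicate(300, simulate_drift_series(n, dt = 0.4, model = m,
    sd_delta = 0.03 / sqrt(2), seed = sample.int(1e6, 1))$delta[n])
  expect_equal(var(d1), v_theory, tolerance = 0.25)
  expect_equal(var(d2), v_theory, tolerance = 0.25)
  # determinism contract
  s1 <- simulate_drift_series(40, seed = 8)
  s2 <- simulate_drift_series(40, seed = 8)
  expect_identical(s1, s2)
})

test_that("the filter recovers inclusion against the closed-form oracle", {
  # constant buoyancy -0.2, tight observation noise, 10 one-sided
  # outliers displaced by +0.3 among 110 dives
  set.seed(11)
  n <- 110
  tt <- cumsum(runif(n, 0.1, 0.3)); tt <- tt - tt[1]
  mu_true <- -0.2
  r <- rnorm(n, mu_true, 0.02)
  out <- sort(sample.int(n, 10))
  r[out] <- r[out] + 0.3
  fit <- fit_trajectory_filter(tt, r, seed = 1, n_iter = 1500,
                               n_burnin = 750)
  o <- fit$observations
  # every displaced dive is flagged
  expect_true(all(o$p_in[out] <= 0.95))
  # classification agrees with the conditional mixture-posterior oracle at
  # the true parameters (p = 100/110, sd_out from the 0.3 displacement)
  p_or <- mixture_p_in(r, mu_true, 0.02, sqrt(0.3^2 + 0.02^2), 100 / 110)
  agree <- (o$p_in > 0.95) == (p_or > 0.95)
  expect_gte(mean(agree), 0.9)
  expect_lt(mean(abs(o$p_in - p_or)), 0.1)
  # posterior buoyancy tracks the constant truth within the noise SD
  expect_lt(sqrt(mean((o$mu_post - mu_true)^2)), 0.02)
})

test_that("degenerate mixtures lose their discriminating power", {
  # as tau_r_out -> tau_r_in the two components coincide and P(z) is
  # dominated by the prior p, identically across dives
  set.seed(4)
  r <- rnorm(60, -0.25, 0.02)
  r[c(10, 40)] <- r[c(10, 40)] + 0.4            # would-be outliers
  m <- buoyancy_model(sd_extra_scale = 1e-6)
  fit <- fit_trajectory_filter(seq(0, by = 0.2, length.out = 60), r,
                               model = m, seed = 2, n_iter = 800,
                               n_burnin = 400)
  p_in <- fit$observations$p_in
  expect_lt(max(p_in) - min(p_in), 0.15)
  expect_equal(mean(p_in), 0.9, tolerance = 0.08)  # Beta(9,1) prior mean
  # with a finite large tau_r_out, a far outlier is driven to P ~ 0
  fit2 <- fit_trajectory_filter(seq(0, by = 0.2, length.out = 60), r,
                                seed = 2, n_iter = 800, n_burnin = 400)
  expect_lt(max(fit2$observations$p_in[c(10, 40)]), 0.05)
})

test_that("a single observation is handled without a walk", {
  fit <- fit_trajectory_filter(0, -0.25, seed = 9, n_chains = 2,
                               n_iter = 500, n_burnin = 250, n_adapt = 200)
  p1 <- fit$observations$p_in
  expect_true(is.finite(p1) && p1 >= 0 && p1 <= 1)
})

test_that("input validation and reproducibility hold", {
  expect_error(fit_trajectory_filter(c(0, 1, 1), c(-0.2, -0.2, -0.2)),
               "strictly increasing")
  expect_error(fit_trajectory_filter(numeric(0), numeric(0)),
               "at least one")
  set.seed(123)
  r <- rnorm(30, -0.2, 0.03)
  f1 <- fit_trajectory_filter(seq_len(30) / 5, r, seed = 7, n_chains = 2,
                              n_iter = 400, n_burnin = 200, n_adapt = 200)
  f2 <- fit_trajectory_filter(seq_len(30) / 5, r, seed = 7, n_chains = 2,
                              n_iter = 400, n_burnin = 200, n_adapt = 200)
  expect_identical(f1$observations$p_in, f2$observations$p_in)
})

test_that("final selection keeps observed rates above the strict threshold", {
  traj <- structure(list(observations = data.frame(
    t = 1:4, r = c(-0.3, -0.28, 0.1, -0.26),
    p_in = c(0.96, 0.95, 0.10, 0.99),
    mu_post = c(-0.29, -0.29, -0.28, -0.28),
    accepted = c(TRUE, FALSE, FALSE, TRUE))),
    class = "drift_trajectory")
  kept <- select_final_drift_dives(traj)
  expect_equal(kept$t, c(1, 4))
  expect_equal(kept$r, c(-0.3, -0.26))    # observed rates, not mu_post
  expect_false(0.95 %in% kept$p_in)       # P = 0.95 exactly is rejected
  none <- select_final_drift_dives(traj, threshold = 1)
  expect_equal(nrow(none), 0L)
})

test_that("posterior calibration holds for the identified quantities", {
  # scaled-down simulation-based check: prior-draw replicates, 90% CI
  # coverage of the within-trajectory SD and recovery of the buoyancy path
  m <- buoyancy_model()
  nrep <- 10; n <- 60
  cov_sdin <- logical(nrep); mu_ok <- logical(nrep)
  for (i in seq_len(nrep)) {
    set.seed(500 + i)
    alpha_t <- rnorm(1, m$alpha_mean, m$alpha_sd)
    V_t <- abs(rnorm(1, m$V_mean, m$V_sd))
    sdd_t <- abs(rnorm(1, 0, m$sd_delta_scale))
    sdin_t <- abs(rnorm(1, 0, m$sd_in_scale))
    sdout_t <- sdin_t + abs(rnorm(1, 0, m$sd_extra_scale))
    p_t <- rbeta(1, m$p_shape1, m$p_shape2)
    v0_t <- 1 / 1.01
    delta <- cumsum(c(rnorm(1, 0, m$delta1_sd),
                      rnorm(n - 1, 0, sdd_t * sqrt(0.2))))
    rho <- (1 + delta) / (v0_t + V_t * delta)
    mu <- alpha_t * sign(rho - 1) * sqrt(abs(rho - 1))
    z <- rbinom(n, 1, p_t)
    r <- rnorm(n, mu, ifelse(z == 1, sdin_t, sdout_t))
    # reduced chains: convergence flags are tolerated (not asserted) here
    fit <- suppressWarnings(
      fit_trajectory_filter(seq(0, by = 0.2, length.out = n), r,
        model = buoyancy_model(v0 = v0_t), seed = i, n_chains = 2,
        n_iter = 1000, n_burnin = 500))
    q <- quantile(fit$draws[, , "sd_in"], c(0.05, 0.95))
    cov_sdin[i] <- sdin_t >= q[1] && sdin_t <= q[2]
    mu_ok[i] <- sqrt(mean((fit$observations$mu_post - mu)^2)) <
      max(sdin_t, 0.02)
  }
  expect_gte(sum(cov_sdin), 7L)   # 90% nominal over 10 replicates
  expect_gte(sum(mu_ok), 7L)
})
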