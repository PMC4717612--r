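test_that("generation is deterministic given the seed", {
  cfg <- generator_config(K = 8, n_sampler = 40, seed = 5)
  g1 <- generate_raw_dataset(cfg)
  g2 <- generate_raw_dataset(cfg)
  expect_identical(as.data.frame(g1$dataset), as.data.frame(g2$dataset))
  cfg$seed <- 6L
  g3 <- generate_raw_dataset(cfg)
  expect_false(identical(as.data.frame(g1$dataset),
                         as.data.frame(g3$dataset)))
})

test_that("degenerate population collapses aggregates to the hyper-truth", {
  cfg <- generator_config(K = 3, raw_hyper = list(mu_m = 0.4, sigma_m = 0,
                                                  mu_ls = 0.1, sigma_ls = 0),
                          n_sampler = 1e6, seed = 2)
  g <- generate_raw_dataset(cfg)
  df <- as.data.frame(g$dataset)
  expect_true(all(abs(df$m - 0.4) < 0.01))
  expect_true(all(abs(df$s / exp(0.1) - 1) < 0.01))
})

test_that("aggregate variance matches the two-stage law", {
  # Var(m_i) = sigma_m^2 + E[sigma_i^2] / n under the hierarchy; compared
  # against an independent brute-force two-stage simulation
  hyper <- list(mu_m = 0, sigma_m = 0.7, mu_ls = 0, sigma_ls = 0.2)
  g <- generate_raw_dataset(generator_config(K = 4000, raw_hyper = hyper,
                                             n_sampler = 30, seed = 12))
  v_gen <- var(as.data.frame(g$dataset)$m)
  set.seed(4242)
  brute <- replicate(4000, {
    mu <- rnorm(1, hyper$mu_m, hyper$sigma_m)
    sig <- exp(rnorm(1, hyper$mu_ls, hyper$sigma_ls))
    mean(rnorm(30, mu, sig))
  })
  expect_equal(mean(as.data.frame(g$dataset)$m), 0, tolerance = 0.05)
  expect_equal(v_gen, var(brute), tolerance = 0.08)
})

test_that("simulated aggregates satisfy the t and chi-square pivot laws", {
  # fixed (mu, sigma, n): this validates the likelihood kernels end-to-end
  cfg <- generator_config(K = 10000,
                          raw_hyper = list(mu_m = 0.3, sigma_m = 0,
                                           mu_ls = log(1.2), sigma_ls = 0),
                          n_sampler = 10, seed = 77)
  df <- as.data.frame(generate_raw_dataset(cfg)$dataset)
  n <- 10
  tpiv <- sqrt(n - 1) * (df$m - 0.3) / df$s
  cpiv <- (n - 1) * df$s^2 / 1.2^2
  kt <- suppressWarnings(ks.test(tpiv, "pt", df = n - 1))
  kc <- suppressWarnings(ks.test(cpiv, "pchisq", df = n - 1))
  expect_gt(kt$p.value, 0.01)
  expect_gt(kc$p.value, 0.01)
})

test_that("calibrated generator honours the variance decomposition", {
  ch <- list(mu_delta = 0, sigma_delta = 0, rho_p = 0,
             mu_lt = theta_to_unconstrained(1), sigma_lt = 0, rho_s = 0)
  base <- list(mu_m = 0.2, sigma_m = 0.5, mu_ls = 0, sigma_ls = 0.15)
  cfg <- generator_config(K = 6, raw_hyper = base, calib_hyper = ch,
                          n_sampler = 20000, seed = 9)
  g <- generate_calibrated_dataset(cfg)
  tr <- g$truth
  expect_equal(tr$tau_i^2 + tr$upsilon_i^2, tr$sigma_i^2,
               tolerance = 1e-10)
  df <- as.data.frame(g$dataset)
  # theta = 1: calibration leaves the SD unchanged on average
  expect_equal(df$s_c / df$s, rep(1, 6), tolerance = 0.05)
  # theta -> sqrt(2) (tau = 0): Var(ce) ~ 2 sigma^2
  ch2 <- ch; ch2$mu_lt <- theta_to_unconstrained(sqrt(2) - 1e-6)
  cfg2 <- generator_config(K = 4, raw_hyper = base, calib_hyper = ch2,
                           n_sampler = 1e5, seed = 10)
  df2 <- as.data.frame(generate_calibrated_dataset(cfg2)$dataset)
  expect_equal(df2$s_c^2 / (2 * df2$s^2), rep(1, 4), tolerance = 0.05)
  # mechanistic mode with delta = 0 truth: calibrated errors average 0
  cfg3 <- generator_config(K = 4, raw_hyper = base, calib_hyper = ch,
                           n_sampler = 1e5, seed = 11,
                           calibrated_mode = "mechanistic")
  df3 <- as.data.frame(generate_calibrated_dataset(cfg3)$dataset)
  expect_true(all(abs(df3$m_c) < 0.02))
  # empirical sd(ce)/sd(e) estimates theta_i
  expect_equal(df3$s_c / df3$s,
               generate_calibrated_dataset(cfg3)$truth$theta_i,
               tolerance = 0.05)
  expect_error(generator_config(K = 2, calib_hyper = list(
    mu_delta = 0, sigma_delta = 1, rho_p = 1.2, mu_lt = 0, sigma_lt = 1,
    rho_s = 0)), "rho_p")
})

test_that("recovery_experiment reports per-replication coverage rows", {
  truth <- generator_config(K = 12,
                            raw_hyper = list(mu_m = 0.2, sigma_m = 0.6,
                                             mu_ls = 0.1, sigma_ls = 0.2),
                            n_sampler = 50, seed = 3)
  rec <- recovery_experiment(truth, reps = 1,
                             mcmc = quick_mcmc(4, warmup = 300, draws = 300))
  expect_equal(nrow(rec), 4L)           # one row per hyperparameter
  expect_setequal(rec$quantity, c("mu_m", "sigma_m", "mu_ls", "sigma_ls"))
  agg <- attr(rec, "summary")
  expect_true(all(c("bias", "rmse", "coverage") %in% names(agg)))
  # degenerate K = 3 design: wide intervals flagged, no crash
  tiny <- truth; tiny$K <- 3L
  rec3 <- recovery_experiment(tiny, reps = 1,
                              mcmc = quick_mcmc(4, warmup = 300,
                                                draws = 300))
  expect_true(any(rec3$wide))
})
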