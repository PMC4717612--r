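# a hand-built posterior_draws object lets deterministic operations be
# tested without running the sampler
fake_fit <- function(N = 200, model = "raw", K = 1) {
  draws <- cbind(mu_m = rep(0.5, N), sigma_m = rep(0, N) + 1e-300,
                 mu_ls = rep(log(2), N), sigma_ls = rep(0, N) + 1e-300,
                 `mu[1]` = rep(0.5, N), `sigma[1]` = rep(2, N))
  structure(list(draws = draws, lp = rep(0, N),
                 chain = rep(1:2, each = N / 2), model = model, K = K,
                 labels = "a"),
            class = "posterior_draws")
}

test_that("fit_raw recovers a single dominant series mean", {
  d <- error_dataset(list(aggregate_series("big", 1e5, 1.0, 0.5)))
  f <- fit_raw(d, mcmc = quick_mcmc(3))
  expect_lt(abs(mean(f$draws[, "mu[1]"]) - 1.0), 0.01)
  expect_lt(abs(mean(f$draws[, "sigma[1]"]) - 0.5), 0.005)
})

test_that("posterior draws respect the support invariants", {
  d <- bundled_literature_dataset()
  f <- fit_joint(d, mcmc = quick_mcmc(5, warmup = 300, draws = 300))
  sig_cols <- grep("^sigma", colnames(f$draws))
  expect_true(all(f$draws[, sig_cols] > 0))
  th <- f$draws[, grep("^theta\\[", colnames(f$draws))]
  expect_true(all(th > 0 & th < sqrt(2)))
  expect_true(all(abs(f$draws[, c("rho_p", "rho_s")]) < 1))
})

test_that("joint fit on calibration-free data matches the raw fit marginally", {
  gen <- generate_raw_dataset(generator_config(
    K = 15, raw_hyper = list(mu_m = 0.2, sigma_m = 0.6, mu_ls = 0.1,
                             sigma_ls = 0.2), n_sampler = 60, seed = 31))
  mc <- quick_mcmc(9, chains = 2, warmup = 600, draws = 800)
  fr <- fit_raw(gen$dataset, mcmc = mc)
  fj <- fit_joint(gen$dataset, mcmc = mc, require_calibrated = FALSE)
  expect_error(fit_joint(gen$dataset), "calibrated")
  for (q in c("mu_m", "sigma_m", "mu_ls", "sigma_ls")) {
    cr <- convergence_report(fr, q); cj <- convergence_report(fj, q)
    mcse <- sqrt(sd(fr$draws[, q])^2 / cr$ess[1] +
                 sd(fj$draws[, q])^2 / cj$ess[1])
    expect_lt(abs(mean(fr$draws[, q]) - mean(fj$draws[, q])), 3 * mcse)
  }
})

test_that("identical raw and calibrated aggregates pull delta toward 0", {
  d <- error_dataset(list(
    aggregate_series("eq1", 80, 0.3, 1.1, n_c = 80, m_c = 0.3, s_c = 1.1),
    aggregate_series("eq2", 60, -0.1, 0.9, n_c = 60, m_c = -0.1, s_c = 0.9),
    aggregate_series("eq3", 70, 0.1, 1.0, n_c = 70, m_c = 0.1, s_c = 1.0)))
  f <- fit_joint(d, mcmc = quick_mcmc(13))
  for (i in 1:3)
    expect_lt(abs(mean(f$draws[, paste0("delta[", i, "]")])), 0.15)
})

test_that("replication draws follow the population law and are seeded", {
  f <- fake_fit()
  r1 <- sample_replication(f, seed = 4)
  r2 <- sample_replication(f, seed = 4)
  expect_identical(r1$replication, r2$replication)
  r3 <- sample_replication(f, seed = 5)
  expect_false(identical(r1$replication, r3$replication))
  # degenerate hyper-draws: sigma_m = sigma_ls = 0 gives mu* and sigma*
  # exactly equal to the population locations in every draw
  expect_true(all(r1$replication[, "mu_star"] == 0.5))
  expect_true(all(r1$replication[, "sigma_star"] == 2))
  # replication law against direct Monte-Carlo from the same hyperdraws
  d <- bundled_literature_dataset()
  g <- sample_replication(fit_raw(d, mcmc = quick_mcmc(2)), seed = 8)
  mu_star <- g$replication[, "mu_star"]
  set.seed(8)
  direct <- rnorm(nrow(g$draws), g$draws[, "mu_m"], g$draws[, "sigma_m"])
  expect_identical(mu_star, direct)
  expect_equal(var(mu_star),
               mean(g$draws[, "sigma_m"]^2) + var(g$draws[, "mu_m"]),
               tolerance = 0.1)
})

test_that("summarize_draws applies the fixed quantile rule and derived names", {
  f <- fake_fit()
  sm <- summarize_draws(f, "mu_m")
  expect_equal(sm$mean, 0.5)
  expect_equal(sm$sd, 0)
  expect_true(all(unlist(sm[, 4:8]) == 0.5))
  # frozen type-7 check: quantiles of 0..100 at .025/.975 are 2.5/97.5;
  # on the duplicated 202-value version h = 201 * 0.025 = 5.025 lands
  # between the sorted values 2 and 3: 2 + 0.025 * 1 = 2.025
  f2 <- fake_fit(N = 202)
  f2$draws[, "mu_m"] <- c(0:100, 0:100)
  sm2 <- summarize_draws(f2, "mu_m")
  expect_equal(sm2$q2.5, 2.025, tolerance = 1e-9)
  f2$draws <- f2$draws[1:101, , drop = FALSE]
  f2$lp <- f2$lp[1:101]; f2$chain <- rep(1:2, c(51, 50))
  sm3 <- summarize_draws(f2, "mu_m")
  expect_equal(sm3$q2.5, 2.5)
  expect_equal(sm3$q97.5, 97.5)
  expect_error(summarize_draws(f, "nonesuch"), "unknown quantity")
})

test_that("prob_event returns exact fractions with MC error", {
  f <- sample_replication(fake_fit(), seed = 1)
  expect_equal(prob_event(f, function(q) q("mu_star") > -Inf)$prob, 1)
  expect_equal(prob_event(f, function(q) abs(q("e_star")) < Inf)$prob, 1)
  pe <- prob_event(f, function(q) q("e_star") > 0.5)
  expect_equal(pe$mc_se, sqrt(pe$prob * (1 - pe$prob) / pe$n))
  d <- bundled_literature_dataset()
  g <- sample_replication(fit_joint(d, mcmc = quick_mcmc(2)), seed = 3)
  expect_equal(prob_event(g, function(q) q("theta_star") > sqrt(2))$prob, 0)
})

test_that("posterior-predictive quantiles are calibrated under the truth and flag outliers", {
  gen <- generate_raw_dataset(generator_config(
    K = 34, raw_hyper = list(mu_m = 0.23, sigma_m = 0.71, mu_ls = 0.23,
                             sigma_ls = 0.18), n_sampler = 50, seed = 21))
  f <- fit_raw(gen$dataset, mcmc = quick_mcmc(6))
  ppc <- posterior_predictive_check(f, seed = 99)
  expect_true(all(ppc$quantile >= 0 & ppc$quantile <= 1))
  ks <- suppressWarnings(ks.test(ppc$quantile, "punif"))
  # critical value at alpha = 0.01 for n quantiles
  expect_lt(ks$statistic, 1.63 / sqrt(nrow(ppc)))
  # artificial outlier series: far tail of the population predictive
  d2 <- gen$dataset
  d2$series[[length(d2$series) + 1L]] <-
    aggregate_series("outlier", 50, 10, 1.2)
  f2 <- fit_raw(d2, mcmc = quick_mcmc(6))
  ppc2 <- posterior_predictive_check(f2, seed = 99)
  expect_gt(ppc2$quantile[ppc2$label == "outlier" & ppc2$stat == "m"], 0.99)
})

test_that("convergence_report flags degenerate input and passes on iid draws", {
  f <- fake_fit()
  cv <- convergence_report(f, "mu_m")
  expect_true(is.na(cv$rhat))
  expect_equal(cv$flag, "constant")
  # independent standard-normal draws, 4 chains x 1000
  set.seed(1)
  g <- fake_fit(N = 4000)
  g$chain <- rep(1:4, each = 1000)
  g$draws[, "mu_m"] <- rnorm(4000)
  cv2 <- convergence_report(g, "mu_m")
  expect_lt(cv2$rhat, 1.01)
  expect_gt(cv2$ess, 2000)
  # single chain is flagged, not an error
  h <- fake_fit(); h$chain <- rep(1L, nrow(h$draws))
  cv3 <- convergence_report(h, "mu_m")
  expect_equal(cv3$flag, "single-chain")
})
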