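# frozen oracle values are computed by quadrature inside the test (the
# oracle normalizes the bare kernels numerically, independent of the
# closed-form densities used in the implementation)

test_that("both likelihood kernels are proper densities (quadrature)", {
  for (cs in list(c(n = 5, sig = 1), c(n = 30, sig = 2))) {
    Z <- integrate(function(s) exp(loglik_sd(s, cs["n"], cs["sig"])),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(Z, 1, tolerance = 1e-6)
  }
  for (cfg in list(likelihood_config("as_printed"),
                   likelihood_config("classical"))) {
    Z <- integrate(function(m) exp(loglik_mean(m, s = 1.3, n = 18,
                                               mu = 0.4, cfg = cfg)),
                   -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(Z, 1, tolerance = 1e-6)
  }
})

test_that("loglik_mean: symmetric in mu about m, maximized at mu = m", {
  m <- 0.37; s <- 1.1; n <- 25
  for (d in c(0.1, 0.5, 2)) {
    expect_equal(loglik_mean(m, s, n, m + d), loglik_mean(m, s, n, m - d))
  }
  mus <- seq(-2, 2, by = 0.01)
  ll <- loglik_mean(m, s, n, mus)
  expect_equal(mus[which.max(ll)], m, tolerance = 0.011)
  expect_error(loglik_mean(0, 1, 1, 0), "n >= 2")
  expect_error(loglik_mean(0, 0, 10, 0), "s > 0")
})

test_that("loglik_mean matches a quadrature-normalized t kernel", {
  # independent oracle: normalize the unscaled kernel
  # (1 + c^2 (m - mu)^2 / (s^2 nu))^(-(nu+1)/2) over m numerically
  m <- 0.5; s <- 1.0; n <- 30; mu <- 0
  for (scaling in c("as_printed", "classical")) {
    cfg <- likelihood_config(scaling)
    cc <- if (scaling == "as_printed") sqrt(n - 1) else sqrt(n)
    nu <- n - 1
    kern <- function(x) (1 + cc^2 * (x - mu)^2 / (s^2 * nu))^(-(nu + 1) / 2)
    Z <- integrate(kern, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(loglik_mean(m, s, n, mu, cfg), log(kern(m) / Z),
                 tolerance = 1e-8)
  }
})

test_that("loglik_sd: argmax and scale equivariance", {
  # d/ds of s^(n-2) exp(-(n-1) s^2 / (2 sigma^2)) vanishes at
  # s = sigma sqrt((n-2)/(n-1))
  for (cs in list(c(n = 3, sig = 1), c(n = 10, sig = 0.7),
                  c(n = 50, sig = 2))) {
    n <- unname(cs["n"]); sig <- unname(cs["sig"])
    ss <- seq(sig * 0.3, sig * 2, length.out = 4000)
    shat <- ss[which.max(loglik_sd(ss, n, sig))]
    expect_equal(shat, sig * sqrt((n - 2) / (n - 1)),
                 tolerance = 2 * diff(ss[1:2]))
  }
  for (k in c(0.5, 2, 7)) {
    expect_equal(loglik_sd(k * 1.2, 12, k * 0.9),
                 loglik_sd(1.2, 12, 0.9) - log(k))
  }
})

test_that("as_printed vs classical scaling: implied SE ratio is sqrt(n/(n-1))", {
  # the implied SE of the mean is s/sqrt(n-1) (as printed) vs s/sqrt(n):
  # ratio sqrt(n/(n-1)) - 1 is 2.9% at the often-quoted n = 18, 4.4% at
  # the bundled minimum n = 12, and below 2% only for n >= 26
  ratio <- function(n) sqrt(n / (n - 1))
  expect_equal(ratio(18) - 1, 0.0290, tolerance = 1e-3)
  expect_equal(ratio(12) - 1, 0.0445, tolerance = 1e-3)
  expect_true(all(ratio(26:200) - 1 < 0.02))
  ns <- vapply(bundled_literature_dataset()$series, `[[`, integer(1), "n")
  expect_identical(min(ns), 12L)
})

test_that("(m, s) are independent under normal sampling (Monte-Carlo)", {
  set.seed(42)
  R <- 5000; n <- 10
  sims <- replicate(R, {
    x <- rnorm(n, 1, 2)
    c(mean(x), sd(x))
  })
  expect_lt(abs(cor(sims[1, ], sims[2, ])), 3 / sqrt(R))
})

test_that("theta transform is the stated bijection with its Jacobian", {
  expect_equal(theta_to_unconstrained(sqrt(2) / 2), 0)
  expect_equal(unconstrained_to_theta(0), sqrt(2) / 2)
  for (th in c(0.1, 1.0, 1.4)) {
    expect_equal(unconstrained_to_theta(theta_to_unconstrained(th)), th)
  }
  # limits
  expect_lt(theta_to_unconstrained(1e-9), -20)
  expect_gt(theta_to_unconstrained(sqrt(2) - 1e-12), 20)
  expect_lt(sqrt(2) - unconstrained_to_theta(40), 1e-10)
  expect_error(theta_to_unconstrained(1.5), "sqrt")
  # Jacobian at 0 is sqrt(2)/4; spot-check against finite differences
  expect_equal(exp(theta_transform_log_jacobian(0)), sqrt(2) / 4)
  h <- 1e-6
  for (z in c(-1.3, 0, 2.1)) {
    fd <- (unconstrained_to_theta(z + h) - unconstrained_to_theta(z - h)) /
      (2 * h)
    expect_equal(exp(theta_transform_log_jacobian(z)), fd,
                 tolerance = 1e-7)
  }
})

test_that("unbiased_log_sd corrects the downward bias of log s", {
  expect_equal(unbiased_log_sd(1, 2), 0.5)
  expect_equal(unbiased_log_sd(2, 1e7), log(2), tolerance = 1e-6)
  set.seed(11)
  n <- 5; R <- 1e5
  logs <- replicate(R, log(sd(rnorm(n))))
  bias_raw <- abs(mean(logs) - 0)               # true log sigma = 0
  bias_corr <- abs(mean(logs + 1 / (2 * (n - 1))) - 0)
  expect_lt(bias_corr, bias_raw)
  # the correction is first-order: the exact residual bias is
  # (digamma((n-1)/2) - log((n-1)/2))/2 + 1/(2(n-1)), ~ -0.010 at n = 5
  resid <- abs((digamma((n - 1) / 2) - log((n - 1) / 2)) / 2 +
                 1 / (2 * (n - 1)))
  expect_equal(bias_corr, resid, tolerance = 0.15)
})
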