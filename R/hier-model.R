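#' Prior configuration
#'
#' Weakly informative priors: Cauchy(0, `location_scale`) on the location
#' hyperparameters (population mean bias, mean bias correction, mean
#' log-SD, mean transformed SD-ratio), half-Cauchy(0, `sd_scale`) on the
#' corresponding population SDs, Uniform(-1, 1) on the two correlations.
#' The data (mean errors and log-SDs) are roughly centered and unit-scaled,
#' so scale 3 is weakly informative without favouring absurd magnitudes.
#'
#' @param location_scale Cauchy scale for location hyperparameters (> 0).
#' @param sd_scale Half-Cauchy scale for SD hyperparameters (> 0).
#' @return A `prior_config` object.
#' @export
prior_config <- function(location_scale = 3, sd_scale = 3) {
  stopifnot(location_scale > 0, sd_scale > 0)
  structure(list(location_scale = location_scale, sd_scale = sd_scale),
            class = "prior_config")
}

#' MCMC configuration
#'
#' The sampler is a componentwise adaptive random-walk Metropolis on a
#' non-centered parameterization; step sizes adapt during warmup toward
#' `target_acceptance` (0.44, the optimum for one-dimensional Gaussian
#' random-walk proposals) and are frozen for the sampling phase.
#'
#' @param chains Number of chains (>= 2 for reported fits).
#' @param warmup_draws Warmup iterations per chain (adaptation phase).
#' @param sampling_draws Post-warmup iterations kept per chain.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param target_acceptance Componentwise acceptance target in (0, 1).
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(chains = 4, warmup_draws = 1000,
                        sampling_draws = 1000, seed = 20160119L,
                        target_acceptance = 0.44) {
  stopifnot(chains >= 1, warmup_draws >= 1, sampling_draws >= 1,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(chains = as.integer(chains),
                 warmup_draws = as.integer(warmup_draws),
                 sampling_draws = as.integer(sampling_draws),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance),
            class = "mcmc_config")
}

# assemble the data list consumed by the C++ kernels
model_data_list <- function(d, priors, lik) {
  df <- as.data.frame(d)
  cal <- which(!is.na(df$n_c))
  list(m = df$m, s = df$s, n = as.integer(df$n),
       cal_idx = as.integer(cal - 1L),
       mc = df$m_c[cal], sc = df$s_c[cal], nc = as.integer(df$n_c[cal]),
       loc_scale = priors$location_scale, sd_scale = priors$sd_scale,
       as_printed = identical(lik$mean_scaling, "as_printed"))
}

# data-driven initial values, jittered per chain (jitter drawn from the
# current RNG stream so each chain starts in a different overdispersed spot)
init_values <- function(model, dl, jitter = 0.5) {
  K <- length(dl$m)
  safe_sd <- function(x, floor) {
    s <- stats::sd(x)
    if (is.na(s)) floor else max(s, floor)   # K = 1 has no spread
  }
  base <- c(mean(dl$m), log(safe_sd(dl$m, 0.2)),
            mean(log(dl$s)), log(safe_sd(log(dl$s), 0.1)))
  if (model == 2L) {
    dshift <- if (length(dl$cal_idx) > 0)
      dl$mc - dl$m[dl$cal_idx + 1L] else 0
    base <- c(base, mean(dshift), log(0.3), 0, 0, log(0.3), 0)
  }
  latent <- c(dl$m, log(dl$s))        # mu_i, lambda_i at their MLEs
  if (model == 2L && length(dl$cal_idx) > 0) {
    delta0 <- dl$mc - dl$m[dl$cal_idx + 1L]
    th <- pmin(pmax(dl$sc / dl$s[dl$cal_idx + 1L], 0.05), sqrt(2) - 0.05)
    latent <- c(latent, delta0, log(th / (sqrt(2) - th)))
  }
  p <- c(base, latent)
  p + stats::rnorm(length(p), 0, jitter) *
    c(rep(0.3, length(base)), rep(0.1, length(latent)))
}

# parameter names on the natural scale, in storage order
hyper_names <- function(model) {
  nm <- c("mu_m", "sigma_m", "mu_ls", "sigma_ls")
  if (model == 2L)
    nm <- c(nm, "mu_delta", "sigma_delta", "rho_p", "mu_lt", "sigma_lt",
            "rho_s")
  nm
}

# map unconstrained draws (one chain) to natural-scale named draws
transform_draws <- function(model, raw, K, cal_idx = integer()) {
  H <- if (model == 1L) 4L else 10L
  hyp <- raw[, seq_len(H), drop = FALSE]
  hyp[, 2] <- exp(hyp[, 2]); hyp[, 4] <- exp(hyp[, 4])
  if (model == 2L) {
    hyp[, 6] <- exp(hyp[, 6]); hyp[, 9] <- exp(hyp[, 9])
    hyp[, 7] <- tanh(hyp[, 7]); hyp[, 10] <- tanh(hyp[, 10])
  }
  colnames(hyp) <- hyper_names(model)
  mu_i <- raw[, H + seq_len(K), drop = FALSE]
  sigma_i <- exp(raw[, H + K + seq_len(K), drop = FALSE])
  colnames(mu_i) <- paste0("mu[", seq_len(K), "]")
  colnames(sigma_i) <- paste0("sigma[", seq_len(K), "]")
  out <- cbind(hyp, mu_i, sigma_i)
  if (model == 2L) {
    # sampled delta/z for calibrated series; data-free series' delta/z are
    # exact draws from the conditional prior given (mu_i, lambda_i, hypers)
    # (they carry no likelihood, so this is distributionally equivalent to
    # sampling them in the chain, without the funnel)
    N <- nrow(raw)
    cal <- cal_idx + 1L
    C <- length(cal)
    delta_i <- matrix(NA_real_, N, K)
    z_i <- matrix(NA_real_, N, K)
    if (C > 0) {
      delta_i[, cal] <- raw[, H + 2 * K + seq_len(C), drop = FALSE]
      z_i[, cal] <- raw[, H + 2 * K + C + seq_len(C), drop = FALSE]
    }
    free <- setdiff(seq_len(K), cal)
    if (length(free) > 0) {
      rho_p <- hyp[, "rho_p"]; rho_s <- hyp[, "rho_s"]
      lam_i <- log(sigma_i)
      for (i in free) {
        delta_i[, i] <- stats::rnorm(
          N,
          hyp[, "mu_delta"] + rho_p * hyp[, "sigma_delta"] /
            hyp[, "sigma_m"] * (mu_i[, i] - hyp[, "mu_m"]),
          hyp[, "sigma_delta"] * sqrt(1 - rho_p^2))
        z_i[, i] <- stats::rnorm(
          N,
          hyp[, "mu_lt"] + rho_s * hyp[, "sigma_lt"] /
            hyp[, "sigma_ls"] * (lam_i[, i] - hyp[, "mu_ls"]),
          hyp[, "sigma_lt"] * sqrt(1 - rho_s^2))
      }
    }
    theta_i <- unconstrained_to_theta(z_i)
    colnames(delta_i) <- paste0("delta[", seq_len(K), "]")
    colnames(theta_i) <- paste0("theta[", seq_len(K), "]")
    out <- cbind(out, delta_i, theta_i)
  }
  out
}

run_model <- function(model, d, priors, lik, mcmc) {
  viol <- validate_dataset(d)
  if (nrow(viol) > 0L)
    stop("invalid dataset: ", paste(unique(viol$rule), collapse = "; "),
         call. = FALSE)
  dl <- model_data_list(d, priors, lik)
  K <- length(dl$m)
  C <- length(dl$cal_idx)
  P <- if (model == 1L) 4L + 2L * K else 10L + 2L * K + 2L * C
  draws <- NULL; lp <- c(); chain <- c(); accept <- NULL
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch - 1L)
    init <- init_values(model, dl)
    res <- mwg_chain_cpp(model, dl, init, mcmc$warmup_draws,
                         mcmc$sampling_draws, mcmc$target_acceptance,
                         rep(0.5, P))
    tr <- transform_draws(model, res$draws, K, dl$cal_idx)
    draws <- rbind(draws, tr)
    lp <- c(lp, res$lp)
    chain <- c(chain, rep(ch, mcmc$sampling_draws))
    accept <- rbind(accept, res$accept)
  }
  structure(list(draws = draws, lp = lp, chain = chain,
                 model = if (model == 1L) "raw" else "joint",
                 K = K, dataset = d,
                 labels = vapply(d$series, `[[`, character(1), "label"),
                 priors = priors, lik = lik, mcmc = mcmc,
                 accept = accept),
            class = "posterior_draws")
}

#' Fit the raw-error hierarchical model
#'
#' Series biases are normal around a population mean bias, series SDs are
#' lognormal; observed aggregates enter through the exact Student-t /
#' chi-square sampling likelihoods ([loglik_mean()], [loglik_sd()]).
#' Calibrated blocks, if present in the dataset, are ignored by this fit.
#'
#' @param d An `error_dataset`.
#' @param priors A [prior_config()].
#' @param lik A [likelihood_config()].
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_draws` object (no replication draws yet; see
#'   [sample_replication()]).
#' @export
fit_raw <- function(d, priors = prior_config(), lik = likelihood_config(),
                    mcmc = mcmc_config()) {
  run_model(1L, d, priors, lik, mcmc)
}

#' Fit the joint raw + calibrated hierarchical model
#'
#' Adds, for every series, a bias correction `delta_i` (bivariate normal
#' with the bias `mu_i`) and a SD-ratio `theta_i` in (0, sqrt(2)) whose
#' logit-type transform is bivariate normal with `log sigma_i`; series with
#' calibrated aggregates contribute the additional t / chi-square terms at
#' `(mu_i + delta_i, sigma_i * theta_i)`, series without contribute only
#' raw terms (their `delta_i`, `theta_i` are hierarchy-only).
#'
#' @inheritParams fit_raw
#' @param require_calibrated Error if the dataset has no calibrated series
#'   (default).  Set `FALSE` to fit anyway, e.g. to check that the joint
#'   model then reduces to the raw model marginally.
#' @return A `posterior_draws` object.
#' @export
fit_joint <- function(d, priors = prior_config(), lik = likelihood_config(),
                      mcmc = mcmc_config(), require_calibrated = TRUE) {
  ncal <- sum(vapply(d$series, has_calibrated, logical(1)))
  if (require_calibrated && ncal == 0L)
    stop("fit_joint requires at least one series with calibrated aggregates",
         call. = FALSE)
  run_model(2L, d, priors, lik, mcmc)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s model, %d series, %d draws (%d chains)\n",
              x$model, x$K, nrow(x$draws), max(x$chain)))
  cat("  quantities:", paste(utils::head(colnames(x$draws), 8),
                             collapse = ", "), "...\n")
  if (!is.null(x$replication))
    cat("  replication draws present:",
        paste(colnames(x$replication), collapse = ", "), "\n")
  invisible(x)
}

#' Draw new-study and new-observation replication quantities
#'
#' For each posterior draw, samples the parameters of a hypothetical new
#' study and one new observation in it: `mu_star ~ N(mu_m, sigma_m^2)`,
#' `log sigma_star ~ N(mu_ls, sigma_ls^2)`, `e_star ~ N(mu_star,
#' sigma_star^2)`.  For a joint fit, the pair (`mu_star`, `delta_star`)
#' and (`log sigma_star`, `z_star`) are drawn from their bivariate laws,
#' `theta_star` is the back-transformed SD-ratio, and the calibrated
#' quantities `mu_c_star = mu_star + delta_star`, `sigma_c_star =
#' sigma_star * theta_star`, `e_c_star ~ N(mu_c_star, sigma_c_star^2)` are
#' added.  Deterministic given `seed`.
#'
#' @param p A `posterior_draws` object.
#' @param seed Integer seed.
#' @return `p` with a `replication` matrix attached.
#' @export
sample_replication <- function(p, seed = 1L) {
  stopifnot(inherits(p, "posterior_draws"))
  set.seed(seed)
  dr <- p$draws
  N <- nrow(dr)
  mu_star <- stats::rnorm(N, dr[, "mu_m"], dr[, "sigma_m"])
  log_sigma_star <- stats::rnorm(N, dr[, "mu_ls"], dr[, "sigma_ls"])
  sigma_star <- exp(log_sigma_star)
  e_star <- stats::rnorm(N, mu_star, sigma_star)
  rep <- cbind(mu_star = mu_star, sigma_star = sigma_star, e_star = e_star)
  if (p$model == "joint") {
    rho_p <- dr[, "rho_p"]; rho_s <- dr[, "rho_s"]
    delta_star <- stats::rnorm(
      N,
      dr[, "mu_delta"] + rho_p * dr[, "sigma_delta"] / dr[, "sigma_m"] *
        (mu_star - dr[, "mu_m"]),
      dr[, "sigma_delta"] * sqrt(1 - rho_p^2))
    z_star <- stats::rnorm(
      N,
      dr[, "mu_lt"] + rho_s * dr[, "sigma_lt"] / dr[, "sigma_ls"] *
        (log_sigma_star - dr[, "mu_ls"]),
      dr[, "sigma_lt"] * sqrt(1 - rho_s^2))
    theta_star <- unconstrained_to_theta(z_star)
    mu_c_star <- mu_star + delta_star
    sigma_c_star <- sigma_star * theta_star
    e_c_star <- stats::rnorm(N, mu_c_star, sigma_c_star)
    rep <- cbind(rep, delta_star = delta_star, theta_star = theta_star,
                 mu_c_star = mu_c_star, sigma_c_star = sigma_c_star,
                 e_c_star = e_c_star)
  }
  p$replication <- rep
  p$replication_seed <- as.integer(seed)
  p
}

# fetch a named quantity (parameter, replication or derived) as a vector
draw_quantity <- function(p, name) {
  if (name %in% colnames(p$draws)) return(p$draws[, name])
  if (!is.null(p$replication) && name %in% colnames(p$replication))
    return(p$replication[, name])
  derived <- c("e_star_sq", "abs_e_star", "e_c_star_sq", "abs_e_c_star",
               "lp")
  if (name == "lp") return(p$lp)
  if (name %in% derived) {
    if (is.null(p$replication))
      stop("replication draws required for '", name, "'; run ",
           "sample_replication() first", call. = FALSE)
    base <- if (grepl("_c_", name)) p$replication[, "e_c_star"]
            else p$replication[, "e_star"]
    return(if (grepl("sq$", name)) base^2 else abs(base))
  }
  stop("unknown quantity '", name, "'", call. = FALSE)
}

#' Summarize posterior quantities
#'
#' Mean, SD and the 0.025/0.25/0.5/0.75/0.975 quantiles (type-7 estimator)
#' of named draws.  Besides parameter and replication names, the derived
#' quantities `"e_star_sq"`, `"abs_e_star"`, `"e_c_star_sq"`,
#' `"abs_e_c_star"` and `"lp"` are accepted.
#'
#' @param p A `posterior_draws` object.
#' @param quantities Character vector of quantity names.
#' @return A data frame, one row per quantity, with columns `quantity`,
#'   `mean`, `sd`, `q2.5`, `q25`, `q50`, `q75`, `q97.5`.
#' @export
summarize_draws <- function(p, quantities) {
  rows <- lapply(quantities, function(q) {
    x <- draw_quantity(p, q)
    qs <- stats::quantile(x, c(.025, .25, .5, .75, .975), names = FALSE,
                          type = 7)
    data.frame(quantity = q, mean = mean(x), sd = stats::sd(x),
               q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
               q97.5 = qs[5])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Root of the posterior-mean squared replicated error
#'
#' `sqrt(mean(e_star^2))` (or the calibrated analogue), the scalar the
#' summary tables report as the root mean quadratic expected error.
#'
#' @param p A `posterior_draws` with replication draws.
#' @param calibrated Use `e_c_star` instead of `e_star`.
#' @return A number, g/dL.
#' @export
rms_expected_error <- function(p, calibrated = FALSE) {
  q <- if (calibrated) "e_c_star_sq" else "e_star_sq"
  sqrt(mean(draw_quantity(p, q)))
}

#' Posterior probability of an event
#'
#' Fraction of posterior draws satisfying a predicate, with its
#' Monte-Carlo standard error `sqrt(p (1-p) / N)`.
#'
#' @param p A `posterior_draws` object.
#' @param predicate Function taking the function `q(name)` that returns a
#'   draws vector, and returning a logical vector over draws, e.g.
#'   `function(q) q("theta_star") > 1`.
#' @return List with elements `prob`, `mc_se`, `n`.
#' @export
prob_event <- function(p, predicate) {
  ind <- predicate(function(name) draw_quantity(p, name))
  stopifnot(is.logical(ind))
  ph <- mean(ind)
  list(prob = ph, mc_se = sqrt(ph * (1 - ph) / length(ind)),
       n = length(ind))
}

#' Posterior-predictive check of the observed aggregates
#'
#' For each observed statistic (each series' m and s, and the calibrated
#' counterparts when the joint model was fitted), simulates the statistic
#' at the series' sample size from each posterior draw and records the
#' quantile of the observation within that replicated distribution.
#'
#' With `reference = "population"` (default) the replication draws the
#' series parameters of a hypothetical new study from the population laws
#' first; observed aggregates from a well-specified model are then
#' approximately uniform quantiles, and an outlying series lands in the
#' far tail.  With `reference = "series"` the series' own posterior
#' parameters are used; these quantiles concentrate around 0.5 by
#' construction (the parameters were fitted to the very statistic being
#' checked) and are useful for spotting gross misfit only.
#'
#' @param p A `posterior_draws` object.
#' @param d The dataset the model was fitted to (defaults to the one
#'   stored in `p`).
#' @param seed Integer seed.
#' @param reference `"population"` or `"series"` (see above).
#' @param max_draws Subsample size of posterior draws per statistic.
#' @return Data frame with columns `label`, `stat` (m, s, m_c, s_c),
#'   `observed`, `quantile`.
#' @export
posterior_predictive_check <- function(p, d = p$dataset, seed = 1L,
                                       reference = c("population", "series"),
                                       max_draws = 1000L) {
  reference <- match.arg(reference)
  set.seed(seed)
  df <- as.data.frame(d)
  N <- nrow(p$draws)
  idx <- if (N > max_draws) sample.int(N, max_draws) else seq_len(N)
  nd <- length(idx)
  out <- list()
  pq <- function(sim, obs) (sum(sim < obs) + 0.5 * sum(sim == obs)) /
    length(sim)
  joint <- p$model == "joint"
  for (i in seq_len(nrow(df))) {
    if (reference == "series") {
      mu_i <- p$draws[idx, paste0("mu[", i, "]")]
      sigma_i <- p$draws[idx, paste0("sigma[", i, "]")]
      if (joint) {
        delta_i <- p$draws[idx, paste0("delta[", i, "]")]
        theta_i <- p$draws[idx, paste0("theta[", i, "]")]
      }
    } else {
      mu_i <- stats::rnorm(nd, p$draws[idx, "mu_m"],
                           p$draws[idx, "sigma_m"])
      sigma_i <- exp(stats::rnorm(nd, p$draws[idx, "mu_ls"],
                                  p$draws[idx, "sigma_ls"]))
      if (joint) {
        rho_p <- p$draws[idx, "rho_p"]; rho_s <- p$draws[idx, "rho_s"]
        delta_i <- stats::rnorm(
          nd,
          p$draws[idx, "mu_delta"] + rho_p * p$draws[idx, "sigma_delta"] /
            p$draws[idx, "sigma_m"] * (mu_i - p$draws[idx, "mu_m"]),
          p$draws[idx, "sigma_delta"] * sqrt(1 - rho_p^2))
        z_i <- stats::rnorm(
          nd,
          p$draws[idx, "mu_lt"] + rho_s * p$draws[idx, "sigma_lt"] /
            p$draws[idx, "sigma_ls"] * (log(sigma_i) - p$draws[idx, "mu_ls"]),
          p$draws[idx, "sigma_lt"] * sqrt(1 - rho_s^2))
        theta_i <- unconstrained_to_theta(z_i)
      }
    }
    n <- df$n[i]
    m_rep <- stats::rnorm(nd, mu_i, sigma_i / sqrt(n))
    s_rep <- sigma_i * sqrt(stats::rchisq(nd, n - 1) / (n - 1))
    out[[length(out) + 1L]] <- data.frame(
      label = df$label[i], stat = c("m", "s"),
      observed = c(df$m[i], df$s[i]),
      quantile = c(pq(m_rep, df$m[i]), pq(s_rep, df$s[i])))
    if (!is.na(df$n_c[i]) && joint) {
      mu_c <- mu_i + delta_i
      sigma_c <- sigma_i * theta_i
      nc <- df$n_c[i]
      mc_rep <- stats::rnorm(nd, mu_c, sigma_c / sqrt(nc))
      sc_rep <- sigma_c * sqrt(stats::rchisq(nd, nc - 1) / (nc - 1))
      out[[length(out) + 1L]] <- data.frame(
        label = df$label[i], stat = c("m_c", "s_c"),
        observed = c(df$m_c[i], df$s_c[i]),
        quantile = c(pq(mc_rep, df$m_c[i]), pq(sc_rep, df$s_c[i])))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# split-Rhat and effective sample size (split chains, initial monotone
# positive sequence for the autocorrelation sum)
split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    out[[length(out) + 1L]] <- v[seq_len(h)]
    out[[length(out) + 1L]] <- v[h + seq_len(h)]
  }
  out
}

rhat_ess <- function(x, chain) {
  cs <- split_chains(x, chain)
  L <- length(cs[[1]]); Cn <- length(cs)
  means <- vapply(cs, mean, numeric(1))
  vars <- vapply(cs, stats::var, numeric(1))
  W <- mean(vars)
  B <- L * stats::var(means)
  if (!is.finite(W) || W <= 0)
    return(c(rhat = NA_real_, ess = NA_real_))
  var_plus <- (L - 1) / L * W + B / L
  rhat <- sqrt(var_plus / W)
  # chain-averaged autocovariances
  maxlag <- min(L - 1, 400L)
  acov <- matrix(0, maxlag + 1, Cn)
  for (j in seq_len(Cn)) {
    v <- cs[[j]] - means[j]
    a <- stats::acf(v, lag.max = maxlag, type = "covariance",
                    plot = FALSE, demean = FALSE)$acf[, 1, 1]
    acov[, j] <- a
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial positive sequence over lag pairs
  ssum <- 0; t <- 1
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    ssum <- ssum + pair
    t <- t + 2
  }
  ess <- Cn * L / (1 + 2 * ssum)
  c(rhat = rhat, ess = min(ess, Cn * L))
}

#' MCMC convergence diagnostics
#'
#' Split-Rhat, effective sample size and the ratio of the Monte-Carlo
#' standard error to the posterior SD per monitored quantity, with an
#' overall pass flag (`Rhat <= threshold` everywhere it is defined).
#' Constant (degenerate) quantities yield `NA` diagnostics and are flagged
#' but do not crash.
#'
#' @param p A `posterior_draws` object.
#' @param quantities Names to monitor; defaults to the hyperparameters
#'   plus `lp`.
#' @param rhat_threshold Pass threshold (default 1.01).
#' @return Data frame with columns `quantity`, `rhat`, `ess`,
#'   `mcse_sd_ratio`, `flag`, plus attributes `pass` and `n_chains`.
#' @export
convergence_report <- function(p, quantities = NULL, rhat_threshold = 1.01) {
  if (is.null(quantities))
    quantities <- c(hyper_names(if (p$model == "raw") 1L else 2L), "lp")
  single <- max(p$chain) < 2
  rows <- lapply(quantities, function(q) {
    x <- draw_quantity(p, q)
    if (stats::sd(x) == 0 || single) {
      flag <- if (single) "single-chain" else "constant"
      return(data.frame(quantity = q, rhat = NA_real_, ess = NA_real_,
                        mcse_sd_ratio = NA_real_, flag = flag))
    }
    re <- rhat_ess(x, p$chain)
    data.frame(quantity = q, rhat = re["rhat"], ess = re["ess"],
               mcse_sd_ratio = 1 / sqrt(re["ess"]), flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$rhat[is.finite(out$rhat)]
  attr(out, "pass") <- length(ok) > 0 && all(ok <= rhat_threshold)
  attr(out, "n_chains") <- max(p$chain)
  out
}

#' Export posterior (and replication) draws as a data frame
#'
#' One row per draw, one column per quantity, plus `chain` and `lp`;
#' suitable for CSV export and for [impact_over_draws()] round trips.
#'
#' @param p A `posterior_draws` object.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.posterior_draws <- function(p, ...) {
  out <- data.frame(chain = p$chain, lp = p$lp, check.names = FALSE)
  out <- cbind(out, as.data.frame(p$draws, check.names = FALSE))
  if (!is.null(p$replication))
    out <- cbind(out, as.data.frame(p$replication, check.names = FALSE))
  out
}
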