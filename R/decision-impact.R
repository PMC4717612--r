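#' Distribution of the true measured value
#'
#' The clinical-impact integrals weight decision errors by the density of
#' the true value (here tHb).  Only a uniform distribution ships: it covers
#' the clinically useful threshold range without privileging a mode, which
#' is what the impact assessment assumes by default ([4, 12] g/dL).
#'
#' @param lower,upper Support bounds, g/dL (`lower < upper`).
#' @return A `value_distribution` object with fields `kind`, `lower`,
#'   `upper` and functions `g` (density), `G` (CDF).
#' @export
value_distribution <- function(lower = 4, upper = 12) {
  stopifnot(lower < upper)
  structure(list(kind = "uniform", lower = lower, upper = upper,
                 g = function(x) stats::dunif(x, lower, upper),
                 G = function(x) stats::punif(x, lower, upper)),
            class = "value_distribution")
}

#' Impact-assessment configuration
#'
#' @param thresholds Decision thresholds t, g/dL; must lie strictly inside
#'   the value support.  Default 6:10, the clinically useful transfusion
#'   range.
#' @param value_dist A [value_distribution()].
#' @param nodes Number of Gauss-Legendre quadrature nodes (default 201;
#'   the integrand is smooth, so the tables are stable well below that).
#' @return An `impact_config` object.
#' @export
impact_config <- function(thresholds = 6:10,
                          value_dist = value_distribution(),
                          nodes = 201L) {
  if (any(thresholds <= value_dist$lower | thresholds >= value_dist$upper))
    stop("thresholds must lie strictly inside the value support",
         call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 value_dist = value_dist, nodes = as.integer(nodes)),
            class = "impact_config")
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# decomposition of the Jacobi matrix
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1) {
    x <- 0; w <- 2
  } else {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    o <- order(x)
    x <- x[o]; w <- w[o]
  }
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# CDF of the error at q (vector) for one (mu, sigma); sigma = 0
# degenerates to a step at mu
err_cdf <- function(q, mu, sigma) {
  if (sigma > 0) stats::pnorm(q, mu, sigma) else as.numeric(q >= mu)
}

# vectorized positive / true-positive probabilities: smooth normal case by
# Gauss-Legendre quadrature, the sigma = 0 case by the exact closed form
# (quadrature of a step function would not be exact)
conv_probs <- function(mu, sigma, t, vd, nodes) {
  k <- pmax(length(mu), length(sigma))
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  Pp <- TP <- numeric(k)
  pos <- sigma > 0
  dens <- 1 / (vd$upper - vd$lower)
  if (any(pos)) {
    glp <- gauss_legendre(nodes, vd$lower, vd$upper)
    glt <- gauss_legendre(nodes, vd$lower, min(t, vd$upper))
    Pp[pos] <- as.vector(pnorm_outer(t - glp$x, mu[pos], sigma[pos]) %*%
                           glp$w) * dens
    TP[pos] <- as.vector(pnorm_outer(t - glt$x, mu[pos], sigma[pos]) %*%
                           glt$w) * dens
  }
  if (any(!pos)) {
    # reading = x + mu: positive iff x < t - mu
    Pp[!pos] <- vd$G(t - mu[!pos])
    TP[!pos] <- vd$G(pmin(t, t - mu[!pos]))
  }
  list(Pp = Pp, TP = TP)
}

#' Probability of a positive (below-threshold) reading
#'
#' `Pr(reading < t) = integral of F(t - x) g(x) dx` over the value
#' support, where F is the N(mu, sigma^2) error CDF; a "positive" is a
#' transfusion-triggering low reading.
#'
#' @param mu,sigma Error mean and SD, g/dL (`sigma >= 0`; 0 is the
#'   error-free step-function case).  Vectorized over draws.
#' @param t Threshold, g/dL, inside the value support.
#' @param vd A [value_distribution()].
#' @param nodes Quadrature nodes.
#' @return Probability (vector along `mu`/`sigma`).
#' @export
prob_positive <- function(mu, sigma, t, vd = value_distribution(),
                          nodes = 201L) {
  if (t <= vd$lower || t >= vd$upper)
    stop("threshold outside value support", call. = FALSE)
  conv_probs(mu, sigma, t, vd, nodes)$Pp
}

#' Probability of a true positive
#'
#' `Pr(reading < t and value < t)`: the integral above restricted to
#' values x < t, i.e. over `[lower, min(t, upper)]`.  Bounded by
#' `min(prob_positive, G(t))`.
#'
#' @inheritParams prob_positive
#' @return Probability (vector along `mu`/`sigma`).
#' @export
prob_true_positive <- function(mu, sigma, t, vd = value_distribution(),
                               nodes = 201L) {
  if (t <= vd$lower || t >= vd$upper)
    stop("threshold outside value support", call. = FALSE)
  conv_probs(mu, sigma, t, vd, nodes)$TP
}

#' Diagnostic indices at one threshold for one error distribution
#'
#' From the positive probability P+, true-positive probability TP and
#' prevalence pi = G(t): sensitivity `TP/pi`, specificity
#' `(1 - P+ - pi + TP)/(1 - pi)`, predictive values `TP/P+` and
#' `(1 - P+ - pi + TP)/(1 - P+)`, decision-error probability
#' `(P+ - TP) + (pi - TP)` (false positives plus false negatives) and
#' accuracy `1 - err`.  When P+ is 0 or 1 a predictive value is undefined
#' and returned as `NA`.
#'
#' @inheritParams prob_positive
#' @return Named list: `se`, `sp`, `ppv`, `npv`, `acc`, `err` (vectors
#'   along `mu`/`sigma`).
#' @export
diagnostic_indices <- function(mu, sigma, t, vd = value_distribution(),
                               nodes = 201L) {
  pi_t <- vd$G(t)
  if (pi_t <= 0 || pi_t >= 1)
    stop("threshold must have 0 < G(t) < 1", call. = FALSE)
  cp <- conv_probs(mu, sigma, t, vd, nodes)
  Pp <- cp$Pp; TP <- cp$TP
  TN <- 1 - Pp - pi_t + TP
  err <- (Pp - TP) + (pi_t - TP)
  list(se = TP / pi_t,
       sp = TN / (1 - pi_t),
       ppv = ifelse(Pp > 0, TP / Pp, NA_real_),
       npv = ifelse(Pp < 1, TN / (1 - Pp), NA_real_),
       acc = 1 - err,
       err = err)
}

#' Diagnostic impact propagated over posterior draws
#'
#' Computes the six indices per posterior replication draw (`mu_star`,
#' `sigma_star`, or the calibrated pair) at each configured threshold,
#' then summarizes each index over draws by mean, SD and the five standard
#' quantiles — the per-draw-then-summarize order is what produces honest
#' uncertainty columns.
#'
#' @param p A `posterior_draws` object with replication draws.
#' @param which `"raw"` (uses `mu_star`, `sigma_star`) or `"calibrated"`
#'   (`mu_c_star`, `sigma_c_star`; joint fit only).
#' @param cfg An [impact_config()].
#' @return An `impact_table` data frame with columns `index`, `threshold`,
#'   `mean`, `sd`, `q2.5`, `q25`, `q50`, `q75`, `q97.5`.
#' @export
impact_over_draws <- function(p, which = c("raw", "calibrated"),
                              cfg = impact_config()) {
  which <- match.arg(which)
  if (is.null(p$replication))
    stop("replication draws missing; run sample_replication() first",
         call. = FALSE)
  if (which == "calibrated" && !("mu_c_star" %in% colnames(p$replication)))
    stop("calibrated replication draws require a joint fit", call. = FALSE)
  mu <- p$replication[, if (which == "raw") "mu_star" else "mu_c_star"]
  sigma <- p$replication[, if (which == "raw") "sigma_star" else
    "sigma_c_star"]
  impact_table_from_pairs(mu, sigma, cfg)
}

#' Impact table from explicit (mu, sigma) draw pairs
#'
#' Workhorse behind [impact_over_draws()], usable directly on draws read
#' back from a CSV export.
#'
#' @param mu,sigma Vectors of error-distribution parameters, one per draw.
#' @param cfg An [impact_config()].
#' @return An `impact_table` data frame (see [impact_over_draws()]).
#' @export
impact_table_from_pairs <- function(mu, sigma, cfg = impact_config()) {
  vd <- cfg$value_dist
  rows <- list()
  for (t in cfg$thresholds) {
    cp <- conv_probs(mu, sigma, t, vd, cfg$nodes)
    Pp <- cp$Pp; TP <- cp$TP
    pi_t <- vd$G(t)
    TN <- 1 - Pp - pi_t + TP
    err <- (Pp - TP) + (pi_t - TP)
    idx <- list(Se = TP / pi_t, Sp = TN / (1 - pi_t),
                PPV = ifelse(Pp > 0, TP / Pp, NA_real_),
                NPV = ifelse(Pp < 1, TN / (1 - Pp), NA_real_),
                Acc = 1 - err, Err = err)
    for (nm in names(idx)) {
      x <- idx[[nm]]
      qs <- stats::quantile(x, c(.025, .25, .5, .75, .975), names = FALSE,
                            na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        index = nm, threshold = t, mean = mean(x, na.rm = TRUE),
        sd = stats::sd(x, na.rm = TRUE), q2.5 = qs[1], q25 = qs[2],
        q50 = qs[3], q75 = qs[4], q97.5 = qs[5])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("impact_table", class(out))
  out
}

# matrix of F(q_j | mu_i, sigma_i): rows draws, cols quadrature nodes
pnorm_outer <- function(q, mu, sigma) {
  n <- length(mu); k <- length(q)
  Q <- matrix(q, n, k, byrow = TRUE)
  M <- matrix(mu, n, k)
  S <- matrix(sigma, n, k)
  ifelse(S > 0, stats::pnorm(Q, M, pmax(S, .Machine$double.xmin)),
         (Q >= M) + 0)
}

#' Write an impact table to CSV and markdown
#'
#' @param x An `impact_table`.
#' @param csv_path,md_path Output paths (either may be `NULL` to skip).
#' @param digits Decimal places in the markdown rendering.
#' @return `x`, invisibly.
#' @export
write_impact_table <- function(x, csv_path = NULL, md_path = NULL,
                               digits = 3) {
  if (!is.null(csv_path))
    utils::write.csv(x, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    num <- function(v) formatC(v, digits = digits, format = "f")
    lines <- c("| Index | Threshold | Mean | SD | 2.5% | 25% | 50% | 75% | 97.5% |",
               "|---|---|---|---|---|---|---|---|---|",
               sprintf("| %s | %g | %s | %s | %s | %s | %s | %s | %s |",
                       x$index, x$threshold, num(x$mean), num(x$sd),
                       num(x$q2.5), num(x$q25), num(x$q50), num(x$q75),
                       num(x$q97.5)))
    writeLines(lines, md_path)
  }
  invisible(x)
}
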