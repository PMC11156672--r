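#' Genetic risk score from a first-stage fit
#'
#' The stage-one linear predictor \eqn{s_i = \sum_j \hat b_j G_{ij}} on the
#' \eqn{\theta/\sigma} scale. Thresholds do not enter: the score is the
#' genetically predicted latent exposure up to location and scale.
#'
#' @param fit An [fit_ordinal_iv()] result.
#' @param G Dosage matrix whose columns align with `fit$b`.
#' @return Numeric score vector, one value per row of `G`.
#' @export
risk_score <- function(fit, G) {
  stopifnot(inherits(fit, "ordinal_iv_fit"))
  G <- as_dosage_numeric(G, length(fit$b))
  drop(G %*% fit$b)
}

#' Two-stage causal estimate on the sigma-scaled latent axis
#'
#' Stage one fits the latent-threshold model of the exposure category on
#' the instruments ([fit_ordinal_iv()]); stage two regresses the outcome on
#' the fitted genetic score (with intercept) by least squares. The slope
#' estimates \eqn{\sigma\beta}: the causal effect of the latent exposure on
#' the outcome times the unidentified latent scale \eqn{\sigma}. Its sign
#' and significance are those of the causal effect itself.
#'
#' @param G Dosage matrix (individuals x instruments).
#' @param X Integer exposure categories `1..K`.
#' @param Y Continuous outcome vector.
#' @param start Optional stage-one starting values (see [fit_ordinal_iv()]).
#' @param min_score_sd Scores with standard deviation below this are
#'   treated as a degenerate (null/weak) first stage and raise an error.
#' @param reltol Stage-one optimizer tolerance (see [fit_ordinal_iv()]).
#' @return A list with `beta_hat` (the \eqn{\sigma\beta} estimate),
#'   `fit` (stage one), `score`, and `n_used`.
#' @examples
#' d <- simulate_dataset(table1_scenario("C", seed = 1))
#' two_stage_estimate(d$G, d$X, d$Y)$beta_hat  # targets sigma*beta = 2.25
#' @export
two_stage_estimate <- function(G, X, Y, start = NULL, min_score_sd = 1e-8,
                               reltol = 1e-12) {
  G <- as_dosage_numeric(G)
  keep <- stats::complete.cases(G) & !is.na(X) & !is.na(Y)
  G <- G[keep, , drop = FALSE]; X <- X[keep]; Y <- Y[keep]
  fit <- fit_ordinal_iv(G, X, start = start, vcov = FALSE, reltol = reltol)
  s <- risk_score(fit, G)
  if (stats::sd(s) < min_score_sd)
    stop("degenerate genetic score (all instrument effects ~0): ",
         "the first stage carries no signal, so the causal effect is ",
         "not estimable from these instruments")
  beta_hat <- stats::cov(Y, s) / stats::var(s)
  list(beta_hat = beta_hat, fit = fit, score = s, n_used = length(Y))
}

#' Bootstrap confidence intervals for the two-stage estimate
#'
#' Resamples individuals with replacement, refitting both stages per
#' resample, and reports three interval types at the requested level:
#' normal (\eqn{\hat\beta \pm z \cdot \mathrm{sd}(\hat\beta^*)}), basic
#' (reflected quantiles \eqn{2\hat\beta - q^*}), and percentile (raw
#' quantiles of the replicate estimates). Resamples in which the exposure
#' collapses to a single category are redrawn; a warning is issued if more
#' than 5% of draws had to be redrawn.
#'
#' @inheritParams two_stage_estimate
#' @param B Number of bootstrap replicates (at least 100 for reported
#'   intervals; smaller values are allowed for smoke tests).
#' @param level Confidence level (default 0.95).
#' @param seed Integer RNG seed for the resampling.
#' @return An object of class `mr_causal_estimate`: `beta_hat`,
#'   `boot_draws`, `ci_normal`, `ci_basic`, `ci_percentile`, `level`,
#'   `p_value` (derived from the basic interval via [p_from_ci()]), `B`,
#'   `seed`, `n_redrawn`, `n_used`.
#' @export
bootstrap_cis <- function(G, X, Y, B = 500L, level = 0.95, seed = 1L) {
  stopifnot(B >= 1, level > 0, level < 1)
  G <- as_dosage_numeric(G)
  keep <- stats::complete.cases(G) & !is.na(X) & !is.na(Y)
  G <- G[keep, , drop = FALSE]; X <- as.integer(X[keep]); Y <- Y[keep]
  n <- length(Y)
  full <- two_stage_estimate(G, X, Y)
  beta_hat <- full$beta_hat
  warm <- c(full$fit$b, full$fit$a)

  set.seed(seed)
  draws <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(X[idx])) >= 2L) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * B)
        stop("exposure collapses to one category in nearly all resamples")
    }
    st <- if (max(X[idx]) == length(warm) - length(full$fit$b) + 1L) warm else NULL
    draws[b] <- two_stage_estimate(G[idx, , drop = FALSE], X[idx], Y[idx],
                                   start = st, reltol = 1e-8)$beta_hat
  }
  if (n_redrawn > 0.05 * B)
    warning(sprintf("%d degenerate resample(s) redrawn (>5%% of B = %d)",
                    n_redrawn, B))

  alpha <- (1 - level) / 2
  z <- stats::qnorm(1 - alpha)
  q <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
  est <- list(beta_hat = beta_hat, boot_draws = draws,
              ci_normal = c(beta_hat - z * stats::sd(draws),
                            beta_hat + z * stats::sd(draws)),
              ci_basic = c(2 * beta_hat - q[2L], 2 * beta_hat - q[1L]),
              ci_percentile = q, level = level, B = as.integer(B),
              seed = as.integer(seed), n_redrawn = n_redrawn,
              n_used = n, fit = full$fit)
  est$p_value <- p_from_ci(beta_hat, est$ci_basic, level)
  class(est) <- "mr_causal_estimate"
  est
}

#' @export
print.mr_causal_estimate <- function(x, ...) {
  f <- function(ci) sprintf("(%.3f, %.3f)", ci[1L], ci[2L])
  cat(sprintf("Two-stage causal estimate (sigma-scaled): %.3f\n", x$beta_hat))
  cat(sprintf("  %d%% CI  normal %s  basic %s  percentile %s\n",
              round(100 * x$level), f(x$ci_normal), f(x$ci_basic),
              f(x$ci_percentile)))
  cat(sprintf("  p (from basic CI) = %.4g   [B = %d bootstrap replicates]\n",
              x$p_value, x$B))
  invisible(x)
}

#' Two-sided p-value derived from a confidence interval
#'
#' Treats the interval as a symmetric normal-theory interval: the implied
#' standard error is `(upper - lower) / (2 * z)` with
#' `z = qnorm((1 + level)/2)`, and the p-value is
#' `2 * (1 - pnorm(|beta_hat| / SE))`. This is the standard back-derivation
#' of a p-value from a reported estimate and CI.
#'
#' @param beta_hat Point estimate.
#' @param ci Length-2 interval, lower then upper.
#' @param level Confidence level of the interval.
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' p_from_ci(1.883, c(0.182, 3.512))  # ~0.027
#' @export
p_from_ci <- function(beta_hat, ci, level = 0.95) {
  stopifnot(length(ci) == 2L, level > 0, level < 1)
  if (!(ci[2L] > ci[1L])) stop("CI must have lower < upper")
  z <- stats::qnorm((1 + level) / 2)
  se <- (ci[2L] - ci[1L]) / (2 * z)
  2 * stats::pnorm(-abs(beta_hat / se))
}

#' Rescale a sigma-scaled estimate to the natural exposure scale
#'
#' The two-stage estimate targets \eqn{\sigma\beta} where \eqn{\sigma^2}
#' is the latent-exposure variance not attributable to genotype. If the
#' heritability of the latent exposure, \eqn{h^2 = V_G / (V_G + \sigma^2)},
#' and the genetic variance \eqn{V_G} are known from an external source,
#' then \eqn{\hat\sigma^2 = V_G (1 - h^2) / h^2} and the causal effect on
#' the natural latent scale is \eqn{\hat\beta / \hat\sigma}. First-stage
#' slopes rescale in the opposite direction, \eqn{\hat\theta = \hat b
#' \hat\sigma}.
#'
#' @param beta_hat_scaled Estimate on the \eqn{\sigma\beta} scale.
#' @param h2 Heritability of the latent exposure, in (0, 1).
#' @param V_G Latent-exposure variance attributed to genotype (positive).
#' @param b Optional scaled first-stage slopes to rescale to \eqn{\theta}.
#' @return A list with `beta` (natural-scale causal effect), `sigma`,
#'   `sigma2`, and `theta` (if `b` supplied).
#' @examples
#' rescale_by_heritability(2.25, h2 = 0.5, V_G = 2.25)$beta  # 1.5
#' @export
rescale_by_heritability <- function(beta_hat_scaled, h2, V_G, b = NULL) {
  if (!(h2 > 0 && h2 < 1)) stop("h2 must lie strictly in (0, 1)")
  if (V_G <= 0) stop("V_G must be positive")
  sigma2 <- V_G * (1 - h2) / h2
  sigma <- sqrt(sigma2)
  out <- list(beta = beta_hat_scaled / sigma, sigma = sigma, sigma2 = sigma2)
  if (!is.null(b)) out$theta <- b * sigma
  out
}

#' Simulation study driver over the preset scenario groups
#'
#' Runs the full two-stage pipeline on data simulated from
#' [table1_scenario()] configurations, in one of two modes.
#' `"single_dataset_bootstrap"` draws one dataset per group and reports the
#' point estimate with all three bootstrap intervals — the layout of a
#' one-dataset-per-group study table. `"replicate_datasets"` draws `reps`
#' independent datasets per group and reports the mean and SD of the
#' estimate; when `B > 0` it also computes a basic bootstrap interval per
#' replicate and reports empirical coverage of the true \eqn{\sigma\beta}.
#'
#' @param groups Character vector of scenario labels (subset of `"A".."J"`).
#' @param mode `"replicate_datasets"` or `"single_dataset_bootstrap"`.
#' @param reps Replicate datasets per group (replicate mode).
#' @param B Bootstrap replicates; in replicate mode `B = 0` skips interval
#'   computation (fast means-only study).
#' @param level Confidence level.
#' @param seed Integer seed; per-group/replicate seeds are derived from it.
#' @param strength First-stage strength passed to [table1_scenario()].
#' @return A data frame keyed by group. Replicate mode: columns `group`,
#'   `n_iv`, `beta`, `sigma_beta` (true target), `mean_beta_hat`,
#'   `sd_beta_hat`, `coverage` (NA when `B = 0`), `reps`. Single-dataset
#'   mode: `group`, `n_iv`, `beta`, `beta_hat`, the six CI bounds and `p`.
#' @export
run_simulation_study <- function(groups = LETTERS[1:10],
                                 mode = c("replicate_datasets",
                                          "single_dataset_bootstrap"),
                                 reps = 500L, B = 500L, level = 0.95,
                                 seed = 1L, strength = "strong") {
  mode <- match.arg(mode)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    cfg <- table1_scenario(g, strength = strength)
    target <- cfg$beta * sigma_of(cfg)
    if (mode == "single_dataset_bootstrap") {
      d <- simulate_dataset(cfg, seed = seed + 1000L * gi)
      est <- bootstrap_cis(d$G, d$X, d$Y, B = B, level = level,
                           seed = seed + 1000L * gi + 1L)
      rows[[gi]] <- data.frame(
        group = g, n_iv = length(cfg$mafs), beta = cfg$beta,
        beta_hat = est$beta_hat,
        normal_lo = est$ci_normal[1L], normal_hi = est$ci_normal[2L],
        basic_lo = est$ci_basic[1L], basic_hi = est$ci_basic[2L],
        pct_lo = est$ci_percentile[1L], pct_hi = est$ci_percentile[2L],
        p = est$p_value)
    } else {
      bh <- numeric(reps)
      cover <- if (B > 0) logical(reps) else NA
      for (r in seq_len(reps)) {
        rs <- seed + 100000L * gi + r
        d <- simulate_dataset(cfg, seed = rs)
        if (B > 0) {
          est <- bootstrap_cis(d$G, d$X, d$Y, B = B, level = level,
                               seed = rs + 50000L)
          bh[r] <- est$beta_hat
          cover[r] <- est$ci_basic[1L] <= target && target <= est$ci_basic[2L]
        } else {
          bh[r] <- two_stage_estimate(d$G, d$X, d$Y)$beta_hat
        }
      }
      rows[[gi]] <- data.frame(
        group = g, n_iv = length(cfg$mafs), beta = cfg$beta,
        sigma_beta = target, mean_beta_hat = mean(bh),
        sd_beta_hat = stats::sd(bh),
        coverage = if (B > 0) mean(cover) else NA_real_,
        reps = as.integer(reps))
    }
  }
  do.call(rbind, rows)
}
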