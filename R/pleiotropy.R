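#' Per-instrument exposure and outcome effects for MR-Egger
#'
#' For each instrument separately: the exposure effect is the scaled slope
#' \eqn{\theta_j/\sigma} from a single-instrument latent-threshold fit
#' (with SE from its observed information), and the outcome effect is the
#' least-squares slope of the outcome on that instrument alone (with
#' intercept). Instruments whose single-instrument fit fails are excluded
#' with a warning.
#'
#' @inheritParams two_stage_estimate
#' @return A data frame with one row per instrument: `id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`.
#' @export
instrument_effects <- function(G, X, Y) {
  G <- as_dosage_numeric(G)
  if (ncol(G) < 3L) stop("MR-Egger needs at least 3 instruments")
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("iv", seq_len(ncol(G)))
  rows <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(X) & !is.na(Y)
    row <- tryCatch({
      fit <- fit_ordinal_iv(g[ok], X[ok], vcov = TRUE)
      se_b <- if (!is.null(fit$vcov)) sqrt(fit$vcov[1L, 1L]) else NA_real_
      co <- stats::coef(summary(stats::lm(Y[ok] ~ g[ok])))
      data.frame(id = ids[j], beta_exp = unname(fit$b[1L]), se_exp = se_b,
                 beta_out = co[2L, 1L], se_out = co[2L, 2L])
    }, error = function(e) {
      warning("instrument '", ids[j], "' excluded: ", conditionMessage(e))
      NULL
    })
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 3L)
    stop("fewer than 3 instruments with usable effect estimates")
  rownames(out) <- NULL
  out
}

#' P-value for an Egger intercept from its estimate and standard error
#'
#' Two-sided test of a zero Egger intercept using a t reference with
#' `J - 2` residual degrees of freedom, `J` being the number of
#' instruments. Useful for re-deriving the pleiotropy p-value from a
#' reported intercept and SE.
#'
#' @param intercept Egger intercept estimate.
#' @param se Its standard error (positive).
#' @param J Number of instruments (at least 3).
#' @return Two-sided p-value.
#' @examples
#' egger_intercept_p(1.203, 1.221, J = 7)  # ~0.370
#' @export
egger_intercept_p <- function(intercept, se, J) {
  stopifnot(J >= 3, se > 0)
  2 * stats::pt(-abs(intercept / se), df = J - 2)
}

#' MR-Egger regression and intercept test for horizontal pleiotropy
#'
#' Regresses per-instrument outcome effects on exposure effects by weighted
#' least squares (weights `1/se_out^2`, or unweighted) with a free
#' intercept. Under valid instruments the fit passes through the origin;
#' a nonzero intercept indicates directional horizontal pleiotropy. Each
#' instrument is first oriented so its exposure effect is nonnegative (the
#' standard Egger convention; the intercept is not invariant to instrument
#' orientation). The intercept p-value uses a t reference with `J - 2`
#' residual degrees of freedom.
#'
#' @param beta_exp Per-instrument exposure effects (scaled slopes).
#' @param beta_out Per-instrument outcome effects.
#' @param se_out Standard errors of `beta_out` (used as weights).
#' @param weighted Use inverse-variance weights (default) or OLS.
#' @return An object of class `mr_egger`: `intercept`, `se_intercept`,
#'   `p_intercept`, `slope`, `se_slope`, `df`, `J`.
#' @examples
#' eff <- data.frame(beta_exp = c(0.2, 0.3, 0.5, 0.4),
#'                   beta_out = c(0.5, 0.7, 1.2, 1.0),
#'                   se_out = rep(0.1, 4))
#' egger_test(eff$beta_exp, eff$beta_out, eff$se_out)
#' @export
egger_test <- function(beta_exp, beta_out, se_out, weighted = TRUE) {
  J <- length(beta_exp)
  stopifnot(length(beta_out) == J, length(se_out) == J)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(beta_exp)
  flip[flip == 0] <- 1
  bx <- beta_exp * flip
  by <- beta_out * flip
  w <- if (weighted) 1 / se_out^2 else rep(1, J)
  fit <- stats::lm(by ~ bx, weights = w)
  co <- stats::coef(summary(fit))
  res <- list(intercept = co[1L, 1L], se_intercept = co[1L, 2L],
              p_intercept = egger_intercept_p(co[1L, 1L], co[1L, 2L], J),
              slope = co[2L, 1L], se_slope = co[2L, 2L],
              df = J - 2L, J = J)
  class(res) <- "mr_egger"
  res
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger pleiotropy test\n")
  cat(sprintf("  intercept %.3f (SE %.3f), t(%d), p = %.3f\n",
              x$intercept, x$se_intercept, x$df, x$p_intercept))
  cat(sprintf("  slope %.3f (SE %.3f), J = %d instruments\n",
              x$slope, x$se_slope, x$J))
  invisible(x)
}
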