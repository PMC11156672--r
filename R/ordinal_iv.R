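#' Category probabilities under the scaled latent-threshold model
#'
#' Computes \eqn{P(X = k \mid G_i) = \Phi(a_k - b \cdot G_i) -
#' \Phi(a_{k-1} - b \cdot G_i)} with \eqn{a_0 = -\infty}, \eqn{a_K =
#' +\infty}, for any number of ordered categories \eqn{K \ge 2}. Here
#' `b` are the instrument slopes on the \eqn{\theta/\sigma} scale and `a`
#' the scaled thresholds \eqn{(t_k - \theta_0)/\sigma}.
#'
#' @param b Scaled instrument slopes, one per column of `G`.
#' @param a Strictly increasing scaled thresholds (length `K - 1`).
#' @param G Numeric dosage matrix (individuals by instruments) or a vector
#'   for a single instrument.
#' @return An `n x K` matrix of probabilities; each row sums to 1.
#' @examples
#' category_probabilities(b = 0.5, a = c(-0.5, 0.5), G = matrix(2))
#' @export
category_probabilities <- function(b, a, G) {
  G <- as_dosage_numeric(G, length(b))
  a <- as.numeric(a)
  if (length(a) < 1L || is.unsorted(a, strictly = TRUE))
    stop("scaled thresholds 'a' must be strictly increasing")
  ordprobit_probs(as.numeric(b), a, G, length(a) + 1L)
}

#' Log-likelihood of the scaled latent-threshold model
#'
#' Sum over individuals of the log category probability of the observed
#' exposure, \eqn{\sum_i \log P(X_i = x_i \mid G_i)}. Probabilities are
#' floored at 1e-12 inside the log so the value is finite even for
#' parameter values that give an observation essentially zero probability.
#'
#' @inheritParams category_probabilities
#' @param X Integer exposure categories in `1..K` where
#'   `K = length(a) + 1`.
#' @return The log-likelihood (a scalar, at most 0).
#' @export
ordinal_loglik <- function(b, a, G, X) {
  G <- as_dosage_numeric(G, length(b))
  a <- as.numeric(a)
  if (is.unsorted(a, strictly = TRUE))
    stop("scaled thresholds 'a' must be strictly increasing")
  K <- length(a) + 1L
  X <- as.integer(X)
  if (any(is.na(X)) || any(X < 1L | X > K))
    stop("exposure categories must be integers in 1..", K)
  if (length(X) != nrow(G)) stop("length(X) must match nrow(G)")
  -ordprobit_nll_gr(as.numeric(b), a, G, X, K, numeric(0))$nll
}

# Collapse identical (G-row, X) patterns to unique rows with counts; the
# weighted likelihood is exactly the individual-level one. Dosages take 3
# values, so a base-3 key indexes patterns uniquely (exact in doubles for
# the J here).
aggregate_patterns <- function(G, X, K) {
  J <- ncol(G)
  if (J > 25L) return(list(G = G, X = X, w = numeric(0)))
  key <- drop(G %*% 3^(seq_len(J) - 1)) * K + (X - 1L)
  first <- !duplicated(key)
  if (sum(first) > 0.9 * length(key))
    return(list(G = G, X = X, w = numeric(0)))
  m <- match(key, key[first])
  list(G = G[first, , drop = FALSE], X = X[first],
       w = as.numeric(tabulate(m, sum(first))))
}

# coerce vector/matrix dosages to a numeric matrix with J columns
as_dosage_numeric <- function(G, J = NULL) {
  if (is.null(dim(G))) G <- matrix(as.numeric(G), ncol = if (is.null(J)) 1L else J)
  storage.mode(G) <- "double"
  if (!is.null(J) && ncol(G) != J)
    stop("number of instrument columns (", ncol(G),
         ") does not match number of slopes (", J, ")")
  G
}

# par = (b, a1, log(a2-a1), ...): unconstrained, thresholds always ordered
par_to_ba <- function(par, J, K) {
  b <- par[seq_len(J)]
  raw <- par[J + seq_len(K - 1L)]
  a <- if (K == 2L) raw else cumsum(c(raw[1L], exp(raw[-1L])))
  list(b = b, a = a)
}

ba_to_par <- function(b, a) {
  K <- length(a) + 1L
  raw <- if (K == 2L) a else c(a[1L], log(diff(a)))
  c(b, raw)
}

#' Fit the latent-threshold first-stage model by maximum likelihood
#'
#' Maximizes the ordered-probit log-likelihood of the exposure category
#' given instrument dosages, yielding the scaled instrument effects
#' \eqn{b = \theta/\sigma} and scaled thresholds \eqn{a_k = (t_k -
#' \theta_0)/\sigma}. Only these scaled quantities are identified from
#' `(G, X)`; see [rescale_by_heritability()] for recovering the natural
#' scale when the exposure heritability is known.
#'
#' Rows with any missing dosage or missing exposure are dropped (complete
#' cases). Thresholds are kept ordered by optimizing
#' `(a_1, log(a_2 - a_1), ...)` unconstrained with BFGS and an analytic
#' gradient; starting values are `b = 0` and `a` from probit-transformed
#' cumulative category proportions.
#'
#' @param G Dosage matrix (individuals x instruments), values 0/1/2 or
#'   `NA`; a vector is treated as a single instrument.
#' @param X Integer exposure categories; at least two distinct categories
#'   must be present. Categories are used as given (they must be `1..K`).
#' @param start Optional starting parameter vector `c(b, a)` (slopes then
#'   raw thresholds), e.g. from a previous fit on similar data.
#' @param vcov Logical; compute the parameter covariance from the inverse
#'   observed information at the optimum (numerically differentiated
#'   analytic gradient). Skipping it speeds up bootstrap refits.
#' @param reltol Relative convergence tolerance of the BFGS optimizer.
#'   The default gives parameter accuracy well beyond reporting precision;
#'   bootstrap refits use a looser value since quantiles of the replicate
#'   estimates are insensitive at that scale.
#' @return An object of class `ordinal_iv_fit` with elements `b`, `a`,
#'   `loglik` (unfloored, at the optimum), `n_used`, `converged`, `vcov`
#'   (rows/cols ordered as `b` then `a`; `NULL` if not requested), `K`.
#' @examples
#' d <- simulate_dataset(table1_scenario("C", seed = 1))
#' fit <- fit_ordinal_iv(d$G, d$X)
#' fit$b   # estimates of theta/sigma
#' @export
fit_ordinal_iv <- function(G, X, start = NULL, vcov = TRUE,
                           reltol = 1e-12) {
  G <- as_dosage_numeric(G)
  X <- as.integer(X)
  if (length(X) != nrow(G)) stop("length(X) must match nrow(G)")
  keep <- stats::complete.cases(G) & !is.na(X)
  G <- G[keep, , drop = FALSE]
  X <- X[keep]
  n <- nrow(G); J <- ncol(G)
  if (n == 0L) stop("no complete cases")
  if (any(X < 1L)) stop("exposure categories must be coded 1..K")
  K <- max(X)
  if (length(unique(X)) < 2L)
    stop("exposure is degenerate: only one category observed")
  agg <- aggregate_patterns(G, X, K)
  Ga <- agg$G; Xa <- agg$X; w <- agg$w

  if (is.null(start)) {
    cum <- cumsum(tabulate(X, K))[seq_len(K - 1L)] / n
    cum <- pmin(pmax(cum, 1 / (n + 1)), n / (n + 1))
    a0 <- stats::qnorm(cum)
    a0 <- cummax(a0 + seq_len(K - 1L) * 1e-8)  # guard exact ties
    par0 <- ba_to_par(rep(0, J), a0)
  } else {
    stopifnot(length(start) == J + K - 1L)
    par0 <- ba_to_par(start[seq_len(J)], start[J + seq_len(K - 1L)])
  }

  # Newton iterations on the concave likelihood: analytic Hessian, damped
  # steps that respect the threshold ordering; falls back to BFGS on the
  # order-free reparameterization if a step or solve ever fails.
  nt <- newton_ordprobit(par_to_ba(par0, J, K), Ga, Xa, K, w,
                         tol = max(reltol, 1e-10))
  if (nt$converged) {
    p <- list(b = nt$b, a = nt$a)
    opt_nll <- nt$nll
    gnorm <- nt$gnorm
    converged <- TRUE
    H <- nt$hess
  } else {
    fn <- function(par) {
      pp <- par_to_ba(par, J, K)
      ordprobit_nll_gr(pp$b, pp$a, Ga, Xa, K, w)$nll
    }
    gr <- function(par) {
      pp <- par_to_ba(par, J, K)
      r <- ordprobit_nll_gr(pp$b, pp$a, Ga, Xa, K, w)
      ga <- r$ga
      graw <- if (K == 2L) ga
      else {
        # chain rule through a = cumsum(c(raw1, exp(raw_j)))
        csum <- rev(cumsum(rev(ga)))
        c(csum[1L], exp(par[J + 2:(K - 1L)]) * csum[-1L])
      }
      c(r$gb, graw)
    }
    opt <- stats::optim(par0, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = reltol))
    p <- par_to_ba(opt$par, J, K)
    opt_nll <- opt$value
    gnorm <- sqrt(sum(gr(opt$par)^2))
    converged <- opt$convergence == 0L && is.finite(gnorm)
    H <- ordprobit_nll_gr_hess(p$b, p$a, Ga, Xa, K, w)$hess
  }

  V <- NULL
  if (vcov) {
    V <- tryCatch(solve((H + t(H)) / 2), error = function(e) {
      warning("observed information is singular; vcov unavailable")
      NULL
    })
  }
  nm <- c(if (!is.null(colnames(G))) colnames(G) else paste0("b", seq_len(J)),
          paste0("a", seq_len(K - 1L)))
  if (!is.null(V)) dimnames(V) <- list(nm, nm)
  structure(list(b = stats::setNames(p$b, nm[seq_len(J)]),
                 a = stats::setNames(p$a, nm[J + seq_len(K - 1L)]),
                 loglik = -opt_nll, n_used = n, converged = converged,
                 grad_norm = gnorm, vcov = V, K = K),
            class = "ordinal_iv_fit")
}

# Damped Newton on the (b, a) parameterization. Steps that break the
# threshold ordering or fail to decrease the objective are halved; the
# caller falls back to BFGS when this reports non-convergence.
newton_ordprobit <- function(start, G, X, K, w, tol = 1e-10,
                             maxit = 50L) {
  b <- start$b; a <- start$a
  J <- length(b)
  r <- ordprobit_nll_gr_hess(b, a, G, X, K, w)
  for (it in seq_len(maxit)) {
    step <- tryCatch(solve(r$hess, r$grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(converged = FALSE))
    lam <- 1
    repeat {
      b2 <- b - lam * step[seq_len(J)]
      a2 <- a - lam * step[J + seq_len(K - 1L)]
      ok <- K == 2L || !is.unsorted(a2, strictly = TRUE)
      if (ok) {
        r2 <- ordprobit_nll_gr_hess(b2, a2, G, X, K, w)
        if (r2$nll <= r$nll + 1e-12) break
      }
      lam <- lam / 2
      if (lam < 1e-10) return(list(converged = FALSE))
    }
    drop_nll <- r$nll - r2$nll
    b <- b2; a <- a2; r <- r2
    gnorm <- sqrt(sum(r$grad^2))
    if (gnorm < 1e-6 || drop_nll < tol * (abs(r$nll) + tol))
      return(list(converged = TRUE, b = b, a = a, nll = r$nll,
                  gnorm = gnorm, hess = r$hess))
  }
  list(converged = FALSE)
}

# central-difference Jacobian of a vector-valued function
numeric_jacobian <- function(f, x, eps = 1e-5) {
  m <- length(f(x)); J <- matrix(0, m, length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.ordinal_iv_fit <- function(x, ...) {
  cat(sprintf(
    "Latent-threshold first-stage fit: %d obs, %d instruments, K = %d\n",
    x$n_used, length(x$b), x$K))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n", x$loglik,
              x$converged))
  est <- c(x$b, x$a)
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, length(est))
  print(data.frame(estimate = est, se = se))
  invisible(x)
}

#' Summarize a first-stage fit as a parameter table
#'
#' @param object An `ordinal_iv_fit`.
#' @param ... Unused.
#' @return A data frame with columns `parameter`, `estimate`, `se`.
#' @export
summary.ordinal_iv_fit <- function(object, ...) {
  est <- c(object$b, object$a)
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov))
        else rep(NA_real_, length(est))
  data.frame(parameter = names(est), estimate = unname(est), se = unname(se))
}

#' Probit-inversion diagnostic for a single instrument
#'
#' The model implies \eqn{\Phi^{-1}(P(X = 1 \mid G = g)) = a_1 - g\,
#' \theta/\sigma}: the probit of the lowest-category probability is linear
#' in the dosage with slope \eqn{-\theta/\sigma}. This diagnostic computes
#' the empirical lowest-category frequency at each distinct dosage value,
#' probit-transforms it, and fits a least-squares line — a quick
#' model-free check on the sign and rough size of the scaled effect.
#'
#' @param g Dosage vector for a single instrument.
#' @param X Integer exposure categories.
#' @return A list with `intercept`, `slope` (estimates \eqn{-\theta/\sigma}),
#'   and `excluded` (dosage values dropped because the empirical
#'   probability was 0 or 1).
#' @export
probit_inversion_diagnostic <- function(g, X) {
  keep <- !is.na(g) & !is.na(X)
  g <- g[keep]; X <- as.integer(X[keep])
  lv <- sort(unique(g))
  if (length(lv) < 2L)
    stop("instrument must take at least 2 distinct dosage values")
  p1 <- vapply(lv, function(v) mean(X[g == v] == 1L), numeric(1))
  bad <- p1 <= 0 | p1 >= 1
  if (any(bad))
    warning("dosage value(s) ", paste(lv[bad], collapse = ", "),
            " excluded: empirical lowest-category probability is 0 or 1")
  if (sum(!bad) < 2L)
    stop("fewer than 2 usable dosage values after exclusions")
  z <- stats::qnorm(p1[!bad])
  co <- stats::coef(stats::lm(z ~ lv[!bad]))
  list(intercept = unname(co[1L]), slope = unname(co[2L]),
       excluded = lv[bad])
}
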