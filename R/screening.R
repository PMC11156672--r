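#' Per-variant association scan
#'
#' Fits, for each variant, `trait ~ dosage + covariates` — by ordinary
#' least squares for continuous traits or logistic regression for binary
#' traits — and reports the dosage coefficient with its Wald test. Rows
#' with missing trait, dosage, or covariates are dropped per variant
#' (complete cases). Constant dosage columns produce a record with `NA`
#' estimate and `p = NA` rather than being silently dropped.
#'
#' @param G Dosage matrix or [genotype_matrix()]; columns are variants.
#' @param trait Trait vector (binary 0/1 for `family = "logistic"`).
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param family `"linear"` or `"logistic"`.
#' @param variants Optional data frame with columns `id`, `chr`, `pos`
#'   (taken from a `genotype_matrix` automatically).
#' @return A data frame of class `mr_assoc_scan` with one row per variant:
#'   `id`, `chr`, `pos`, `estimate`, `se`, `statistic`, `p`, `family`,
#'   `n_used`.
#' @export
association_scan <- function(G, trait, covariates = NULL,
                             family = c("linear", "logistic"),
                             variants = NULL) {
  family <- match.arg(family)
  if (inherits(G, "genotype_matrix")) {
    if (is.null(variants)) variants <- G$variants
    G <- G$dosages
  }
  G <- as_dosage_numeric(G)
  J <- ncol(G)
  if (is.null(variants)) {
    ids <- colnames(G)
    if (is.null(ids)) ids <- paste0("v", seq_len(J))
    variants <- data.frame(id = ids, chr = rep(1L, J), pos = seq_len(J))
  }
  stopifnot(nrow(variants) == J, length(trait) == nrow(G))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(G))
  }
  if (family == "logistic") {
    lv <- unique(trait[!is.na(trait)])
    if (!all(lv %in% c(0, 1)))
      stop("logistic family requires a binary 0/1 trait")
  }

  out <- data.frame(id = variants$id, chr = variants$chr, pos = variants$pos,
                    estimate = NA_real_, se = NA_real_,
                    statistic = NA_real_, p = NA_real_,
                    family = family, n_used = NA_integer_)
  for (j in seq_len(J)) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(trait)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    n_ok <- sum(ok)
    out$n_used[j] <- n_ok
    if (n_ok < 3L || stats::var(g[ok]) == 0) next  # flagged as NA, kept
    df <- data.frame(.trait = trait[ok], .g = g[ok])
    if (!is.null(covariates))
      df <- cbind(df, as.data.frame(covariates[ok, , drop = FALSE]))
    covnames <- setdiff(names(df), c(".trait", ".g"))
    fml <- if (length(covnames)) {
      stats::as.formula(paste(".trait ~ .g +",
                              paste(covnames, collapse = " + ")))
    } else .trait ~ .g
    co <- if (family == "linear") {
      stats::coef(summary(stats::lm(fml, data = df)))
    } else {
      stats::coef(summary(stats::glm(fml, data = df,
                                     family = stats::binomial())))
    }
    if (!".g" %in% rownames(co)) next
    out$estimate[j] <- co[".g", 1L]
    out$se[j] <- co[".g", 2L]
    out$statistic[j] <- co[".g", 3L]
    out$p[j] <- if (family == "linear") {
      2 * stats::pt(-abs(co[".g", 3L]), df = n_ok - nrow(co))
    } else {
      2 * stats::pnorm(-abs(co[".g", 3L]))
    }
  }
  class(out) <- c("mr_assoc_scan", "data.frame")
  out
}

#' Squared dosage correlation between two variants
#'
#' The standard composite LD measure for additively coded genotypes:
#' squared Pearson correlation over pairwise-complete observations.
#'
#' @param G Dosage matrix.
#' @param i,j Column indices.
#' @return A value in `[0, 1]`.
#' @export
ld_r2 <- function(G, i, j) {
  if (inherits(G, "genotype_matrix")) G <- G$dosages
  gi <- G[, i]; gj <- G[, j]
  ok <- !is.na(gi) & !is.na(gj)
  if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0)
    stop("LD undefined: zero-variance dosage column")
  stats::cor(gi[ok], gj[ok])^2
}

#' Greedy p-value clumping of an association scan
#'
#' Reduces a scan to approximately independent index variants the way GWAS
#' clumping tools do: repeatedly take the not-yet-absorbed variant with the
#' smallest p-value at most `p1` as an index, then absorb every
#' not-yet-absorbed variant on the same chromosome within `window_kb`
#' kilobases of it whose dosage r-squared with the index exceeds `r2_cut`.
#' Ties in p-value are broken by (chromosome, position) order.
#'
#' @param scan An [association_scan()] result (rows align with `G` columns).
#' @param G Dosage matrix used for LD.
#' @param p1 Index significance threshold (default 1e-5).
#' @param window_kb Physical window, inclusive, in kb on each side
#'   (default 500).
#' @param r2_cut Variants with `r^2 >` this value are absorbed
#'   (default 0.2).
#' @return An object of class `mr_clump_set`: a data frame with one row per
#'   index (`index`, `chr`, `pos`, `p`, `members` as a comma-separated id
#'   string) plus the parameters as attributes.
#' @export
greedy_clump <- function(scan, G, p1 = 1e-5, window_kb = 500, r2_cut = 0.2) {
  if (inherits(G, "genotype_matrix")) G <- G$dosages
  stopifnot(nrow(scan) == ncol(G))
  p <- scan$p
  ord_key <- order(scan$chr, scan$pos)
  rank_cp <- match(seq_len(nrow(scan)), ord_key)  # tie-break order
  free <- !is.na(p)
  rows <- list()
  repeat {
    cand <- which(free & p <= p1)
    if (length(cand) == 0L) break
    idx <- cand[order(p[cand], rank_cp[cand])][1L]
    free[idx] <- FALSE
    near <- which(free & scan$chr == scan$chr[idx] &
                    abs(scan$pos - scan$pos[idx]) <= window_kb * 1000)
    absorbed <- integer(0)
    for (j in near) {
      r2 <- tryCatch(ld_r2(G, idx, j), error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_cut) absorbed <- c(absorbed, j)
    }
    free[absorbed] <- FALSE
    rows[[length(rows) + 1L]] <- data.frame(
      index = scan$id[idx], chr = scan$chr[idx], pos = scan$pos[idx],
      p = p[idx],
      members = paste(scan$id[absorbed], collapse = ","))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(index = character(0), chr = integer(0),
                         pos = integer(0), p = numeric(0),
                         members = character(0))
  attr(out, "p1") <- p1
  attr(out, "window_kb") <- window_kb
  attr(out, "r2_cut") <- r2_cut
  class(out) <- c("mr_clump_set", "data.frame")
  out
}

#' Exclude candidate instruments associated with known confounders
#'
#' Drops any exposure index variant whose p-value in any confounder scan is
#' at or below `exclusion_p`; the remainder are returned as the selected
#' instruments. Instruments guilty of a confounder association violate the
#' exchangeability assumption of Mendelian randomization.
#'
#' @param exposure_clumps A [greedy_clump()] result for the exposure.
#' @param confounder_scans A list of [association_scan()] results, one per
#'   confounder (optionally named).
#' @param exclusion_p Exclusion threshold (default 1e-5, the same
#'   stringency as instrument selection).
#' @return Character vector of retained instrument ids, with an
#'   `exclusions` attribute (data frame: id, confounder, p). Candidates
#'   missing from a confounder scan trigger a warning and are retained.
#' @export
select_instruments <- function(exposure_clumps, confounder_scans = list(),
                               exclusion_p = 1e-5) {
  ids <- exposure_clumps$index
  if (length(confounder_scans) && is.null(names(confounder_scans)))
    names(confounder_scans) <- paste0("confounder",
                                      seq_along(confounder_scans))
  excl <- data.frame(id = character(0), confounder = character(0),
                     p = numeric(0))
  drop <- rep(FALSE, length(ids))
  for (cn in names(confounder_scans)) {
    sc <- confounder_scans[[cn]]
    m <- match(ids, sc$id)
    if (anyNA(m))
      warning("candidate(s) ", paste(ids[is.na(m)], collapse = ", "),
              " missing from confounder scan '", cn,
              "'; treated as not excluded")
    hit <- !is.na(m) & !is.na(sc$p[m]) & sc$p[m] <= exclusion_p
    if (any(hit)) {
      excl <- rbind(excl, data.frame(id = ids[hit], confounder = cn,
                                     p = sc$p[m][hit]))
      drop <- drop | hit
    }
  }
  out <- ids[!drop]
  attr(out, "exclusions") <- excl
  out
}
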