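#' Genotype dosage container
#'
#' A light container pairing an individuals-by-variants dosage matrix
#' (values 0/1/2 or `NA`) with per-variant metadata and unique sample ids.
#'
#' @param dosages Numeric matrix, individuals in rows.
#' @param variants Data frame with columns `id`, `chr`, `pos` (and
#'   optionally `ref`, `alt`), one row per dosage column. Defaults are
#'   synthesized from column names when omitted.
#' @param samples Character sample ids, one per row; must be unique.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants = NULL, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  n <- nrow(dosages); J <- ncol(dosages)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) stop("one sample id per dosage row required")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (is.null(variants)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("v", seq_len(J))
    variants <- data.frame(id = ids, chr = rep(1L, J),
                           pos = seq_len(J) * 1000L)
  }
  if (nrow(variants) != J)
    stop("variant metadata rows must match dosage columns")
  stopifnot(all(c("id", "chr", "pos") %in% names(variants)))
  colnames(dosages) <- variants$id
  rownames(dosages) <- samples
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read genotype dosages from a VCF or dosage TSV
#'
#' For VCF, the dosage is the alternate-allele count from the GT field;
#' `./.` and half-missing calls become `NA`, and multi-allelic records are
#' skipped with a warning. The dosage TSV layout is one variant per row
#' with columns `id`, `chr`, `pos` followed by one column per sample
#' (header row of sample ids).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "chr", "pos")
  if (!all(need %in% names(df)))
    stop("dosage TSV must have columns id, chr, pos then sample columns")
  samples <- setdiff(names(df), need)
  dos <- t(as.matrix(df[, samples, drop = FALSE]))
  storage.mode(dos) <- "double"
  genotype_matrix(dos, variants = df[, need], samples = samples)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alternate alleles; any missing allele makes the call missing
  dose_one <- function(s) {
    al <- strsplit(s, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dos <- apply(gt, 2L, dose_one)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chr = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT)
  genotype_matrix(t(dos), variants = variants, samples = colnames(gt))
}

#' Write genotype dosages to a dosage TSV or minimal VCF
#'
#' The VCF writer emits a minimal VCFv4.2 with GT-only genotype fields
#' (dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`), using
#' `ref`/`alt` metadata when present and `A`/`B` placeholders otherwise.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gm, path, format = c("dosage_tsv", "vcf")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    df <- cbind(gm$variants[, c("id", "chr", "pos")],
                as.data.frame(t(gm$dosages), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ref <- if ("ref" %in% names(gm$variants)) gm$variants$ref
           else rep("A", nrow(gm$variants))
    alt <- if ("alt" %in% names(gm$variants)) gm$variants$alt
           else rep("B", nrow(gm$variants))
    gtmap <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$samples),
                     collapse = "\t"))
    for (j in seq_len(ncol(gm$dosages))) {
      d <- gm$dosages[, j]
      gt <- ifelse(is.na(d), "./.", gtmap[d + 1L])
      lines <- c(lines, paste(c(gm$variants$chr[j], gm$variants$pos[j],
                                gm$variants$id[j], ref[j], alt[j], ".",
                                "PASS", ".", "GT", gt), collapse = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a TSV/CSV (by extension) with a header; an `id` column is
#' required and must be unique. Rows with missing outcome or exposure are
#' retained — complete-casing happens per analysis, so each exposure can
#' use its own maximal sample.
#'
#' @param path File path (`.csv` is comma-separated, anything else tab).
#' @param exposure Optional name of an ordered-exposure column to validate
#'   and recode to contiguous `1..K` via [recode_exposure()]; the mapping
#'   is stored in `attr(, "exposure_map")` and reported by message.
#' @return A data frame; sample ids in column `id`.
#' @export
read_phenotypes <- function(path, exposure = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("phenotype table must have an 'id' column")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate sample id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!is.null(exposure)) {
    if (!exposure %in% names(df)) stop("no column named '", exposure, "'")
    rec <- recode_exposure(df[[exposure]])
    df[[exposure]] <- rec
    attr(df, "exposure_map") <- attr(rec, "map")
  }
  df
}

#' Recode an ordered exposure to contiguous integer categories
#'
#' Validates that the (non-missing) codes are integers and maps the sorted
#' distinct values onto `1..K`, preserving order. The applied mapping is
#' reported via `message()` and attached as the `map` attribute.
#'
#' @param x Exposure codes (integers, possibly with gaps, e.g. 1/3/5).
#' @return Integer vector in `1..K` with a `map` attribute
#'   (data frame `from`, `to`).
#' @export
recode_exposure <- function(x) {
  xx <- x[!is.na(x)]
  if (!is.numeric(x) || any(xx != round(xx)))
    stop("exposure codes must be integers; offending values: ",
         paste(unique(utils::head(xx[xx != round(xx)], 5)), collapse = ", "))
  lv <- sort(unique(xx))
  out <- match(x, lv)
  map <- data.frame(from = lv, to = seq_along(lv))
  if (!identical(as.numeric(lv), as.numeric(seq_along(lv))))
    message("exposure recoded to 1..", length(lv), ": ",
            paste(map$from, "->", map$to, collapse = ", "))
  attr(out, "map") <- map
  out
}

#' Align genotypes and phenotypes by sample id
#'
#' Intersects the two sample sets (order-independently) and returns the
#' genotype matrix and phenotype table restricted to the shared ids, in
#' the same order. Reports how many samples were dropped from each side.
#'
#' @param gm A [genotype_matrix()].
#' @param pheno A phenotype data frame with an `id` column.
#' @param quiet Suppress the alignment message.
#' @return A list with `G` (dosage matrix), `pheno`, and `ids`.
#' @export
align_samples <- function(gm, pheno, quiet = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), "id" %in% names(pheno))
  ids <- intersect(gm$samples, pheno$id)
  if (length(ids) == 0L) stop("no shared sample ids")
  if (!quiet && (length(ids) < length(gm$samples) ||
                 length(ids) < nrow(pheno)))
    message(sprintf(
      "aligned %d shared samples (dropped %d genotype-only, %d phenotype-only)",
      length(ids), length(gm$samples) - length(ids),
      nrow(pheno) - length(ids)))
  list(G = gm$dosages[match(ids, gm$samples), , drop = FALSE],
       pheno = pheno[match(ids, pheno$id), , drop = FALSE],
       ids = ids)
}

# --- tabular writers (fixed column orders, tab-delimited) -----------------

write_tsv_exact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association scan in GWAS-tool column layout
#'
#' Columns `CHR, SNP, BP, BETA, SE, STAT, P, N` (with `BETA` renamed `OR`
#' is not applied; logistic estimates stay on the log-odds scale).
#'
#' @param scan An [association_scan()] result.
#' @param path Output path.
#' @export
write_scan <- function(scan, path) {
  write_tsv_exact(data.frame(CHR = scan$chr, SNP = scan$id, BP = scan$pos,
                             BETA = scan$estimate, SE = scan$se,
                             STAT = scan$statistic, P = scan$p,
                             N = scan$n_used), path)
}

#' Write a clump set as TSV
#' @param clumps A [greedy_clump()] result.
#' @param path Output path.
#' @export
write_clumps <- function(clumps, path) {
  write_tsv_exact(data.frame(INDEX = clumps$index, CHR = clumps$chr,
                             BP = clumps$pos, P = clumps$p,
                             MEMBERS = clumps$members), path)
}

#' Write a causal estimate row as TSV
#' @param est An [bootstrap_cis()] result.
#' @param path Output path.
#' @param variable Label for the exposure analyzed.
#' @export
write_estimate <- function(est, path, variable = "exposure") {
  write_tsv_exact(data.frame(
    variable = variable, n_iv = length(est$fit$b), n = est$n_used,
    beta_hat = est$beta_hat,
    normal_lo = est$ci_normal[1L], normal_hi = est$ci_normal[2L],
    basic_lo = est$ci_basic[1L], basic_hi = est$ci_basic[2L],
    pct_lo = est$ci_percentile[1L], pct_hi = est$ci_percentile[2L],
    p = est$p_value, B = est$B), path)
}
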