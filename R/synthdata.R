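#' Simulation configuration for the latent-threshold structural model
#'
#' Bundles every structural parameter of the data-generating process used
#' throughout the package:
#' \deqn{X^* = \theta_0 + \theta G + \gamma U + \epsilon_2, \quad
#'       Y = \beta_0 + \beta X^* + \alpha U + \epsilon_1,}
#' with \eqn{U \sim N(0,\sigma_u^2)}, \eqn{\epsilon_1 \sim N(0,\sigma_1^2)},
#' \eqn{\epsilon_2 \sim N(0,\sigma_2^2)} mutually independent of each other
#' and of the genotypes \eqn{G}. The observed exposure \eqn{X} is the ordered
#' category of \eqn{X^*} relative to the strictly increasing `thresholds`
#' (values at or below the first threshold fall in category 1). The composite
#' non-genetic latent scale is \eqn{\sigma = \sqrt{\gamma^2\sigma_u^2 +
#' \sigma_2^2}}; only \eqn{\theta/\sigma} and \eqn{\sigma\beta} are
#' identified from `(G, X, Y)`.
#'
#' @param n Sample size.
#' @param mafs Minor-allele frequencies, one per instrument, each in (0, 0.5].
#' @param theta Per-instrument latent effects (recycled to `length(mafs)`).
#' @param theta0 Latent intercept.
#' @param gamma Confounder effect on the latent exposure.
#' @param alpha Confounder effect on the outcome.
#' @param beta0 Outcome intercept.
#' @param beta Causal effect of the latent exposure on the outcome.
#' @param sigma_u Confounder standard deviation (positive).
#' @param sigma_1 Outcome noise standard deviation (positive).
#' @param sigma_2 Latent noise standard deviation (positive).
#' @param thresholds Strictly increasing cut points; `length(thresholds) + 1`
#'   ordered categories.
#' @param seed Integer RNG seed stored with the configuration and used by
#'   [simulate_dataset()].
#' @return An object of class `mr_sim_config` (a validated list). The derived
#'   scale is available as `sigma_of(config)`.
#' @seealso [simulate_dataset()], [table1_scenario()]
#' @examples
#' cfg <- sim_config(n = 500, mafs = c(0.3, 0.4), theta = 0.5, beta = 1.5)
#' sigma_of(cfg)
#' @export
sim_config <- function(n, mafs, theta, theta0 = 0, gamma = 1, alpha = 1,
                       beta0 = 0, beta = 0, sigma_u = 1, sigma_1 = 1,
                       sigma_2 = 1, thresholds = c(-0.5, 0.5), seed = 1L) {
  stopifnot(length(n) == 1L, n >= 1)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("every minor-allele frequency must lie in (0, 0.5]")
  theta <- rep_len(as.numeric(theta), length(mafs))
  if (any(c(sigma_u, sigma_1, sigma_2) <= 0))
    stop("sigma_u, sigma_1 and sigma_2 must be positive")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing with at least one cut point")
  cfg <- list(n = as.integer(n), mafs = as.numeric(mafs), theta = theta,
              theta0 = theta0, gamma = gamma, alpha = alpha, beta0 = beta0,
              beta = beta, sigma_u = sigma_u, sigma_1 = sigma_1,
              sigma_2 = sigma_2, thresholds = thresholds,
              seed = as.integer(seed))
  class(cfg) <- "mr_sim_config"
  cfg
}

#' Composite non-genetic latent scale of a configuration
#'
#' @param config An [sim_config()] object.
#' @return \eqn{\sigma = \sqrt{\gamma^2 \sigma_u^2 + \sigma_2^2}}.
#' @export
sigma_of <- function(config) {
  sqrt(config$gamma^2 * config$sigma_u^2 + config$sigma_2^2)
}

#' @export
print.mr_sim_config <- function(x, ...) {
  K <- length(x$thresholds) + 1L
  cat("Latent-threshold simulation config\n")
  cat(sprintf("  n = %d, instruments = %d, categories K = %d\n",
              x$n, length(x$mafs), K))
  cat(sprintf("  beta = %g, sigma = %g (=> sigma*beta = %g)\n",
              x$beta, sigma_of(x), x$beta * sigma_of(x)))
  invisible(x)
}

#' Simulate diallelic genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant is simulated independently as the count of minor alleles,
#' `Binomial(2, maf)`, giving additive 0/1/2 dosages.
#'
#' @param n Number of individuals.
#' @param mafs Minor-allele frequencies in (0, 0.5], one per variant.
#' @param seed Integer RNG seed.
#' @return An `n x length(mafs)` integer matrix with values in `{0, 1, 2}`.
#' @examples
#' G <- simulate_genotypes(100, mafs = c(0.2, 0.5), seed = 1)
#' colMeans(G)  # approx 2 * mafs
#' @export
simulate_genotypes <- function(n, mafs, seed = 1L) {
  stopifnot(n >= 1)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("every minor-allele frequency must lie in (0, 0.5]")
  set.seed(seed)
  J <- length(mafs)
  G <- matrix(0L, n, J)
  for (j in seq_len(J)) G[, j] <- stats::rbinom(n, 2L, mafs[j])
  colnames(G) <- paste0("iv", seq_len(J))
  G
}

# Category from latent value: X = k iff t_{k-1} < x* <= t_k
# (t_0 = -Inf, t_K = +Inf); exact ties go to the lower category.
categorize_latent <- function(x_star, thresholds) {
  K <- length(thresholds) + 1L
  x <- rep.int(1L, length(x_star))
  for (k in seq_along(thresholds)) x <- x + (x_star > thresholds[k])
  stopifnot(all(x >= 1L & x <= K))
  x
}

#' Simulate a dataset from the structural model
#'
#' Draws genotypes, confounder, latent exposure, observed ordered category
#' and outcome exactly per the structural equations stored in the
#' configuration (see [sim_config()]).
#'
#' @param config An [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `mr_sim_data`: a list with genotype matrix `G`,
#'   latent exposure `x_star`, observed category `X` (integers `1..K`),
#'   confounder `U` and outcome `Y`, plus the generating `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n = 200, mafs = 0.3, theta = 0.6,
#'                                  beta = 1.5, seed = 7))
#' table(d$X)
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mr_sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n <- config$n
  G <- simulate_genotypes(n, config$mafs, seed = seed)
  # simulate_genotypes seeded the stream; continue it for the noise draws
  U <- stats::rnorm(n, 0, config$sigma_u)
  eps2 <- stats::rnorm(n, 0, config$sigma_2)
  eps1 <- stats::rnorm(n, 0, config$sigma_1)
  x_star <- config$theta0 + drop(G %*% config$theta) + config$gamma * U + eps2
  X <- categorize_latent(x_star, config$thresholds)
  Y <- config$beta0 + config$beta * x_star + config$alpha * U + eps1
  out <- list(G = G, x_star = x_star, X = X, U = U, Y = Y, config = config)
  class(out) <- "mr_sim_data"
  out
}

#' @export
print.mr_sim_data <- function(x, ...) {
  cat(sprintf("Simulated latent-threshold dataset: n = %d, %d instruments\n",
              length(x$Y), ncol(x$G)))
  print(table(category = x$X))
  invisible(x)
}

# Table-1 scenario layout: instrument count and causal effect per group.
.table1_rows <- list(
  A = list(J = 8L, beta =  1.5), B = list(J = 6L, beta =  1.5),
  C = list(J = 5L, beta =  1.5), D = list(J = 4L, beta =  2.7),
  E = list(J = 6L, beta =  2.7), F = list(J = 6L, beta = -2.7),
  G = list(J = 6L, beta = -1.5), H = list(J = 5L, beta =  0),
  I = list(J = 8L, beta =  0),   J = list(J = 3L, beta =  0)
)

#' Preset simulation scenarios for the ten-group simulation study
#'
#' Returns the configuration for one of the ten scenario groups (A-J) of the
#' simulation study: n = 1000 individuals, a preset composite scale of
#' sigma = 1.5, and the group's instrument count and causal effect
#' (A: 8 instruments, beta = 1.5; B: 6, 1.5; C: 5, 1.5; D: 4, 2.7; E: 6, 2.7;
#' F: 6, -2.7; G: 6, -1.5; H: 5, 0; I: 8, 0; J: 3, 0).
#'
#' Quantities the study design leaves free are fixed as documented package
#' defaults: minor-allele frequencies evenly spaced over \[0.2, 0.5\]; equal
#' latent effects theta across instruments, scaled so the latent first-stage
#' R-squared equals the `strength` setting; the sigma budget split equally
#' between the confounder path and latent noise (\eqn{\gamma\sigma_u =
#' \sigma_2 = \sigma/\sqrt2}, \eqn{\sigma_u = 1}); confounder-outcome effect
#' alpha = 1 and outcome noise sigma_1 = 1; thresholds at the tertiles of the
#' marginal latent distribution, giving three roughly balanced categories.
#'
#' @param group Scenario label, one of `"A"` to `"J"`.
#' @param strength First-stage latent R-squared (variance in the latent
#'   exposure explained by the instruments), either a number in (0, 1) or
#'   `"strong"` (0.3), `"moderate"` (0.1), `"weak"` (0.02).
#' @param seed Seed stored in the configuration.
#' @return An [sim_config()] object with `sigma_of(config) == 1.5`.
#' @examples
#' cfg <- table1_scenario("C")
#' c(n = cfg$n, J = length(cfg$mafs), beta = cfg$beta, sigma = sigma_of(cfg))
#' @export
table1_scenario <- function(group, strength = "strong", seed = 1L) {
  group <- as.character(group)
  if (!group %in% names(.table1_rows))
    stop("unknown scenario group '", group, "' (expected one of A..J)")
  row <- .table1_rows[[group]]
  r2 <- if (is.character(strength)) {
    switch(match.arg(strength, c("strong", "moderate", "weak")),
           strong = 0.3, moderate = 0.1, weak = 0.02)
  } else {
    stopifnot(strength > 0, strength < 1)
    as.numeric(strength)
  }
  sigma <- 1.5
  mafs <- seq(0.2, 0.5, length.out = row$J)
  # equal theta across instruments such that V_G = r2/(1-r2) * sigma^2
  v_g <- r2 / (1 - r2) * sigma^2
  g_var <- sum(2 * mafs * (1 - mafs))
  theta <- sqrt(v_g / g_var)
  sigma_u <- 1
  gamma <- sigma / sqrt(2)     # gamma*sigma_u = sigma_2 = sigma/sqrt(2)
  sigma_2 <- sigma / sqrt(2)
  theta0 <- 0
  mu <- theta0 + theta * sum(2 * mafs)          # marginal latent mean
  sd_lat <- sqrt(theta^2 * g_var + sigma^2)     # marginal latent sd
  thr <- stats::qnorm(c(1, 2) / 3, mean = mu, sd = sd_lat)
  sim_config(n = 1000L, mafs = mafs, theta = theta, theta0 = theta0,
             gamma = gamma, alpha = 1, beta0 = 0, beta = row$beta,
             sigma_u = sigma_u, sigma_1 = 1, sigma_2 = sigma_2,
             thresholds = thr, seed = seed)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the phenotype part (`id`, `X`, `Y`, `U`, `x_star`) as a TSV, the
#' genotypes as a dosage TSV (see [write_genotypes()]), and the generating
#' configuration as JSON.
#'
#' @param data An `mr_sim_data` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_sim_dataset <- function(data, dir, prefix = "sim") {
  stopifnot(inherits(data, "mr_sim_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(data$Y)
  ids <- sprintf("S%05d", seq_len(n))
  ph <- data.frame(id = ids, X = data$X, Y = data$Y, U = data$U,
                   x_star = data$x_star)
  paths <- c(pheno = file.path(dir, paste0(prefix, "_pheno.tsv")),
             geno  = file.path(dir, paste0(prefix, "_dosage.tsv")),
             config = file.path(dir, paste0(prefix, "_config.json")))
  utils::write.table(ph, paths[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gm <- genotype_matrix(data$G, samples = ids)
  write_genotypes(gm, paths[["geno"]], format = "dosage_tsv")
  cfg <- unclass(data$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a simulation configuration from JSON
#'
#' @param path Path to a JSON file written by [write_sim_dataset()] (or
#'   hand-authored with the same field names).
#' @return An [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(n = x$n, mafs = x$mafs, theta = x$theta, theta0 = x$theta0,
             gamma = x$gamma, alpha = x$alpha, beta0 = x$beta0,
             beta = x$beta, sigma_u = x$sigma_u, sigma_1 = x$sigma_1,
             sigma_2 = x$sigma_2, thresholds = x$thresholds,
             seed = x$seed)
}
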