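# Independent oracles and fixture builders shared across tests.

# Brute-force clumping by the stated rule, written independently of
# greedy_clump: full r^2 matrix up front, traversal of a (p, chr, pos)-
# sorted list with explicit absorbed bookkeeping.
brute_clump <- function(scan, G, p1 = 1e-5, window_kb = 500, r2_cut = 0.2) {
  r2 <- suppressWarnings(stats::cor(G))^2
  ord <- order(scan$p, scan$chr, scan$pos)
  absorbed <- rep(FALSE, nrow(scan))
  idx_out <- integer(0)
  members <- list()
  for (v in ord) {
    if (absorbed[v] || is.na(scan$p[v]) || scan$p[v] > p1) next
    absorbed[v] <- TRUE
    mem <- integer(0)
    for (u in seq_len(nrow(scan))) {
      if (absorbed[u]) next
      if (scan$chr[u] == scan$chr[v] &&
          abs(scan$pos[u] - scan$pos[v]) <= window_kb * 1000 &&
          !is.na(r2[v, u]) && r2[v, u] > r2_cut) {
        absorbed[u] <- TRUE
        mem <- c(mem, u)
      }
    }
    idx_out <- c(idx_out, v)
    members[[length(members) + 1L]] <- sort(scan$id[mem])
  }
  list(index = scan$id[idx_out], members = members)
}

# Random variant panel with planted correlation blocks: each variant may
# spawn a correlated twin nearby (dosages copied, a fraction resampled).
random_ld_panel <- function(n = 300, J = 20, seed = 1) {
  set.seed(seed)
  mafs <- runif(J, 0.1, 0.5)
  G <- sapply(mafs, function(m) rbinom(n, 2, m))
  chr <- sample(1:2, J, replace = TRUE)
  pos <- sample.int(2e6, J)
  twin_of <- sample(J, floor(J / 3))
  for (k in seq_along(twin_of)) {
    src <- twin_of[k]
    dst <- ((src + k) %% J) + 1L
    g <- G[, src]
    flip <- runif(n) < 0.15
    g[flip] <- rbinom(sum(flip), 2, mafs[src])
    G[, dst] <- g
    chr[dst] <- chr[src]
    pos[dst] <- pmin(2e6, pos[src] + sample.int(8e5, 1))
  }
  scan <- data.frame(id = paste0("v", seq_len(J)), chr = chr, pos = pos,
                     p = 10^-runif(J, 0, 8))
  list(scan = scan, G = G)
}

# Panel wrapping a structural-model dataset for end-to-end pipeline tests:
# true instruments plus LD twins, null variants, and one variant that both
# enters the latent exposure and drives a measured confounder trait.
pipeline_panel <- function(seed, n = 1000, J_true = 7, beta = 1.5) {
  mafs <- seq(0.25, 0.5, length.out = J_true + 1)   # last one pleiotropic
  sigma <- 1.5
  v_g <- 0.3 / 0.7 * sigma^2
  theta <- sqrt(v_g / sum(2 * mafs * (1 - mafs)))
  mu <- theta * sum(2 * mafs)
  sd_lat <- sqrt(theta^2 * sum(2 * mafs * (1 - mafs)) + sigma^2)
  cfg <- sim_config(n = n, mafs = mafs, theta = theta, gamma = sigma / sqrt(2),
                    alpha = 1, beta = beta, sigma_u = 1, sigma_1 = 1,
                    sigma_2 = sigma / sqrt(2),
                    thresholds = qnorm(c(1, 2) / 3, mu, sd_lat), seed = seed)
  d <- simulate_dataset(cfg)
  set.seed(seed + 1L)
  J_all <- J_true + 1L
  # LD twins of the first two true instruments
  twins <- sapply(1:2, function(j) {
    g <- d$G[, j]
    flip <- runif(n) < 0.1
    g[flip] <- rbinom(sum(flip), 2, mafs[j])
    g
  })
  nulls <- sapply(runif(20, 0.1, 0.5), function(m) rbinom(n, 2, m))
  G <- cbind(d$G, twins, nulls)
  Jp <- ncol(G)
  variants <- data.frame(
    id = c(paste0("iv", seq_len(J_all)), "twin1", "twin2",
           paste0("null", 1:20)),
    chr = c(rep(1L, J_all + 2L), rep(2L, 20)),
    pos = c(seq_len(J_all) * 2e6, 1L * 2e6 + 1e4, 2L * 2e6 + 1e4,
            seq_len(20) * 1e6))
  colnames(G) <- variants$id
  # measured confounder trait driven by the last "true" instrument
  conf_trait <- 0.6 * d$G[, J_all] + rnorm(n)
  list(G = G, variants = variants, X = d$X, Y = d$Y,
       conf_trait = conf_trait, sigma_beta = beta * sigma,
       true_ids = paste0("iv", seq_len(J_true)),
       pleio_id = paste0("iv", J_all))
}
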