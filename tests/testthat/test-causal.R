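test_that("risk scores are the stage-one linear predictor", {
  d <- simulate_dataset(table1_scenario("J", seed = 1))
  fit <- fit_ordinal_iv(d$G, d$X)
  s <- risk_score(fit, d$G)
  expect_equal(s, drop(d$G %*% fit$b))
  # thresholds do not enter the score
  fit2 <- fit
  fit2$a <- fit$a + 5
  expect_identical(risk_score(fit2, d$G), s)
  fit0 <- fit
  fit0$b[] <- 0
  expect_true(all(risk_score(fit0, d$G) == 0))
  expect_error(risk_score(fit, d$G[, 1:2]), "does not match")
})

test_that("the two-stage estimate targets sigma*beta and vanishes under the null", {
  cfg <- table1_scenario("C", seed = 5)
  cfg$n <- 20000L
  d <- simulate_dataset(cfg)
  est <- two_stage_estimate(d$G, d$X, d$Y)
  expect_equal(est$beta_hat, 1.5 * 1.5, tolerance = 0.05)
  cfg0 <- table1_scenario("H", seed = 6)
  cfg0$n <- 20000L
  d0 <- simulate_dataset(cfg0)
  expect_lt(abs(two_stage_estimate(d0$G, d0$X, d0$Y)$beta_hat), 0.1)
})

test_that("estimation error of the two-stage estimate shrinks with n", {
  errs <- sapply(c(1000L, 10000L, 100000L), function(n) {
    cfg <- table1_scenario("C", seed = 77)
    cfg$n <- n
    d <- simulate_dataset(cfg)
    abs(two_stage_estimate(d$G, d$X, d$Y)$beta_hat - 2.25)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / 2.25, 0.02)
})

test_that("a causally inert first stage raises an informative error", {
  set.seed(8)
  n <- 300
  G <- simulate_genotypes(n, c(0.3, 0.4), seed = 8)
  X <- sample(1:3, n, replace = TRUE)   # exposure unrelated to G
  Y <- rnorm(n)
  fit <- fit_ordinal_iv(G, X)
  # force an exactly-zero score to exercise the degenerate branch
  expect_error(two_stage_estimate(G * 0, X, Y),
               "first stage carries no signal")
})

test_that("CI-derived p-values follow the normal back-derivation", {
  expect_equal(p_from_ci(0, c(-1, 1)), 1)
  expect_error(p_from_ci(1, c(2, 2)), "lower < upper")
  # symmetric interval at another level
  expect_equal(p_from_ci(1, c(1 - qnorm(0.95), 1 + qnorm(0.95)), level = 0.9),
               2 * pnorm(-1), tolerance = 1e-12)
})

test_that("heritability rescaling inverts the sigma scaling", {
  # identity when V_G makes sigma = 1
  expect_equal(rescale_by_heritability(2.25, h2 = 0.5, V_G = 1)$beta, 2.25)
  # algebra oracle: h2 = 0.5, V_G = 2.25 => sigma = 1.5
  r <- rescale_by_heritability(2.25, h2 = 0.5, V_G = 2.25, b = c(0.4, 0.2))
  expect_equal(r$sigma, 1.5)
  expect_equal(r$beta, 1.5)
  expect_equal(r$theta, c(0.6, 0.3))
  expect_error(rescale_by_heritability(1, h2 = 1, V_G = 1), "h2")
  expect_error(rescale_by_heritability(1, h2 = 0.5, V_G = -1), "V_G")
  # end-to-end: rescaling a large-n estimate by the true sigma recovers beta
  cfg <- table1_scenario("C", seed = 9)
  cfg$n <- 20000L
  d <- simulate_dataset(cfg)
  bh <- two_stage_estimate(d$G, d$X, d$Y)$beta_hat
  v_g <- sum(cfg$theta^2 * 2 * cfg$mafs * (1 - cfg$mafs))
  h2 <- v_g / (v_g + sigma_of(cfg)^2)
  expect_equal(rescale_by_heritability(bh, h2 = h2, V_G = v_g)$beta,
               cfg$beta, tolerance = 0.05)
})

test_that("bootstrap intervals have the stated construction", {
  d <- simulate_dataset(table1_scenario("C", seed = 12))
  est <- bootstrap_cis(d$G, d$X, d$Y, B = 200, seed = 4)
  draws <- est$boot_draws
  expect_length(draws, 200L)
  al <- 0.025
  q <- quantile(draws, c(al, 1 - al), names = FALSE)
  expect_equal(est$ci_percentile, q)
  expect_equal(est$ci_basic, c(2 * est$beta_hat - q[2], 2 * est$beta_hat - q[1]))
  expect_equal(est$ci_normal,
               est$beta_hat + c(-1, 1) * qnorm(0.975) * sd(draws))
  expect_true(est$ci_percentile[1] <= est$beta_hat &&
                est$beta_hat <= est$ci_percentile[2])
  # p from the normal CI is exactly the z-test on the bootstrap SD
  expect_equal(p_from_ci(est$beta_hat, est$ci_normal),
               2 * pnorm(-abs(est$beta_hat / sd(draws))), tolerance = 1e-12)
  # identical seed reproduces the draws
  est2 <- bootstrap_cis(d$G, d$X, d$Y, B = 200, seed = 4)
  expect_identical(est2$boot_draws, draws)
})

test_that("basic and percentile intervals agree with the boot package on the same draws", {
  d <- simulate_dataset(table1_scenario("J", seed = 14))
  est <- bootstrap_cis(d$G, d$X, d$Y, B = 499, seed = 2)
  bo <- structure(list(t0 = est$beta_hat, t = matrix(est$boot_draws),
                       R = est$B, data = data.frame(i = seq_len(est$n_used)),
                       seed = 1L, sim = "ordinary", stype = "i",
                       strata = rep(1, est$n_used), weights = NULL,
                       statistic = function(d, i) 0,
                       call = quote(boot())),
                  class = "boot")
  ci <- boot::boot.ci(bo, type = c("basic", "perc"), conf = 0.95)
  # boot interpolates order statistics slightly differently; agreement is
  # to within a small fraction of the interval width
  tol <- 0.05 * diff(range(est$ci_percentile))
  expect_lt(max(abs(est$ci_basic - ci$basic[4:5])), tol)
  expect_lt(max(abs(est$ci_percentile - ci$percent[4:5])), tol)
})

test_that("resamples that lose an exposure category are redrawn with a warning", {
  set.seed(3)
  n <- 8
  G <- matrix(rbinom(n, 2, 0.4))
  X <- c(rep(1L, 7), 2L)          # one lone top-category observation
  Y <- 0.5 * G[, 1] + rnorm(n)
  expect_warning(bootstrap_cis(G, X, Y, B = 40, seed = 7),
                 "redrawn")
})

test_that("the study driver emits one row per group in both modes", {
  tab <- run_simulation_study(c("C", "H"), mode = "replicate_datasets",
                              reps = 2, B = 0, seed = 101)
  expect_identical(tab$group, c("C", "H"))
  expect_identical(tab$n_iv, c(5L, 5L))
  expect_true(all(is.na(tab$coverage)))
  expect_equal(tab$sigma_beta, c(2.25, 0))
  tab2 <- run_simulation_study("J", mode = "single_dataset_bootstrap",
                               B = 150, seed = 102)
  expect_identical(nrow(tab2), 1L)
  expect_true(all(c("basic_lo", "basic_hi", "p") %in% names(tab2)))
  expect_lt(tab2$basic_lo, tab2$basic_hi)
  # replicate mode with bootstrap reports coverage in [0, 1]
  tab3 <- run_simulation_study("J", mode = "replicate_datasets",
                               reps = 3, B = 120, seed = 103)
  expect_true(tab3$coverage >= 0 && tab3$coverage <= 1)
})
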