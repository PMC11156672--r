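make_gm <- function(seed = 1, n = 20, J = 4, missing = TRUE) {
  set.seed(seed)
  dos <- matrix(rbinom(n * J, 2, 0.4), n, J)
  if (missing) dos[sample(length(dos), 3)] <- NA
  genotype_matrix(dos,
                  variants = data.frame(id = paste0("rs", seq_len(J)),
                                        chr = rep(1:2, length.out = J),
                                        pos = seq_len(J) * 1e5,
                                        ref = rep("A", J), alt = rep("G", J)),
                  samples = sprintf("P%03d", seq_len(n)))
}

test_that("genotype matrices validate dosages and sample ids", {
  expect_error(genotype_matrix(matrix(3, 1, 1)), "0, 1, 2 or missing")
  expect_error(genotype_matrix(matrix(0:1, 2, 1),
                               samples = c("a", "a")), "unique")
  gm <- make_gm()
  expect_identical(dim(gm$dosages), c(20L, 4L))
  expect_identical(colnames(gm$dosages), gm$variants$id)
})

test_that("dosage TSV writing and reading round-trips", {
  gm <- make_gm(seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gm, path, format = "dosage_tsv")
  back <- read_genotypes(path)
  expect_equal(back$dosages, gm$dosages)
  expect_identical(back$samples, gm$samples)
  expect_identical(back$variants$id, gm$variants$id)
  expect_identical(back$variants$pos, gm$variants$pos)
})

test_that("VCF writing and reading round-trips through GT fields", {
  skip_if_not_installed("vcfR")
  gm <- make_gm(seed = 3)
  path <- tempfile(fileext = ".vcf")
  write_genotypes(gm, path, format = "vcf")
  back <- read_genotypes(path)
  expect_equal(unname(back$dosages), unname(gm$dosages))
  expect_identical(back$samples, gm$samples)
  expect_identical(back$variants$id, gm$variants$id)
})

test_that("VCF GT parsing counts alternate alleles and skips multi-allelics", {
  skip_if_not_installed("vcfR")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT",
          "s1\ts2\ts3\ts4", sep = "\t"),
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1|1\t./.",
    "1\t200\trsB\tA\tG\t.\tPASS\t.\tGT\t0/1\t./1\t0|0\t1/1",
    "1\t300\trsM\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0\t1/2")
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_warning(gm <- read_genotypes(path), "multi-allelic")
  expect_identical(gm$variants$id, c("rsA", "rsB"))
  expect_equal(unname(gm$dosages[, "rsA"]), c(0, 1, 2, NA))
  expect_equal(unname(gm$dosages[, "rsB"]), c(1, NA, 0, 2))
})

test_that("phenotype reading validates ids and recodes gappy exposures", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(id = c("a", "b", "c", "d"),
                   exercise = c(1L, 3L, 5L, 3L),
                   mmse = c(25, 28, NA, 21))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(ph <- read_phenotypes(path, exposure = "exercise"))
  expect_equal(as.integer(ph$exercise), c(1L, 2L, 3L, 2L))
  expect_identical(attr(ph, "exposure_map")$from, c(1L, 3L, 5L))
  expect_identical(nrow(ph), 4L)  # missing outcome retained
  df2 <- df; df2$id[2] <- "a"
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "duplicate sample id")
  expect_error(recode_exposure(c(1, 1.5)), "integers")
  # a cohort-sized table loads with every row accounted for
  big <- data.frame(id = sprintf("C%04d", 1:897),
                    exercise = sample(1:2, 897, TRUE),
                    mmse = sample(0:30, 897, TRUE))
  write.table(big, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(nrow(read_phenotypes(path)), 897L)
})

test_that("sample alignment is by id, immune to row order", {
  d <- simulate_dataset(table1_scenario("J", seed = 61))
  ids <- sprintf("S%04d", seq_along(d$Y))
  gm <- genotype_matrix(d$G, samples = ids)
  ph <- data.frame(id = ids, X = d$X, Y = d$Y)
  set.seed(1)
  ph_shuffled <- ph[sample(nrow(ph)), ]
  al1 <- align_samples(gm, ph, quiet = TRUE)
  al2 <- align_samples(gm, ph_shuffled, quiet = TRUE)
  e1 <- two_stage_estimate(al1$G, al1$pheno$X, al1$pheno$Y)$beta_hat
  e2 <- two_stage_estimate(al2$G, al2$pheno$X, al2$pheno$Y)$beta_hat
  expect_identical(e1, e2)
  # partial overlap is intersected
  expect_message(al3 <- align_samples(gm, ph[1:500, ]), "aligned 500")
  expect_identical(length(al3$ids), 500L)
})

test_that("simulated datasets round-trip through the plain-text writers", {
  d <- simulate_dataset(table1_scenario("J", seed = 62))
  dir <- tempfile()
  paths <- write_sim_dataset(d, dir)
  ph <- read_phenotypes(paths[["pheno"]])
  expect_identical(nrow(ph), 1000L)
  expect_equal(ph$Y, d$Y, tolerance = 1e-9)
  gm <- read_genotypes(paths[["geno"]])
  expect_equal(unname(gm$dosages), unname(d$G) * 1.0)
  cfg <- read_sim_config(paths[["config"]])
  expect_equal(cfg, d$config, tolerance = 1e-12)
})

test_that("the CLI runs the pipeline end to end and is deterministic", {
  dir <- tempfile(); dir.create(dir)
  # simulate a scenario dataset
  expect_identical(run_cli(c("simulate", "--group", "C", "--seed", "9",
                             "--out", dir)), 0L)
  geno <- file.path(dir, "sim_dosage.tsv")
  pheno <- file.path(dir, "sim_pheno.tsv")
  expect_true(file.exists(geno) && file.exists(pheno))
  # first-stage fit table
  fitout <- file.path(dir, "fit.tsv")
  expect_identical(run_cli(c("fit", "--geno", geno, "--pheno", pheno,
                             "--exposure", "X", "--out", fitout)), 0L)
  expect_identical(nrow(read.table(fitout, header = TRUE)), 7L)  # 5 b + 2 a
  # estimate with bootstrap, twice with the same seed: byte-identical
  for (f in c("est1.tsv", "est2.tsv"))
    expect_identical(run_cli(c("estimate", "--geno", geno, "--pheno", pheno,
                               "--exposure", "X", "--outcome", "Y",
                               "--boot", "120", "--seed", "5",
                               "--out", file.path(dir, f))), 0L)
  expect_identical(readLines(file.path(dir, "est1.tsv")),
                   readLines(file.path(dir, "est2.tsv")))
  est <- read.table(file.path(dir, "est1.tsv"), header = TRUE)
  expect_equal(est$beta_hat, 2.25, tolerance = 0.5)
  # egger subcommand
  eggout <- file.path(dir, "egger.tsv")
  expect_identical(run_cli(c("egger", "--geno", geno, "--pheno", pheno,
                             "--exposure", "X", "--outcome", "Y",
                             "--out", eggout)), 0L)
  expect_identical(read.table(eggout, header = TRUE)$J, 5L)
  # study smoke run: one row per group
  stout <- file.path(dir, "study.tsv")
  expect_identical(run_cli(c("study", "--groups", "H,J", "--mode",
                             "replicate", "--reps", "2", "--boot", "0",
                             "--seed", "7", "--out", stout)), 0L)
  expect_identical(read.table(stout, header = TRUE)$group, c("H", "J"))
  # manifests are written alongside outputs
  expect_true(file.exists(paste0(stout, ".manifest.json")))
  # unknown subcommand: nonzero status
  expect_identical(suppressMessages(run_cli("frobnicate")), 1L)
})
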