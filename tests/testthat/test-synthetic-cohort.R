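test_that("identical configurations give identical cohorts", {
  a <- simulate_cohort(small_cfg(seed = 5))
  b <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$subtype, b$truth$subtype)
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$expression, c$expression))
})

test_that("invalid configurations error before sampling", {
  expect_error(sim_config(n_tumor = 0), "counts")
  expect_error(sim_config(n_tumor_normal_shifted = 30), "n_tumor_normal_shifted")
  expect_error(sim_config(metastasis_gene_count = 25), "metastasis_gene_count")
  expect_error(sim_config(subtype_proportions = c(0.5, 0.4, 0.2)), "simplex")
  expect_error(sim_config(rfs_hazard_ratios = c(1, -1, 2)), "rfs_hazard")
  expect_error(sim_config(gene_noise_sd = 0), "gene_noise_sd")
})

test_that("cohort respects its structural contract", {
  cohort <- simulate_cohort(small_cfg(seed = 2))
  cfg <- small_cfg(seed = 2)
  expect_equal(dim(cohort$expression),
               c(cfg$n_regulators + cfg$n_background_genes,
                 cfg$n_tumor + cfg$n_normal))
  expect_true(all(m6a_regulators() %in% rownames(cohort$expression)))
  expect_silent(check_cohort(cohort$expression, cohort$clinical))
  roles <- cohort$truth$gene_roles
  expect_equal(sum(roles$tn_shifted), cfg$n_tumor_normal_shifted)
  expect_equal(sum(roles$metastasis_gene), cfg$metastasis_gene_count)
  # metastasis genes belong to the last subtype's block
  expect_true(all(roles$subtype_block[roles$metastasis_gene] == cfg$k_subtypes))
  norm <- cohort$clinical[cohort$clinical$tissue == "normal", ]
  expect_true(all(norm$metastasis == "unknown"))
  expect_true(all(is.na(norm$os_time)))
})

test_that("group means of shifted regulators recover tau and delta", {
  # large cohorts, effects isolated: tau with delta off, delta with tau off
  cfg_t <- sim_config(n_tumor = 5000, n_normal = 5000, n_background_genes = 5,
                      subtype_shift = 0, activation_shift = 0,
                      tumor_normal_shift = 1, seed = 31)
  co <- simulate_cohort(cfg_t)
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  nor <- co$clinical$sample_id[co$clinical$tissue == "normal"]
  roles <- co$truth$gene_roles
  shifted <- roles$gene_id[roles$tn_shifted]
  unshifted <- roles$gene_id[roles$is_regulator & !roles$tn_shifted]
  diff_s <- rowMeans(co$expression[shifted, tum]) -
    rowMeans(co$expression[shifted, nor])
  diff_u <- rowMeans(co$expression[unshifted, tum]) -
    rowMeans(co$expression[unshifted, nor])
  se <- cfg_t$gene_noise_sd * sqrt(1 / 5000 + 1 / 5000)
  expect_true(all(abs(diff_s - 1) < 4 * se))
  expect_true(all(abs(diff_u) < 4 * se))

  cfg_d <- sim_config(n_tumor = 9000, n_normal = 1000, n_background_genes = 5,
                      subtype_shift = 2, activation_shift = 0,
                      tumor_normal_shift = 0, seed = 32)
  cd <- simulate_cohort(cfg_d)
  st <- cd$truth$subtype
  roles <- cd$truth$gene_roles
  for (s in 1:3) {
    blk <- roles$gene_id[!is.na(roles$subtype_block) & roles$subtype_block == s]
    inside <- rowMeans(cd$expression[blk, names(st)[st == s]])
    outside <- rowMeans(cd$expression[blk, names(st)[st != s]])
    n_in <- sum(st == s); n_out <- sum(st != s)
    se <- cfg_d$gene_noise_sd * sqrt(1 / n_in + 1 / n_out)
    expect_true(all(abs((inside - outside) - 2) < 4 * se))
  }
})

test_that("empirical metastasis rate matches the model's own probabilities", {
  cfg <- sim_config(n_tumor = 4000, n_normal = 50, n_background_genes = 5,
                    seed = 77)
  co <- simulate_cohort(cfg)
  tum <- co$clinical[co$clinical$tissue == "tumor", ]
  rate <- mean(tum$metastasis == "yes")
  p <- co$truth$metastasis_prob
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(rate - mean(p)), 3 * se)
})

test_that("null model (no shifts, no metastasis effect) gives alpha-level screens", {
  cfg <- sim_config(n_tumor = 50, n_normal = 50, n_regulators = 21,
                    n_background_genes = 979, subtype_shift = 0,
                    activation_shift = 0, tumor_normal_shift = 0,
                    metastasis_beta = 0, seed = 13)
  co <- simulate_cohort(cfg)
  res <- screen_regulators(co$expression, co$clinical,
                           regulators = rownames(co$expression),
                           contrast = "tumor_vs_normal", alpha = 0.05)
  expect_gt(mean(res$selected), 0.02)
  expect_lt(mean(res$selected), 0.08)
})

test_that("the censoring mechanism is independent of covariates", {
  # equal hazards across subtypes isolate the censoring draw itself: the
  # observed censoring indicator must then carry no covariate signal
  cfg <- sim_config(n_tumor = 6000, n_normal = 50, n_background_genes = 5,
                    rfs_hazard_ratios = c(1, 1, 1), seed = 41)
  co <- simulate_cohort(cfg)
  tum <- co$clinical[co$clinical$tissue == "tumor", ]
  fit <- glm(I(1 - rfs_event) ~ factor(subtype) + I(metastasis == "yes"),
             family = binomial, data = tum)
  z <- summary(fit)$coefficients[-1, "z value"]
  expect_true(all(abs(z) < 4))
})

test_that("write_cohort produces readable TSVs", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_cfg(seed = 3))
  write_cohort(co, dir)
  expect_identical(read_expression_matrix(file.path(dir, "expr.tsv")),
                   co$expression)
  back <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(back$sample_id, co$clinical$sample_id)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$subtype, unname(co$truth$subtype))
})

test_that("YAML round-trip of the configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_tumor: 40", "n_normal: 10", "seed: 9",
               "subtype_shift: 1.5"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_tumor, 40)
  expect_equal(cfg$subtype_shift, 1.5)
  expect_equal(cfg$k_subtypes, 3)
  writeLines(c("n_tumor: 40", "bogus_field: 1"), path)
  expect_error(read_sim_config(path), "bogus_field")
})
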