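test_that("the default design yields 63 queens x 4 niches = 252 samples", {
  st <- generate_study(study_config(seed = 11))
  expect_equal(nrow(st$otu$counts), 252)
  expect_equal(length(unique(st$metadata$queen_id)), 63)
  expect_equal(sort(unique(st$metadata$niche)), sort(NICHE_LEVELS))
  tab <- table(unique(st$metadata[, c("queen_id", "age_class", "source")])[, -1])
  expect_equal(sort(as.vector(tab)), c(15, 16, 16, 16))
  expect_equal(nrow(st$carbonyl), 63)
})

test_that("identical seeds reproduce the study byte for byte", {
  a <- generate_study(study_config(seed = 5))
  b <- generate_study(study_config(seed = 5))
  expect_identical(a$otu$counts, b$otu$counts)
  expect_identical(a$qpcr$totals, b$qpcr$totals)
  expect_identical(a$carbonyl, b$carbonyl)
  c2 <- generate_study(study_config(seed = 6))
  expect_false(identical(a$otu$counts, c2$otu$counts))
})

test_that("truth records exactly the nonzero configured effects", {
  fx <- matrix(0, 4, 9, dimnames = list(NICHE_LEVELS, core_taxa()))
  fx["rectum", "B_asteroides"] <- 1
  fx["mouth", "Delftia"] <- -0.5
  st <- generate_study(study_config(age_log2_effects = fx, seed = 2))
  tr <- st$truth$age_effects
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$taxon, c("B_asteroides", "Delftia"))
  expect_null(st$truth$source_effects)
  st0 <- generate_study(study_config(seed = 2))
  expect_null(st0$truth$age_effects)
})

test_that("sample proportions converge to the base composition as concentration grows", {
  cfg <- study_config(concentration = c(mouth = 1e6, midgut = 1e6,
                                        ileum = 1e6, rectum = 1e6),
                      rare_mass = 0, n_rare_otus = 0, seed = 3)
  set.seed(3)
  cnt <- generate_counts(cfg, "rectum", "young", "AZ", 50)
  p_hat <- colMeans(cnt / rowSums(cnt))[core_taxa()]
  expect_lt(max(abs(p_hat - cfg$base_composition["rectum", ])), 0.005)
})

test_that("a +1 log2 age effect doubles the old-group mean proportion", {
  fx <- matrix(0, 4, 9, dimnames = list(NICHE_LEVELS, core_taxa()))
  fx["rectum", "B_asteroides"] <- 1
  cfg <- study_config(age_log2_effects = fx, rare_mass = 0,
                      n_rare_otus = 0, seed = 4)
  set.seed(4)
  young <- generate_counts(cfg, "rectum", "young", "AZ", 200)
  old <- generate_counts(cfg, "rectum", "old", "AZ", 200)
  ratio <- mean(old[, "B_asteroides"] / rowSums(old)) /
    mean(young[, "B_asteroides"] / rowSums(young))
  exp_ratio <- expected_composition(cfg, "rectum", "old", "AZ")["B_asteroides"] /
    expected_composition(cfg, "rectum", "young", "AZ")["B_asteroides"]
  expect_equal(unname(exp_ratio), 2 / (1 + cfg$base_composition["rectum", "B_asteroides"]),
               tolerance = 1e-10) # renormalization closes the composition
  expect_equal(ratio, unname(exp_ratio), tolerance = 0.12)
})

test_that("degenerate configurations are rejected", {
  expect_error(study_config(depth_mean = c(mouth = 50, midgut = 50,
                                           ileum = 50, rectum = 50)),
               "at least 100")
  bad <- default_composition(); bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(study_config(base_composition = bad), "sum to 1")
  expect_error(study_config(rare_prevalence = 0.5), "sporadic")
})

test_that("qPCR totals match the configured geometric means", {
  cfg <- study_config(qpcr_sdlog = 0, seed = 8)
  set.seed(8)
  expect_equal(unname(generate_qpcr(cfg, "rectum", 5)), rep(1.212e8, 5))
  cfg2 <- study_config(seed = 8)
  set.seed(8)
  x <- generate_qpcr(cfg2, "rectum", 1000)
  expect_equal(exp(mean(log(x))), 1.212e8, tolerance = 0.05)
})

test_that("carbonyl draws encode the configured age and source structure", {
  queens <- data.frame(queen_id = sprintf("Q%02d", 1:60),
                       age_class = rep(c("young", "old"), each = 30),
                       source = "AZ", stringsAsFactors = FALSE)
  cfg <- study_config(carbonyl = list(young_mean = 2, old_mean = 4,
                                      source_shift = 0, sd = 0,
                                      taxon_link = numeric(0),
                                      protein_mg = 0.5, volume_ul = 100,
                                      path_cm = 1), seed = 9)
  cb <- generate_carbonyl(cfg, queens)
  expect_equal(mean(cb$carbonyl_nmol_per_mg[31:60]) -
                 mean(cb$carbonyl_nmol_per_mg[1:30]), 2)
  # record is consistent with the assay math
  expect_equal(carbonyl_per_mg(cb$A345, cb$path_cm, cb$volume_ul,
                               cb$protein_mg),
               cb$carbonyl_nmol_per_mg, tolerance = 1e-12)

  # effect = 2 sd: one-way ANOVA recovers the age difference at n = 60
  cfg2 <- study_config(carbonyl = list(young_mean = 2, old_mean = 4,
                                       source_shift = 0, sd = 1,
                                       taxon_link = numeric(0),
                                       protein_mg = 0.5, volume_ul = 100,
                                       path_cm = 1), seed = 9)
  set.seed(9)
  cb2 <- suppressWarnings(generate_carbonyl(cfg2, queens)) # rare truncation ok
  fit <- stats::anova(stats::lm(cb2$carbonyl_nmol_per_mg ~ queens$age_class))
  expect_lt(fit[["Pr(>F)"]][1], 0.01)
  expect_gt(mean(cb2$carbonyl_nmol_per_mg[31:60]),
            mean(cb2$carbonyl_nmol_per_mg[1:30]))
})

test_that("negative carbonyl draws are truncated at zero with a warning", {
  queens <- data.frame(queen_id = "Q1", age_class = "young", source = "AZ",
                       stringsAsFactors = FALSE)
  cfg <- study_config(carbonyl = list(young_mean = -5, old_mean = 1,
                                      source_shift = 0, sd = 0.1,
                                      taxon_link = numeric(0),
                                      protein_mg = 0.5, volume_ul = 100,
                                      path_cm = 1), seed = 10)
  set.seed(10)
  expect_warning(cb <- generate_carbonyl(cfg, queens), "truncated")
  expect_equal(cb$carbonyl_nmol_per_mg, 0)
  expect_equal(attr(cb, "n_truncated"), 1L)
})

test_that("rare-tail OTUs stay sporadic (low prevalence)", {
  cfg <- study_config(seed = 12)
  set.seed(12)
  cnt <- generate_counts(cfg, "rectum", "young", "AZ", 150)
  rare <- cnt[, grepl("^rare", colnames(cnt)), drop = FALSE]
  prev <- colMeans(rare > 0)
  expect_lt(stats::quantile(prev, 0.95), 0.2)
  expect_gt(sum(rare), 0)
})

test_that("study configurations read from YAML merge with the defaults", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_queens: {young_AZ: 5, old_AZ: 5}",
               "qpcr_sdlog: 0.3",
               "seed: 17",
               "age_log2_effects:",
               "  rectum: {B_asteroides: 1.0}",
               "carbonyl: {young_mean: 1.5, old_mean: 3.5}"), p)
  cfg <- read_study_config(p)
  expect_equal(cfg$qpcr_sdlog, 0.3)
  expect_equal(unname(cfg$age_log2_effects["rectum", "B_asteroides"]), 1)
  expect_equal(cfg$age_log2_effects["mouth", "L_firm5"], 0,
               ignore_attr = TRUE)
  expect_equal(cfg$carbonyl$old_mean, 3.5)
  expect_equal(cfg$carbonyl$sd, 0.75) # untouched default survives the merge
  st <- generate_study(cfg)
  expect_equal(nrow(st$otu$counts), 40)
})

test_that("a study round-trips through the file formats", {
  cfg <- study_config(n_queens = c(young_AZ = 3, old_AZ = 3),
                      n_rare_otus = 5, seed = 13)
  st <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  otu <- read_otu_table(file.path(dir, "counts.csv"), metadata = meta)
  expect_equal(otu$counts, st$otu$counts)
  q <- read_qpcr(file.path(dir, "qpcr.csv"))
  expect_equal(q$totals, st$qpcr$totals, tolerance = 1e-12)
  cb <- read_carbonyl(file.path(dir, "carbonyl.csv"))
  expect_equal(cb$carbonyl_nmol_per_mg, st$carbonyl$carbonyl_nmol_per_mg,
               tolerance = 1e-9)
})
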