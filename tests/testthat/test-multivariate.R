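test_that("Pillai trace matches the Type III cross-check on the unbalanced design", {
  skip_if_not_installed("car")
  set.seed(31)
  dat <- study_factors()
  Y <- matrix(rnorm(63 * 4), 63, 4) + 0.5 * (dat$age_class == "old")
  mine <- manova_pillai(Y, dat)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  fit <- stats::lm(Y ~ age_class * source, data = dat)
  s <- summary(car::Manova(fit, type = 3), multivariate = TRUE)
  options(old)
  for (t in c("age_class", "source", "age_class:source")) {
    mt <- s$multivariate.tests[[t]]
    V_car <- sum(diag(solve(mt$SSPE + mt$SSPH) %*% mt$SSPH))
    expect_equal(mine$pillai[mine$term == t], V_car, tolerance = 1e-10)
  }
})

test_that("identical group means give V = 0 and p = 1", {
  set.seed(32)
  g <- rep(c("young", "old"), each = 10)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  # force equal group means column by column
  for (j in 1:3) {
    Y[g == "old", j] <- Y[g == "old", j] - mean(Y[g == "old", j])
    Y[g == "young", j] <- Y[g == "young", j] - mean(Y[g == "young", j])
  }
  mv <- manova_pillai(Y, data.frame(age_class = g), ~ age_class)
  expect_equal(mv$pillai, 0, tolerance = 1e-10)
  expect_equal(mv$p_value, 1, tolerance = 1e-8)
})

test_that("a single response reduces Pillai to one-way ANOVA eta^2 and F", {
  set.seed(33)
  y <- rnorm(30) + rep(c(0, 1, 0), each = 10)
  g <- factor(rep(letters[1:3], each = 10))
  mv <- manova_pillai(y, data.frame(g = g), ~ g)
  a <- stats::anova(stats::lm(y ~ g))
  eta2 <- a$`Sum Sq`[1] / sum(a$`Sum Sq`)
  expect_equal(mv$pillai, eta2, tolerance = 1e-10)
  expect_equal(mv$approx_F, a$F[1], tolerance = 1e-10)
  expect_equal(mv$p_value, a$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Pillai is invariant to invertible recombination of responses", {
  set.seed(34)
  dat <- study_factors()
  Y <- matrix(rnorm(63 * 3), 63, 3)
  A <- matrix(c(2, 0.5, 0, 1, 1, 0, 0.3, 0, 1), 3, 3)
  v1 <- manova_pillai(Y, dat)$pillai
  v2 <- manova_pillai(Y %*% A, dat)$pillai
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("MANCOVA adjusts for the covariate and reports it as a term", {
  set.seed(35)
  dat <- study_factors()
  Y <- matrix(rnorm(63 * 3), 63, 3)
  # covariate tracks the first response almost exactly
  cov1 <- Y[, 1] + rnorm(63, 0, 1e-4)
  mv <- mancova_pillai(Y, dat, cov1, covariate_name = "log_carbonyl")
  expect_equal(mv$term[1], "log_carbonyl")
  expect_lt(mv$p_value[1], 1e-10)
  # constant covariate reduces to the MANOVA with a warning
  expect_warning(mv0 <- mancova_pillai(Y, dat, rep(2, 63)), "constant")
  expect_equal(as.data.frame(mv0), as.data.frame(manova_pillai(Y, dat)))
  # independent covariate leaves the factor test essentially unchanged
  set.seed(36)
  mv1 <- manova_pillai(Y, dat)
  mv2 <- mancova_pillai(Y, dat, rnorm(63))
  p1 <- mv1$p_value[mv1$term == "age_class"]
  p2 <- mv2$p_value[mv2$term == "age_class"]
  expect_lt(abs(p1 - p2), 0.2)
})

test_that("degenerate MANOVA inputs fail loudly", {
  dat <- study_factors()
  Y <- matrix(rnorm(63 * 2), 63, 2)
  Y2 <- cbind(Y, Y[, 1]) # singular error matrix
  expect_error(manova_pillai(Y2, dat), "panel")
  dat6 <- data.frame(age_class = rep(c("young", "old"), 3),
                     source = rep(c("CA", "AZ"), each = 3))
  expect_error(manova_pillai(matrix(rnorm(12), 6, 2), dat6,
                             ~ age_class * source), "responses|rank")
})

test_that("Tukey post hocs behave at the boundary cases", {
  set.seed(37)
  # two identical groups -> adjusted p in the ~1 region
  y <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  ph <- pairwise_posthoc(cbind(resp = y), g)
  expect_gte(ph$p_adj, 0.999)

  # with 2 groups Tukey equals the two-sample equal-variance t-test
  y2 <- rnorm(20); g2 <- rep(c("a", "b"), each = 10)
  ph2 <- pairwise_posthoc(cbind(resp = y2), g2)
  tt <- stats::t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(ph2$p_adj, tt$p.value, tolerance = 1e-8)

  # one group shifted by 5 sd stands out; the null pairs do not
  g4 <- rep(letters[1:4], each = 15)
  y4 <- rnorm(60) + 5 * (g4 == "d")
  ph4 <- pairwise_posthoc(cbind(resp = y4), g4)
  with_d <- grepl("d", ph4$comparison)
  expect_true(all(ph4$p_adj[with_d] < 0.001))
  expect_true(all(ph4$p_adj[!with_d] > 0.05))

  # singleton groups are excluded with a warning
  expect_warning(ph5 <- pairwise_posthoc(cbind(r = rnorm(11)),
                                         c(rep("a", 5), rep("b", 5), "c")),
                 "excluded")
  expect_equal(nrow(ph5), 1)
})

test_that("Wilcoxon screen is exact for small untied groups", {
  # {1,2} vs {3,4}: 6 assignments, 2 as extreme -> two-sided p = 1/3
  w <- wilcoxon_by_taxon(cbind(t1 = c(3, 4, 1, 2)),
                         c("old", "old", "young", "young"))
  expect_equal(w$p_raw, 1 / 3, tolerance = 1e-12)
  expect_equal(w$p_raw, enumerate_wilcox_p(c(3, 4), c(1, 2)),
               tolerance = 1e-12)

  # identical data -> p = 1
  w2 <- wilcoxon_by_taxon(cbind(t1 = rep(2, 8)),
                          rep(c("old", "young"), each = 4))
  expect_equal(w2$p_raw, 1)

  # normal approximation close to exact at n = 8 vs 8
  set.seed(38)
  x <- rnorm(8); y <- rnorm(8) + 0.5
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  approx_p <- wilcoxon_by_taxon(cbind(t = c(x, y)),
                                rep(c("old", "young"), each = 8),
                                exact_max = 0)$p_raw
  expect_lt(abs(exact_p - approx_p), 0.01)
})

test_that("multiplicity corrections follow the standard formulas", {
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  for (m in c("bonferroni", "bh", "by"))
    expect_equal(adjust_pvalues(c(1, 1), m), c(1, 1))
  set.seed(39)
  p <- runif(20)
  for (m in c("bonferroni", "bh", "by")) {
    adj <- adjust_pvalues(p, m)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(adjust_pvalues(1.2, "bh"), "\\[0, 1\\]")
})

test_that("Pearson CLR-carbonyl correlations match the closed form", {
  expect_equal(pearson_clr_carbonyl(cbind(t = 1:10), 2 * (1:10))$r, 1)
  expect_equal(pearson_clr_carbonyl(cbind(t = 1:10), -(1:10))$r, -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_clr_carbonyl(cbind(t = x), y)
  expect_equal(got$r, r_hand, tolerance = 1e-4)
  expect_equal(got$r, 0.9819805, tolerance = 1e-4)
  expect_warning(na <- pearson_clr_carbonyl(cbind(t = rep(1, 5)), rnorm(5)),
                 "zero-variance")
  expect_true(is.na(na$r))
})
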