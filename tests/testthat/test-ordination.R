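test_that("distance metrics follow their formulas", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 0, 6))
  expect_equal(as.matrix(distance_matrix(m, "bray_curtis"))["a", "b"], 0)
  expect_equal(as.matrix(distance_matrix(rbind(c(1, 0), c(0, 1)),
                                         "bray_curtis"))[1, 2], 1)
  expect_equal(as.matrix(distance_matrix(rbind(c(0, 0), c(3, 4)),
                                         "euclidean"))[1, 2], 5)
  expect_error(distance_matrix(rbind(c(0, 0), c(1, 1)), "bray_curtis"),
               "all-zero")
})

test_that("CLR PCA recovers rank structure and reconstructs its input", {
  set.seed(41)
  # rank-1 data: PC1 explains everything
  v <- rnorm(6)
  z1 <- outer(rnorm(20), v)
  ord1 <- pca_clr(z1)
  expect_equal(ord1$explained[1], 1, tolerance = 1e-10)

  z <- matrix(rnorm(30 * 5), 30, 5)
  ord <- pca_clr(z)
  # unit eigenvectors are orthonormal; scores reconstruct the centered data
  expect_equal(crossprod(ord$rotation), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  recon <- ord$scores %*% t(ord$rotation)
  expect_equal(recon, scale(z, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained fractions are non-increasing and sum to 1
  expect_true(all(diff(ord$explained) <= 1e-12))
  expect_equal(sum(ord$explained), 1, tolerance = 1e-9)
  # covariance-biplot loadings are rotation columns scaled by sd
  expect_equal(ord$loadings[, 1], ord$rotation[, 1] * ord$sdev[1],
               tolerance = 1e-10)
})

test_that("the carbonyl covariate projects as a correlation vector", {
  set.seed(42)
  z <- matrix(rnorm(40 * 4), 40, 4)
  ord0 <- pca_clr(z)
  carb <- ord0$scores[, 1] * 2 + rnorm(40, 0, 0.01)
  ord <- pca_clr(z, carbonyl = carb)
  expect_gt(abs(ord$carbonyl_vector[1]), 0.99)
  expect_true(all(abs(ord$carbonyl_vector) <= 1 + 1e-12))
})

test_that("ANOSIM separates what is separated and not what is not", {
  # two fully separated clusters: all between > all within -> R = 1
  m <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  d <- distance_matrix(m, "euclidean")
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, permutations = 199, seed = 43)
  expect_equal(res$R, 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  # R bounded and centered near 0 for random labels
  set.seed(44)
  d2 <- stats::dist(matrix(rnorm(24), 12, 2))
  r2 <- anosim_test(d2, sample(rep(c("a", "b"), 6)), 99, seed = 45)
  expect_true(r2$R >= -1 && r2$R <= 1)
})

test_that("ANOSIM agrees with the vegan implementation and with enumeration", {
  set.seed(46)
  m <- matrix(rpois(10 * 5, 20), 10, 5)
  g <- rep(c("a", "b"), each = 5)
  d <- distance_matrix(m, "bray_curtis")
  mine <- anosim_test(d, g, permutations = 999, seed = 47)
  veg <- vegan::anosim(d, g, permutations = 999)
  expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-10)

  # exhaustive p at n = 4 and n = 6 equals brute-force enumeration
  for (n1 in c(2, 3)) {
    n <- 2 * n1
    dm <- as.matrix(stats::dist(matrix(rnorm(n * 2), n, 2)))
    gg <- rep(c("a", "b"), each = n1)
    got <- anosim_test(dm, gg, permutations = "exhaustive")
    # oracle: enumerate assignments directly from the definition
    rank_d <- rank(dm[lower.tri(dm)])
    pi <- row(dm)[lower.tri(dm)]; pj <- col(dm)[lower.tri(dm)]
    M <- length(rank_d)
    r_of <- function(lab) {
      w <- lab[pi] == lab[pj]
      (mean(rank_d[!w]) - mean(rank_d[w])) / (M / 2)
    }
    combos <- utils::combn(n, n1)
    r_all <- apply(combos, 2, function(idx) {
      lab <- rep("b", n); lab[idx] <- "a"; r_of(lab)
    })
    expect_equal(got$p_value, mean(r_all >= r_of(gg) - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("ANOSIM is invariant to monotone transforms of the distances", {
  set.seed(48)
  dm <- as.matrix(stats::dist(matrix(rnorm(16), 8, 2)))
  g <- rep(c("a", "b"), each = 4)
  r1 <- anosim_test(dm, g, permutations = "exhaustive")
  r2 <- anosim_test(dm^2, g, permutations = "exhaustive")
  r3 <- anosim_test(sqrt(dm), g, permutations = "exhaustive")
  expect_equal(r1$R, r2$R)
  expect_equal(r1$R, r3$R)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("DistLM pseudo-F reduces to the classical regression F", {
  set.seed(49)
  x <- rnorm(25)
  y <- 1.5 * x + rnorm(25)
  d <- distance_matrix(cbind(y), "euclidean")
  dl <- distlm(d, x, permutations = 99, seed = 50)
  Freg <- unname(summary(stats::lm(y ~ x))$fstatistic[1])
  expect_equal(dl$pseudo_F, Freg, tolerance = 1e-8)
  expect_equal(dl$R2, summary(stats::lm(y ~ x))$r.squared, tolerance = 1e-8)
})

test_that("DistLM matches the PERMANOVA trace statistic on multivariate data", {
  set.seed(51)
  Y <- matrix(rpois(20 * 6, 15), 20, 6)
  x <- rnorm(20)
  d <- distance_matrix(Y, "bray_curtis")
  dl <- distlm(d, x, permutations = 99, seed = 52)
  ad <- vegan::adonis2(d ~ x, permutations = 99)
  expect_equal(dl$pseudo_F, ad$F[1], tolerance = 1e-8)
  expect_equal(dl$R2, ad$R2[1], tolerance = 1e-8)
})

test_that("DistLM R2 spans [0, 1] and hits 1 on predictor-determined distances", {
  # two predictor levels, zero within-level spread
  y <- rep(c(0, 10), each = 4)
  x <- rep(c(0, 1), each = 4)
  d <- distance_matrix(cbind(y), "euclidean")
  dl <- distlm(d, x, permutations = 99, seed = 53)
  expect_equal(dl$R2, 1, tolerance = 1e-10)
  expect_error(distlm(d, rep(1, 8)), "constant")
})
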