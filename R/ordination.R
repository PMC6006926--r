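#' Pairwise sample distances
#'
#' Bray-Curtis (the conventional companion of distance-based models on
#' abundance data, computed on non-negative abundances) or Euclidean
#' (appropriate for CLR scores). Bray-Curtis is undefined for all-zero
#' samples.
#'
#' @param x abundance or score matrix (samples x taxa).
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return a `dist` object with attribute `metric`.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "bray_curtis") {
    if (any(x < 0)) stop("Bray-Curtis requires non-negative abundances")
    if (any(rowSums(x) == 0))
      stop("all-zero sample: Bray-Curtis undefined")
    d <- vegan::vegdist(x, method = "bray")
  } else {
    d <- stats::dist(x, method = "euclidean")
  }
  attr(d, "metric") <- metric
  d
}

#' PCA of CLR scores with covariance-biplot scaling
#'
#' Eigendecomposition of the covariance of the (column-centered) CLR
#' matrix. Sample scores are the principal coordinates; taxon loadings use
#' covariance-biplot scaling, so each vector's length is proportional to
#' the standard deviation of that taxon's log-ratio to the rest of the
#' panel. An optional carbonyl covariate is projected as a supplementary
#' vector via its correlation with the sample scores.
#'
#' @param z CLR score matrix (samples x taxa), samples >= taxa recommended.
#' @param carbonyl optional numeric vector (one value per sample) rendered
#'   as a supplementary vector.
#' @return An object of class `clr_pca`: list with `scores`, `loadings`
#'   (taxa x components, sd-scaled), `rotation` (unit eigenvectors),
#'   `explained` (variance fractions), `sdev`, and `carbonyl_vector`
#'   (correlations of the covariate with each component) when supplied.
#' @export
pca_clr <- function(z, carbonyl = NULL) {
  z <- as.matrix(z)
  zc <- scale(z, center = TRUE, scale = FALSE)
  sv <- svd(zc)
  n <- nrow(zc)
  sdev <- sv$d / sqrt(n - 1)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rotation <- sv$v
  loadings <- rotation %*% diag(sdev, length(sdev))
  comp <- paste0("PC", seq_along(sv$d))
  dimnames(scores) <- list(rownames(z), comp)
  dimnames(rotation) <- dimnames(loadings) <- list(colnames(z), comp)
  ev <- sdev^2
  explained <- if (sum(ev) > 0) ev / sum(ev) else ev
  out <- list(scores = scores, loadings = loadings, rotation = rotation,
              sdev = sdev, explained = explained)
  if (!is.null(carbonyl)) {
    if (length(carbonyl) != n) stop("carbonyl must have one value per sample")
    keep <- sdev > 1e-12
    vec <- rep(0, length(sdev))
    vec[keep] <- suppressWarnings(cor(carbonyl, scores[, keep, drop = FALSE]))
    vec[is.na(vec)] <- 0
    names(vec) <- comp
    out$carbonyl_vector <- vec
  }
  structure(out, class = "clr_pca")
}

#' @export
print.clr_pca <- function(x, ...) {
  cat("CLR PCA: variance explained ",
      paste(sprintf("%s %.1f%%", names(x$explained) %||%
                      paste0("PC", seq_along(x$explained)),
                    100 * x$explained)[1:min(4, length(x$explained))],
            collapse = ", "), "\n")
  invisible(x)
}

anosim_r <- function(rank_d, within) {
  M <- length(rank_d)
  (mean(rank_d[!within]) - mean(rank_d[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of whether between-group distances exceed
#' within-group distances: R = (mean between-group rank - mean
#' within-group rank) / (M/2) with M = n(n-1)/2, R in \[-1, 1\]. The
#' p-value counts label permutations with R at least as large as observed,
#' the observed labeling included in numerator and denominator. For two
#' groups with few samples all distinct assignments can be enumerated
#' exhaustively (`permutations = "exhaustive"`), making the p-value exact.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param grouping group labels, at least 2 per group.
#' @param permutations number of random permutations (default 999), or
#'   `"exhaustive"` to enumerate all assignments (2 groups only).
#' @param seed optional RNG seed for the permutations.
#' @return list with `R`, `p_value`, `permutations`.
#' @export
anosim_test <- function(d, grouping, permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping must have one label per sample")
  sizes <- table(grouping)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups with at least 2 members each")
  rank_d <- rank(dm[lower.tri(dm)])
  pair_i <- row(dm)[lower.tri(dm)]
  pair_j <- col(dm)[lower.tri(dm)]
  within_of <- function(g) g[pair_i] == g[pair_j]
  R_obs <- anosim_r(rank_d, within_of(grouping))

  if (identical(permutations, "exhaustive")) {
    if (length(sizes) != 2)
      stop("exhaustive enumeration implemented for 2 groups")
    lab <- names(sizes)
    combos <- utils::combn(n, sizes[[1]])
    R_all <- apply(combos, 2, function(idx) {
      g <- rep(lab[2], n); g[idx] <- lab[1]
      anosim_r(rank_d, within_of(g))
    })
    p <- mean(R_all >= R_obs - 1e-12)
    return(list(R = R_obs, p_value = p, permutations = ncol(combos),
                exhaustive = TRUE))
  }
  if (permutations < 99)
    warning("fewer than 99 permutations: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  R_perm <- replicate(permutations, {
    anosim_r(rank_d, within_of(sample(grouping)))
  })
  p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (1 + permutations)
  list(R = R_obs, p_value = p, permutations = permutations,
       exhaustive = FALSE)
}

#' Distance-based linear model (DistLM)
#'
#' Regression of a distance matrix on predictors via Gower-centered inner
#' products: G = -1/2 J D^2 J with J = I - 11'/n; H is the hat matrix of
#' the centered predictor design; pseudo-F = \[tr(HGH)/m\] /
#' \[tr((I-H)G(I-H))/(n-m-1)\]; R^2 = tr(HGH)/tr(G). Significance is by
#' permutation: raw permutation of sample labels (equivalently, predictor
#' rows) by default, or permutation of residuals under the
#' intercept-only reduced model (`scheme = "residual"`; identical to raw
#' when there are no covariates, as here). On Euclidean distances of a
#' single response this reproduces the classical regression F exactly.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param predictors numeric vector or matrix of predictors (e.g. carbonyl
#'   per queen).
#' @param permutations number of permutations (default 999).
#' @param seed optional RNG seed.
#' @param scheme `"raw"` or `"residual"` permutation.
#' @return list with `pseudo_F`, `p_value`, `R2`, `df`.
#' @export
distlm <- function(d, predictors, permutations = 999, seed = NULL,
                   scheme = c("raw", "residual")) {
  scheme <- match.arg(scheme)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 4) stop("need at least 4 samples")
  X <- cbind(predictors)
  if (nrow(X) != n) stop("predictors must have one row per sample")
  if (any(!is.finite(X))) stop("predictors must be finite")
  if (any(apply(X, 2, stats::var) == 0)) stop("constant predictor")
  m <- ncol(X)
  G <- gower_center(dm)
  trG <- sum(diag(G))

  stat_num <- function(Xc) { # tr(HGH) for centered X; F is monotone in it
    H <- Xc %*% solve(crossprod(Xc), t(Xc))
    sum(H * G) # tr(HG) = tr(HGH) since H idempotent, G symmetric
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  num <- stat_num(Xc)
  pseudo_F <- (num / m) / ((trG - num) / (n - m - 1))
  R2 <- num / trG

  if (!is.null(seed)) set.seed(seed)
  F_perm <- replicate(permutations, {
    idx <- sample(n)
    # both schemes permute exchangeable units under the intercept-only null
    nump <- stat_num(Xc[idx, , drop = FALSE])
    (nump / m) / ((trG - nump) / (n - m - 1))
  })
  p <- (1 + sum(F_perm >= pseudo_F - 1e-12)) / (1 + permutations)
  list(pseudo_F = pseudo_F, p_value = p, R2 = R2,
       df = c(m, n - m - 1), permutations = permutations, scheme = scheme)
}

gower_center <- function(dm) {
  A <- -0.5 * dm^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}
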