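#' Fraction of zero cells in a count panel
#'
#' SparCC estimates are unreliable on sparse panels; the reliability flag
#' trips when more than 70% of cells are zero.
#'
#' @param counts count matrix (samples x taxa).
#' @return scalar zero fraction in \[0, 1\].
#' @export
sparsity_fraction <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0) return(0)
  sum(counts == 0) / length(counts)
}

# Posterior-mean fractions under a uniform (add-one) Dirichlet prior.
sparcc_fractions <- function(counts) {
  f <- counts + 1
  f / rowSums(f)
}

# Log-ratio variance matrix t_ij = var(log(x_i / x_j)).
logratio_variance <- function(frac) {
  lf <- log(frac)
  D <- ncol(lf)
  V <- apply(lf, 2, stats::var)
  C <- stats::cov(lf)
  Tm <- outer(V, V, "+") - 2 * C
  Tm[Tm < 0] <- 0
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(frac), colnames(frac))
  Tm
}

# Solve basis variances from t under the sparsity approximation, with an
# inclusion mask over pairs: t_i = d_i * w_i + sum_{j in inc(i)} w_j.
solve_basis_variances <- function(Tm, include) {
  D <- nrow(Tm)
  M <- include * 1
  diag(M) <- rowSums(include)
  t_i <- rowSums(Tm * include)
  w <- solve(M, t_i)
  w
}

basis_correlations <- function(Tm, w) {
  ww <- outer(w, w, "+")
  rho <- (ww - Tm) / (2 * sqrt(outer(w, w)))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

sparcc_core <- function(Tm, n_inner_iter, exclusion_threshold,
                        min_taxa = 4) {
  D <- nrow(Tm)
  include <- matrix(TRUE, D, D)
  diag(include) <- FALSE
  excluded_pairs <- 0L
  n_clipped <- 0L
  rho <- NULL
  for (iter in seq_len(max(1, n_inner_iter))) {
    w <- solve_basis_variances(Tm, include)
    if (any(w <= 0)) {
      n_clipped <- n_clipped + sum(w <= 0)
      w[w <= 0] <- 1e-10
    }
    rho <- basis_correlations(Tm, w)
    if (iter == max(1, n_inner_iter)) break
    cand <- abs(rho) * include
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- FALSE
    excluded_pairs <- excluded_pairs + 1L
    if (any(rowSums(include) < min_taxa - 1)) {
      warning("too many exclusions; returning partial result")
      break
    }
  }
  if (n_clipped > 0)
    warning(n_clipped, " negative basis variance estimate(s) clipped")
  list(rho = rho, omega = w, excluded_pairs = excluded_pairs)
}

#' SparCC basis correlations from compositional counts
#'
#' Estimates correlations among the unobserved absolute (basis) abundances
#' behind a compositional count panel. Counts are converted to fractions
#' with a uniform Dirichlet (add-one) prior; log-ratio variances
#' t_ij = var(log(x_i/x_j)) are decomposed as t_ij = w_i + w_j -
#' 2 rho_ij sqrt(w_i w_j) under the sparsity assumption that most pairs
#' are uncorrelated; the basis variances w are solved from the resulting
#' linear system and the strongest-correlated pair above
#' `exclusion_threshold` is excluded from the system each refinement
#' round. Pair significance is a two-sided bootstrap pseudo-p from
#' column-shuffled null datasets:
#' p = (1 + #\{|rho_boot| >= |rho_obs|\}) / (1 + n_boot).
#'
#' @param counts count matrix (samples x taxa), at least 4 taxa.
#' @param n_inner_iter refinement rounds of pair exclusion (default 20).
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded each round (default 0.1); 1 disables exclusion, giving the
#'   one-shot closed-form solution.
#' @param n_boot bootstrap shuffles for pseudo-p-values (default 100; 0
#'   skips them).
#' @param seed optional RNG seed for the bootstrap.
#' @return An object of class `sparcc`: list with `rho` (basis correlation
#'   matrix), `omega` (basis variances), `t` (log-ratio variance matrix),
#'   `pseudo_p` (or `NULL`), `sparsity_fraction`, `reliability_flag`
#'   (`TRUE` when sparsity exceeds 0.70), `excluded_pairs`.
#' @export
sparcc <- function(counts, n_inner_iter = 20, exclusion_threshold = 0.1,
                   n_boot = 100, seed = NULL) {
  counts <- as.matrix(counts)
  D <- ncol(counts)
  if (D < 4) stop("SparCC needs at least 4 taxa")
  sp <- sparsity_fraction(counts)
  frac <- sparcc_fractions(counts)
  Tm <- logratio_variance(frac)
  fit <- sparcc_core(Tm, n_inner_iter, exclusion_threshold)

  pseudo_p <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(counts)
    exceed <- matrix(0, D, D)
    for (b in seq_len(n_boot)) {
      shuf <- apply(counts, 2, function(col) col[sample.int(n)])
      fb <- suppressWarnings(
        sparcc_core(logratio_variance(sparcc_fractions(shuf)),
                    n_inner_iter, exclusion_threshold))
      exceed <- exceed + (abs(fb$rho) >= abs(fit$rho) - 1e-12)
    }
    pseudo_p <- (1 + exceed) / (1 + n_boot)
    diag(pseudo_p) <- NA
    dimnames(pseudo_p) <- dimnames(Tm)
  }
  structure(list(rho = fit$rho, omega = fit$omega, t = Tm,
                 pseudo_p = pseudo_p, sparsity_fraction = sp,
                 reliability_flag = sp > 0.70,
                 excluded_pairs = fit$excluded_pairs),
            class = "sparcc")
}

#' @export
print.sparcc <- function(x, ...) {
  cat(sprintf("sparcc: %d taxa, sparsity %.1f%%%s, %d pair(s) excluded\n",
              nrow(x$rho), 100 * x$sparsity_fraction,
              if (x$reliability_flag) " [UNRELIABLE: > 70% zeros]" else "",
              x$excluded_pairs))
  invisible(x)
}

#' SparCC edge list
#'
#' Flattens a [sparcc()] result into one row per taxon pair.
#'
#' @param fit a `sparcc` object.
#' @return data.frame with `taxon_a`, `taxon_b`, `rho`, `pseudo_p`.
#' @export
sparcc_edges <- function(fit) {
  rho <- fit$rho
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  data.frame(taxon_a = rownames(rho)[idx[, 1]],
             taxon_b = colnames(rho)[idx[, 2]],
             rho = rho[upper.tri(rho)],
             pseudo_p = if (is.null(fit$pseudo_p)) NA_real_
                        else fit$pseudo_p[upper.tri(rho)],
             stringsAsFactors = FALSE)
}
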