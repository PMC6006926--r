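#' Pillai-trace MANOVA on a CLR score matrix
#'
#' Multivariate analysis of variance with Pillai's trace, the statistic
#' robust to departures from multivariate normality and covariance
#' homogeneity. For each model term, the hypothesis cross-product matrix H
#' is formed from Type III (partial, order-invariant) sums of
#' cross-products under sum-to-zero contrasts -- required because the
#' queen design is slightly unbalanced (16/16/15/16) -- and Pillai's
#' V = sum(lambda / (1 + lambda)) over the eigenvalues lambda of
#' E^-1 H, with the standard (s, m, n) F approximation (exact when s = 1).
#'
#' @param Y numeric response matrix (samples x responses), e.g. the `z`
#'   matrix of a [clr_transform()]; a vector is treated as one response.
#' @param data data.frame of explanatory variables (character columns are
#'   converted to factors).
#' @param formula right-hand-side model formula over columns of `data`,
#'   default `~ age_class * source`, the study's two-way design.
#' @return An object of class `pillai_manova`: data.frame with one row per
#'   term (`term`, `df`, `pillai`, `approx_F`, `num_df`, `den_df`,
#'   `p_value`) plus the `H` and `E` matrices as attributes.
#' @export
manova_pillai <- function(Y, data, formula = ~ age_class * source) {
  Y <- cbind(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  data <- as.data.frame(data)
  for (j in seq_along(data))
    if (is.character(data[[j]])) data[[j]] <- factor(data[[j]])
  if (nrow(Y) != nrow(data)) stop("Y and data must have the same rows")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  term_of_col <- attr(X, "assign")
  term_labels <- attr(stats::terms(formula, data = data), "term.labels")

  n <- nrow(Y)
  r <- qr(X)$rank
  if (r < ncol(X)) stop("rank-deficient design matrix")
  df_res <- n - r
  p_resp <- ncol(Y)
  if (df_res <= p_resp)
    stop("residual df (", df_res, ") must exceed the number of responses (",
         p_resp, "); reduce the taxon panel")
  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  B <- XtXinv %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  if (rcond(E) < 1e-12)
    stop("singular error cross-product matrix; reduce the taxon panel")

  rows <- lapply(seq_along(term_labels), function(k) {
    idx <- which(term_of_col == k)
    Bk <- B[idx, , drop = FALSE]
    H <- t(Bk) %*% solve(XtXinv[idx, idx, drop = FALSE]) %*% Bk
    c(list(term = term_labels[k], df = length(idx)),
      pillai_stats(H, E, q = length(idx), df_res = df_res))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  structure(out, class = c("pillai_manova", "data.frame"),
            E = E, df_res = df_res)
}

# Pillai trace + F approximation from hypothesis/error cross-products.
pillai_stats <- function(H, E, q, df_res) {
  eig <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  eig <- pmax(eig, 0)
  V <- sum(eig / (1 + eig))
  p <- nrow(E)
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (df_res - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  list(pillai = V, approx_F = Fstat, num_df = df1, den_df = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' @export
print.pillai_manova <- function(x, ...) {
  cat("Pillai-trace MANOVA (Type III)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Pillai-trace MANCOVA with a biological-age covariate
#'
#' Identical machinery to [manova_pillai()] but with a numeric covariate
#' (typically log carbonyl) entered as a regression column, so the factor
#' terms are tested on covariate-adjusted cross-products and the covariate
#' itself is reported as a term. A constant covariate is dropped with a
#' warning (the model then reduces to the MANOVA).
#'
#' @inheritParams manova_pillai
#' @param covariate numeric vector (one value per sample).
#' @param covariate_name label for the covariate term.
#' @param formula factor part of the model, default `~ age_class * source`.
#' @return a `pillai_manova` with a leading covariate term.
#' @export
mancova_pillai <- function(Y, data, covariate,
                           covariate_name = "covariate",
                           formula = ~ age_class * source) {
  if (!is.numeric(covariate) || any(!is.finite(covariate)))
    stop("covariate must be finite numeric")
  data <- as.data.frame(data)
  if (stats::var(covariate) == 0) {
    warning("constant covariate dropped; reducing to MANOVA")
    return(manova_pillai(Y, data, formula))
  }
  data[[covariate_name]] <- covariate
  rhs <- paste(covariate_name, "+", paste(deparse(formula[[2]]), collapse = ""))
  manova_pillai(Y, data, stats::as.formula(paste("~", rhs)))
}

#' Tukey HSD post hoc comparisons per response
#'
#' For each response column, fits a one-way ANOVA across the cohorts and
#' reports studentized-range-adjusted pairwise comparisons. Groups with
#' fewer than 2 members are excluded with a warning.
#'
#' @param Y response matrix (samples x responses).
#' @param grouping factor of cohort labels (e.g. the four age x source
#'   cohorts).
#' @return data.frame with columns `response`, `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
pairwise_posthoc <- function(Y, grouping) {
  Y <- cbind(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  grouping <- factor(grouping)
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    warning("groups of size < 2 excluded: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- grouping %in% names(sizes)[sizes >= 2]
    Y <- Y[keep, , drop = FALSE]
    grouping <- droplevels(grouping[keep])
  }
  if (nlevels(grouping) < 2) stop("need at least 2 groups of size >= 2")
  out <- lapply(colnames(Y), function(resp) {
    fit <- stats::aov(Y[, resp] ~ grouping)
    tk <- stats::TukeyHSD(fit)$grouping
    data.frame(response = resp, comparison = rownames(tk),
               diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = tk[, "p adj"], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon rank-sum screen of old vs young abundance, per taxon
#'
#' Compares normalized abundance (or CLR scores) between age classes taxon
#' by taxon with the Wilcoxon rank-sum test -- exact enumeration when both
#' groups have at most 8 observations and no ties, the tie-corrected
#' normal approximation otherwise -- and reports Bonferroni,
#' Benjamini-Hochberg, and Benjamini-Yekutieli adjusted p-values across
#' the taxon family.
#'
#' @param x numeric matrix (samples x taxa).
#' @param age_class vector of `"young"`/`"old"` per sample.
#' @param exact_max largest per-group n for which the exact distribution
#'   is enumerated (default 8).
#' @return data.frame with columns `taxon`, `W`, `p_raw`, `p_bonferroni`,
#'   `p_bh`, `p_by`.
#' @export
wilcoxon_by_taxon <- function(x, age_class, exact_max = 8) {
  x <- cbind(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(ncol(x)))
  if (!all(age_class %in% AGE_LEVELS))
    stop("age_class must be 'young' or 'old'")
  old <- age_class == "old"
  if (sum(old) < 2 || sum(!old) < 2)
    stop("each age class needs at least 2 samples")
  res <- lapply(colnames(x), function(t) {
    a <- x[old, t]; b <- x[!old, t]
    if (all(c(a, b) == c(a, b)[1])) # degenerate: all values identical
      return(data.frame(taxon = t, W = length(a) * length(b) / 2,
                        p_raw = 1, stringsAsFactors = FALSE))
    use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
    data.frame(taxon = t, W = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- adjust_pvalues(out$p_raw, "bonferroni")
  out$p_bh <- adjust_pvalues(out$p_raw, "bh")
  out$p_by <- adjust_pvalues(out$p_raw, "by")
  out
}

#' Multiple-testing corrections
#'
#' Bonferroni, Benjamini-Hochberg (FDR step-up), and Benjamini-Yekutieli
#' (FDR under arbitrary dependence), all capped at 1 with monotonicity
#' enforced, via [stats::p.adjust()].
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method one of `"bonferroni"`, `"bh"`, `"by"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "by")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH",
                                by = "BY")[[method]])
}

#' Pearson correlations of taxon CLR scores with log carbonyl
#'
#' One correlation per taxon between its CLR score and the log-transformed
#' carbonyl value of the same queens, with the usual t-based p-value.
#' Zero-variance inputs yield `NA` with a warning.
#'
#' @param z CLR score matrix (samples x taxa).
#' @param log_carbonyl numeric vector aligned with the rows of `z`.
#' @return data.frame with columns `taxon`, `r`, `p_value`, `n`.
#' @export
pearson_clr_carbonyl <- function(z, log_carbonyl) {
  z <- cbind(z)
  if (is.null(colnames(z))) colnames(z) <- paste0("t", seq_len(ncol(z)))
  if (nrow(z) != length(log_carbonyl)) stop("z and log_carbonyl must align")
  if (nrow(z) < 3) stop("need at least 3 samples")
  if (any(!is.finite(log_carbonyl))) stop("log_carbonyl must be finite")
  res <- lapply(colnames(z), function(t) {
    x <- z[, t]
    if (stats::var(x) == 0 || stats::var(log_carbonyl) == 0) {
      warning("zero-variance input for taxon ", t, "; correlation undefined")
      return(data.frame(taxon = t, r = NA_real_, p_value = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, log_carbonyl, method = "pearson")
    data.frame(taxon = t, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
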