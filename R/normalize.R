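#' Estimate bacterial cell abundances from read proportions
#'
#' Read counts are proportional to 16S gene copies: a taxon's share of the
#' qPCR community size `T` is `T * p_i`, in gene copies, and dividing by
#' its per-genome copy number `c_i` converts gene copies to cells,
#'
#'   cells_i = T * p_i / c_i.
#'
#' The copy-number-weighted total is conserved: sum(cells_i * c_i) =
#' T * sum(p_i). The literal product `T * p_i * c_i` (no division) is kept
#' behind `direction = "multiply"` for sensitivity checks only; it
#' double-counts multi-copy genomes and does not conserve the qPCR total.
#'
#' @param p non-negative proportions (need not sum to 1 when the panel
#'   excludes the pooled tail).
#' @param copy_numbers positive copy numbers aligned with `p`, or a
#'   [copy_number_map()] (looked up by `names(p)`).
#' @param total qPCR total 16S gene copies for the sample (positive).
#' @param direction `"divide"` (cells; default) or `"multiply"`
#'   (literal product, sensitivity variant).
#' @return numeric vector of estimated cell counts, named like `p`.
#' @export
cells_from_reads <- function(p, copy_numbers, total,
                             direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (any(p < 0)) stop("proportions must be non-negative")
  if (!is.finite(total) || total <= 0) stop("qPCR total must be positive")
  if (inherits(copy_numbers, "copy_number_map"))
    copy_numbers <- copy_numbers_for(copy_numbers, names(p))
  if (length(copy_numbers) != length(p))
    stop("copy_numbers must align with p")
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive")
  if (direction == "divide") total * p / copy_numbers else total * p * copy_numbers
}

#' Pool the low-abundance tail into a single "other" cell count
#'
#' OTUs ranked 10-500 by dataset-wide raw reads are summed and corrected by
#' the community size and the mean copy number of the tail (4.2 by
#' default): other = T * sum(p) / default_mean.
#'
#' @param p_tail proportions of the pooled OTUs in the sample.
#' @param total qPCR total for the sample.
#' @param default_mean mean 16S copy number for the tail.
#' @return scalar estimated cell count of the pooled fraction.
#' @export
pool_low_abundance <- function(p_tail, total, default_mean = 4.2) {
  if (any(p_tail < 0)) stop("proportions must be non-negative")
  total * sum(p_tail) / default_mean
}

#' Copy-number-corrected relative abundances
#'
#' Rescales read proportions to cell proportions without reference to
#' community size: q_i = (p_i / c_i) / sum_j (p_j / c_j).
#'
#' @inheritParams cells_from_reads
#' @return proportions summing to 1.
#' @export
copy_corrected_proportions <- function(p, copy_numbers) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (sum(p) == 0) stop("all-zero proportion vector")
  if (inherits(copy_numbers, "copy_number_map"))
    copy_numbers <- copy_numbers_for(copy_numbers, names(p))
  q <- p / copy_numbers
  q / sum(q)
}

#' Rank OTUs by dataset-wide raw read totals
#'
#' Ranking used to define the top-9 / top-37 / top-200 panels; ties are
#' broken by OTU id so panels are deterministic.
#'
#' @param x an [otu_table()] or a count matrix.
#' @return character vector of OTU ids in decreasing read-total order.
#' @export
rank_otus <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else x
  totals <- colSums(counts)
  colnames(counts)[order(-totals, colnames(counts))]
}

#' Build the per-sample cell abundance table
#'
#' For every sample, converts the read proportions of a taxon panel (the
#' top `n_panel` OTUs by raw reads) into estimated cell counts via
#' [cells_from_reads()] and, when `pool_other = TRUE`, adds an `other`
#' column pooling the remaining OTUs via [pool_low_abundance()]. By default
#' proportions are taken over all OTUs in the table so that panel + other
#' exhausts the qPCR total; `renormalize_panel = TRUE` instead renormalizes
#' proportions within the panel (the panel then absorbs the full total).
#'
#' @param x an [otu_table()] (zero-read samples must be dropped first).
#' @param qpcr a [qpcr_table()] covering every sample.
#' @param copy_map a [copy_number_map()].
#' @param n_panel number of top OTUs kept as named columns.
#' @param panel explicit OTU panel (overrides `n_panel`); use this to apply
#'   a dataset-wide ranking to a per-niche subset.
#' @param pool_other add a pooled `other` column for the remaining OTUs.
#' @param renormalize_panel renormalize proportions over the panel only.
#' @return An object of class `cell_abundance`: list with `cells` (samples
#'   x panel matrix), `copy_numbers` used per column, `totals` used per
#'   sample, `panel`, and `metadata` carried over from `x`.
#' @export
cell_abundance <- function(x, qpcr, copy_map, n_panel = 9, panel = NULL,
                           pool_other = TRUE, renormalize_panel = FALSE) {
  stopifnot(inherits(x, "otu_table"), inherits(qpcr, "qpcr_table"),
            inherits(copy_map, "copy_number_map"))
  counts <- x$counts
  if (any(rowSums(counts) == 0))
    stop("zero-read samples present; call drop_empty_samples() first")
  miss <- setdiff(rownames(counts), names(qpcr$totals))
  if (length(miss) > 0)
    stop("samples missing qPCR totals: ", paste(miss, collapse = ", "))
  ranked <- rank_otus(counts)
  if (is.null(panel)) {
    panel <- ranked[seq_len(min(n_panel, length(ranked)))]
  } else {
    miss <- setdiff(panel, colnames(counts))
    if (length(miss) > 0)
      stop("panel OTUs absent from table: ", paste(miss, collapse = ", "))
  }
  tail_ids <- setdiff(ranked, panel)
  props <- counts / rowSums(counts)
  cn <- copy_numbers_for(copy_map, panel)
  totals <- qpcr$totals[rownames(counts)]

  p_panel <- props[, panel, drop = FALSE]
  if (renormalize_panel) {
    p_panel <- p_panel / rowSums(p_panel)
  }
  cells <- sweep(sweep(p_panel, 2, cn, "/"), 1, totals, "*")
  if (pool_other && !renormalize_panel && length(tail_ids) > 0) {
    p_tail <- rowSums(props[, tail_ids, drop = FALSE])
    cells <- cbind(cells, other = totals * p_tail / copy_map$default_mean)
    cn <- c(cn, other = copy_map$default_mean)
  }
  structure(list(cells = cells, copy_numbers = cn, totals = totals,
                 panel = colnames(cells), metadata = x$metadata),
            class = "cell_abundance")
}

#' @export
print.cell_abundance <- function(x, ...) {
  cat(sprintf("cell_abundance: %d samples x %d taxa (%s)\n",
              nrow(x$cells), ncol(x$cells),
              paste(utils::head(x$panel, 3), collapse = ", ")))
  invisible(x)
}

#' Centered log-ratio transform
#'
#' z_i = ln(x_i) - mean_j ln(x_j) per row. Zeros are handled by
#' multiplicative replacement before taking logs: each zero cell receives
#' mass `pseudo_frac` of its row total and the positive cells are shrunk by
#' the common factor that preserves the total, so the transform stays
#' invariant to per-sample scaling. Rows sum to zero by construction.
#'
#' @param x non-negative matrix (samples x taxa) or vector.
#' @param pseudo_frac fraction of the row total assigned to each zero cell
#'   (default 5e-5, half a read at a typical 10k-read depth).
#' @return An object of class `clr_matrix`: list with `z` (same shape as
#'   `x`) and the pseudocount policy.
#' @export
clr_transform <- function(x, pseudo_frac = 5e-5) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (any(x < 0)) stop("CLR input must be non-negative")
  if (any(rowSums(x) == 0)) stop("all-zero row: CLR undefined")
  xz <- t(apply(x, 1, function(r) {
    z <- r == 0
    if (any(z)) {
      total <- sum(r)
      r[z] <- pseudo_frac * total
      r[!z] <- r[!z] * (1 - sum(z) * pseudo_frac)
    }
    r
  }))
  lx <- log(xz)
  z <- lx - rowMeans(lx)
  dimnames(z) <- dimnames(x)
  if (vec) z <- drop(z)
  structure(list(z = z, pseudocount = list(policy = "multiplicative",
                                           pseudo_frac = pseudo_frac)),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  d <- dim(rbind(x$z))
  cat(sprintf("clr_matrix: %d samples x %d taxa, zero policy %s (%g)\n",
              d[1], d[2], x$pseudocount$policy, x$pseudocount$pseudo_frac))
  invisible(x)
}

#' CLR scores of a cell-abundance table
#'
#' Convenience wrapper applying [clr_transform()] to the `cells` matrix.
#'
#' @param ca a [cell_abundance()] object.
#' @param ... passed to [clr_transform()].
#' @return a `clr_matrix` with metadata attached as attribute `metadata`.
#' @export
clr_of_cells <- function(ca, ...) {
  out <- clr_transform(ca$cells, ...)
  attr(out, "metadata") <- ca$metadata
  out
}

#' Percent change in mean cell number with age
#'
#' 100 * (mean_old - mean_young) / mean_young. Because cell numbers are
#' non-negative the loss is bounded below at -100% (complete loss).
#'
#' @param mean_old,mean_young group means of estimated cell counts.
#' @return percent change; `NA` when `mean_young` is zero.
#' @export
percent_change_with_age <- function(mean_old, mean_young) {
  out <- ifelse(mean_young > 0, 100 * (mean_old - mean_young) / mean_young, NA_real_)
  unname(out)
}
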