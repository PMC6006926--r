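#' Per-taxon prevalence
#'
#' Fraction of samples in which a taxon is detected, under either
#' detection definition used for queen/worker comparisons: relative
#' abundance of at least 0.5% of the library (`rel_abund_ge_0.5pct`), or
#' at least two reads in the library (`reads_ge_2`). Threshold ties count
#' as detected.
#'
#' @param counts count matrix (samples x taxa) with positive row totals,
#'   or an [otu_table()].
#' @param definition detection rule.
#' @return named vector of prevalences in \[0, 1\].
#' @export
prevalence <- function(counts, definition = c("rel_abund_ge_0.5pct",
                                              "reads_ge_2")) {
  definition <- match.arg(definition)
  if (inherits(counts, "otu_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count table")
  if (any(rowSums(counts) == 0)) stop("zero-total sample in prevalence input")
  detected <- if (definition == "reads_ge_2") counts >= 2
              else counts / rowSums(counts) >= 0.005
  colMeans(detected)
}

#' Classify taxa as caste-specific, shared, or rare
#'
#' Applies the 50%-prevalence rule used to call longevity-phenotype
#' specificity: a taxon is specific to the caste in which its prevalence
#' reaches the threshold while staying below it in the other caste,
#' shared when both reach it, rare otherwise. Prevalence is expected
#' under the 0.5%-relative-abundance detection definition; optional
#' caste-wide mean relative abundances gate the call at
#' `abundance_threshold` (a caste only qualifies when its dataset-wide
#' average abundance of the taxon also reaches 0.5%). Ties count as
#' meeting a threshold. The rule is symmetric: swapping castes swaps
#' worker_specific and queen_specific.
#'
#' @param worker_prev,queen_prev per-taxon prevalences in \[0, 1\].
#' @param threshold prevalence cutoff (default 0.5).
#' @param worker_abund,queen_abund optional caste-wide mean relative
#'   abundances used as an additional gate.
#' @param abundance_threshold mean-abundance cutoff (default 0.005).
#' @return data.frame with `worker_prevalence`, `queen_prevalence`,
#'   `call` in worker_specific/queen_specific/shared/rare.
#' @export
classify_specificity <- function(worker_prev, queen_prev, threshold = 0.5,
                                 worker_abund = NULL, queen_abund = NULL,
                                 abundance_threshold = 0.005) {
  if (any(worker_prev < 0 | worker_prev > 1) ||
      any(queen_prev < 0 | queen_prev > 1))
    stop("prevalences must lie in [0, 1]")
  w <- worker_prev >= threshold
  q <- queen_prev >= threshold
  if (!is.null(worker_abund)) w <- w & worker_abund >= abundance_threshold
  if (!is.null(queen_abund)) q <- q & queen_abund >= abundance_threshold
  call <- ifelse(w & q, "shared",
          ifelse(w & !q, "worker_specific",
          ifelse(!w & q, "queen_specific", "rare")))
  data.frame(taxon = names(worker_prev) %||% seq_along(worker_prev),
             worker_prevalence = unname(worker_prev),
             queen_prevalence = unname(queen_prev),
             call = unname(call), stringsAsFactors = FALSE)
}

#' Project niche cell counts to a whole-gut profile per queen
#'
#' Sums each queen's estimated cell counts across her sampled niches and
#' renormalizes, giving the relative abundance expected from sequencing
#' the whole gut. Because the rectum carries the overwhelming majority of
#' cells, the projection is dominated by the rectum profile. Queens
#' missing niches are projected over the niches available, with a warning.
#'
#' @param ca a [cell_abundance()] built over all niches (its metadata
#'   links samples to queens).
#' @return matrix (queens x taxa) of whole-gut relative abundances; rows
#'   sum to 1.
#' @export
whole_gut_projection <- function(ca) {
  stopifnot(inherits(ca, "cell_abundance"))
  meta <- ca$metadata
  queens <- unique(meta$queen_id)
  n_niches <- length(unique(meta$niche))
  out <- matrix(0, length(queens), ncol(ca$cells),
                dimnames = list(queens, colnames(ca$cells)))
  short <- character(0)
  for (q in queens) {
    rows <- meta$queen_id == q
    if (sum(rows) < n_niches) short <- c(short, q)
    tot <- colSums(ca$cells[rows, , drop = FALSE])
    if (sum(tot) == 0) stop("queen ", q, " has zero total cells")
    out[q, ] <- tot / sum(tot)
  }
  if (length(short) > 0)
    warning("queens projected over fewer niches than sampled: ",
            paste(short, collapse = ", "))
  out
}

#' Alpha diversity of each library
#'
#' Observed OTU richness, Shannon entropy (-sum p ln p), and inverse
#' Simpson (1 / sum p^2) per sample.
#'
#' @param counts count matrix (samples x OTUs) or a single count vector.
#' @return data.frame with `sample_id`, `observed_otus`, `shannon`,
#'   `inv_simpson`.
#' @export
alpha_diversity <- function(counts) {
  counts <- rbind(counts)
  if (any(rowSums(counts) == 0)) stop("zero-total sample")
  data.frame(sample_id = rownames(counts) %||% seq_len(nrow(counts)),
             observed_otus = rowSums(counts > 0),
             shannon = vegan::diversity(counts, index = "shannon"),
             inv_simpson = vegan::diversity(counts, index = "invsimpson"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefaction curve for one library
#'
#' Expected OTU richness at each subsampling depth: exact by the
#' hypergeometric expectation formula, or Monte Carlo by averaging over
#' random subsamples without replacement. Depths beyond the library total
#' are `NA` in exact mode.
#'
#' @param x count vector for one library.
#' @param depths subsampling depths.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param n_draws Monte Carlo subsamples per depth (default 100).
#' @param seed optional RNG seed for Monte Carlo mode.
#' @return data.frame with `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(x, depths, mode = c("exact", "monte_carlo"),
                              n_draws = 100, seed = NULL) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  total <- sum(x)
  if (total <= 0) stop("library total must be positive")
  if (mode == "exact") {
    er <- rep(NA_real_, length(depths))
    ok <- depths <= total
    if (any(ok)) # rarefy's small-count advisory does not apply to E[S_d]
      er[ok] <- vapply(depths[ok], function(d)
        unname(suppressWarnings(vegan::rarefy(x, sample = d))), numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pool <- rep(seq_along(x), x)
    er <- vapply(depths, function(d) {
      if (d > total) return(NA_real_)
      mean(replicate(n_draws, length(unique(sample(pool, d)))))
    }, numeric(1))
  }
  data.frame(depth = depths, expected_richness = er)
}
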