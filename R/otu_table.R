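#' The four alimentary-tract niches sampled per queen
#'
#' Metadata validation is against this vocabulary; tokens are
#' case-sensitive.
#' @export
NICHE_LEVELS <- c("mouth", "midgut", "ileum", "rectum")

#' The two chronological age classes of the study design
#' @export
AGE_LEVELS <- c("young", "old")

#' Construct an OTU count table with sample metadata
#'
#' The central data container: a samples x OTUs matrix of non-negative
#' integer read counts plus one metadata record per sample. Downstream
#' modules (normalization, statistics, ordination) consume only this object;
#' no other function re-parses files.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Row and
#'   column names are the sample and OTU identifiers (case-sensitive).
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `queen_id`, `niche` (one of mouth/midgut/ileum/rectum),
#'   `age_class` (young/old), `source`, `age_months` (positive).
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   and `metadata`, metadata reordered to match the count rows.
#' @export
otu_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  metadata <- validate_metadata(metadata)
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing) > 0)
    stop("samples missing metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(empty) > 0)
    warning("samples with zero total reads flagged for exclusion: ",
            paste(empty, collapse = ", "))
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat("niches:", paste(names(table(x$metadata$niche)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Drop samples with zero total reads
#'
#' Mirrors the study convention of excluding failed libraries before
#' analysis (zero-read libraries carry no compositional information).
#'
#' @param x an [otu_table()].
#' @return the table restricted to samples with positive totals.
#' @export
drop_empty_samples <- function(x) {
  keep <- rowSums(x$counts) > 0
  if (all(keep)) return(x)
  message(sum(!keep), " zero-read sample(s) excluded")
  structure(list(counts = x$counts[keep, , drop = FALSE],
                 metadata = x$metadata[keep, , drop = FALSE]),
            class = "otu_table")
}

#' Subset an OTU table by sample or OTU
#'
#' @param x an [otu_table()].
#' @param samples,otus logical/integer/character index vectors; `NULL` keeps all.
#' @return the subsetted `otu_table`.
#' @export
subset_samples <- function(x, samples = NULL, otus = NULL) {
  counts <- x$counts
  meta <- x$metadata
  if (!is.null(samples)) {
    counts <- counts[samples, , drop = FALSE]
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  }
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, metadata = meta), class = "otu_table")
}

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata)
  req <- c("sample_id", "queen_id", "niche", "age_class", "source", "age_months")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad_niche <- setdiff(unique(metadata$niche), NICHE_LEVELS)
  if (length(bad_niche) > 0)
    stop("unknown niche value(s) ", paste(sQuote(bad_niche), collapse = ", "),
         "; allowed: ", paste(NICHE_LEVELS, collapse = ", "))
  bad_age <- setdiff(unique(metadata$age_class), AGE_LEVELS)
  if (length(bad_age) > 0)
    stop("unknown age_class value(s) ", paste(sQuote(bad_age), collapse = ", "),
         "; allowed: ", paste(AGE_LEVELS, collapse = ", "))
  metadata$age_months <- as.numeric(metadata$age_months)
  if (any(!is.finite(metadata$age_months)) || any(metadata$age_months <= 0))
    stop("age_months must be positive and finite")
  metadata
}

#' 16S rRNA gene copy numbers per genome
#'
#' Read counts are proportional to 16S gene copies, not cells; dividing by
#' the per-genome copy number converts gene-copy mass to cell abundance.
#' The study panel uses 4 copies for core species, 5 for
#' *Lactobacillus kunkeei*, 2 for *Bifidobacterium asteroides*, 1 for
#' *Parasaccharibacter apium* and Acetobacteraceae Alpha 2.1, and a mean of
#' 4.2 for the pooled low-abundance tail.
#'
#' @param copies named positive numeric vector, taxon -> copies per genome.
#' @param default_mean positive scalar used for taxa absent from `copies`
#'   and for the pooled "other" fraction.
#' @return An object of class `copy_number_map`.
#' @export
copy_number_map <- function(copies, default_mean = 4.2) {
  copies <- unlist(copies)
  if (is.null(names(copies)) || any(names(copies) == ""))
    stop("copies must be a named vector")
  if (any(!is.finite(copies)) || any(copies <= 0))
    stop("all copy numbers must be positive")
  if (!is.finite(default_mean) || default_mean <= 0)
    stop("default_mean must be positive")
  structure(list(copies = copies, default_mean = default_mean),
            class = "copy_number_map")
}

#' Look up copy numbers for a taxon panel
#'
#' Taxa absent from the map fall back to `default_mean` with a warning, the
#' convention used for OTUs whose genomes are uncharacterized.
#'
#' @param map a [copy_number_map()].
#' @param taxa character vector of taxon names.
#' @return named numeric vector of copy numbers, one per taxon.
#' @export
copy_numbers_for <- function(map, taxa) {
  out <- map$copies[taxa]
  names(out) <- taxa
  miss <- is.na(out)
  if (any(miss)) {
    warning("taxa missing from copy-number map, using default mean ",
            map$default_mean, ": ", paste(taxa[miss], collapse = ", "))
    out[miss] <- map$default_mean
  }
  out
}

#' qPCR community sizes per sample
#'
#' Total 16S rRNA gene copies per DNA extraction, the per-sample community
#' size used to convert relative to absolute abundance.
#'
#' @param totals named positive numeric vector, sample_id -> total copies.
#' @return An object of class `qpcr_table`.
#' @export
qpcr_table <- function(totals) {
  totals <- unlist(totals)
  if (is.null(names(totals)) || any(names(totals) == ""))
    stop("totals must be named by sample_id")
  if (anyDuplicated(names(totals)))
    stop("duplicate sample_id in qPCR totals")
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("qPCR totals must be positive")
  structure(list(totals = totals), class = "qpcr_table")
}
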