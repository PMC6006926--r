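#' Read an OTU count table
#'
#' Supports two dialects: a mothur-style "shared" TSV (columns `label`,
#' `Group`, `numOtus`, then one column per OTU) and a plain CSV with sample
#' ids in the first column and OTUs in the remaining columns. The dialect is
#' autodetected from the header unless `format` is given.
#'
#' @param path file to read.
#' @param format `"shared"`, `"csv"`, or `"auto"` (default) to detect from
#'   the header.
#' @param metadata optional data.frame passed to [otu_table()]; if `NULL`
#'   the raw count matrix is returned and metadata must be attached later
#'   with [otu_table()].
#' @return If `metadata` is supplied, an [otu_table()]; otherwise the bare
#'   count matrix with sample and OTU ids in file order.
#' @export
read_otu_table <- function(path, format = c("auto", "shared", "csv"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    header <- strsplit(readLines(path, n = 1), "[\t,]")[[1]]
    format <- if (all(c("label", "Group", "numOtus") %in% header)) "shared" else "csv"
  }
  if (format == "shared") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(tab)))
      stop("not a shared-format file: missing ", paste(setdiff(need, names(tab)), collapse = ", "))
    otu_cols <- setdiff(names(tab), need)
    if (any(tab$numOtus != length(otu_cols)))
      stop(sprintf("shared file declares numOtus=%d but has %d count columns",
                   tab$numOtus[1], length(otu_cols)))
    counts <- as.matrix(tab[, otu_cols, drop = FALSE])
    rownames(counts) <- tab$Group
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
  }
  check_count_matrix(counts)
  storage.mode(counts) <- "double"
  if (any(rowSums(counts) == 0))
    warning("samples with zero total reads flagged for exclusion: ",
            paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  if (is.null(metadata)) counts else otu_table(counts, metadata)
}

check_count_matrix <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (!is.numeric(counts))
    stop("non-numeric count column present")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  invisible(counts)
}

#' Read per-sample metadata
#'
#' CSV with required columns `sample_id`, `queen_id`, `niche`, `age_class`,
#' `source`, `age_months`; niche and age_class are checked against the
#' allowed vocabularies.
#'
#' @param path CSV file.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read qPCR community sizes
#'
#' CSV with columns `sample_id`, `total_copies` (scientific notation
#' accepted).
#'
#' @param path CSV file.
#' @return a [qpcr_table()].
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "total_copies") %in% names(tab)))
    stop("qPCR file must have columns sample_id, total_copies")
  totals <- as.numeric(tab$total_copies)
  names(totals) <- tab$sample_id
  qpcr_table(totals)
}

#' Read a taxon copy-number map
#'
#' CSV with columns `taxon`, `copies`; the pooled-tail mean is given
#' separately (default 4.2 copies per genome).
#'
#' @param path CSV file.
#' @param default_mean copy number used for unmapped taxa and the pooled
#'   low-abundance fraction.
#' @return a [copy_number_map()].
#' @export
read_copy_numbers <- function(path, default_mean = 4.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "copies") %in% names(tab)))
    stop("copy-number file must have columns taxon, copies")
  if (anyDuplicated(tab$taxon)) stop("duplicate taxon in copy-number file")
  copies <- as.numeric(tab$copies)
  names(copies) <- tab$taxon
  copy_number_map(copies, default_mean = default_mean)
}

#' Read carbonyl assay readings
#'
#' CSV with columns `queen_id`, `A345`, `path_cm`, `volume_ul`,
#' `protein_mg`. The derived nmol/mg value is computed on read with
#' [carbonyl_per_mg()].
#'
#' @param path CSV file.
#' @return data.frame with the input columns plus `carbonyl_nmol_per_mg`.
#' @export
read_carbonyl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("queen_id", "A345", "path_cm", "volume_ul", "protein_mg")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("carbonyl file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$queen_id)) stop("duplicate queen_id in carbonyl file")
  tab$carbonyl_nmol_per_mg <-
    carbonyl_per_mg(tab$A345, tab$path_cm, tab$volume_ul, tab$protein_mg)
  tab
}

#' Write result tables as deterministic TSVs
#'
#' Each element of `tables` (a data.frame) is written to
#' `<out_dir>/<name>.tsv` with a fixed field order and no row names, so
#' reruns with the same inputs produce byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(format_for_tsv(tables[[nm]]), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    paths <- c(paths, path)
  }
  invisible(paths)
}

format_for_tsv <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  }
  df
}
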