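#' Assemble and validate a pipeline run configuration
#'
#' A run takes either a `simulate` block (arguments to [study_config()])
#' or an `inputs` block of file paths (`counts`, `metadata`, `qpcr`,
#' `copy_numbers`, `carbonyl`), plus analysis settings. A seed is
#' mandatory whenever any stochastic stage runs (simulation,
#' permutation tests, SparCC bootstrap).
#'
#' @param simulate `NULL`, `TRUE` (default design), or a named list of
#'   [study_config()] overrides.
#' @param inputs named list of input file paths (ignored when simulating).
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed governing every stochastic stage.
#' @param panels panel sizes: `top` named taxa + pooled other (default 9),
#'   `mid` for ANOSIM/DistLM (default 37), `network` for SparCC (default
#'   200); truncated to the OTUs available.
#' @param permutations permutation count for ANOSIM and DistLM.
#' @param n_boot SparCC bootstrap shuffles.
#' @param correction multiplicity correction reported as `q` in the
#'   Table-1-style output (`"bh"`, `"by"`, `"bonferroni"`).
#' @param metric distance metric for ANOSIM/DistLM.
#' @param direction copy-number correction direction (see
#'   [cells_from_reads()]).
#' @param pseudo_frac CLR zero-replacement fraction.
#' @return validated `run_config` list.
#' @export
run_config <- function(simulate = TRUE, inputs = NULL, out_dir,
                       seed = NULL,
                       panels = list(top = 9, mid = 37, network = 200),
                       permutations = 999, n_boot = 100,
                       correction = "bh", metric = "bray_curtis",
                       direction = "divide", pseudo_frac = 5e-5) {
  cfg <- list(simulate = simulate, inputs = inputs, out_dir = out_dir,
              seed = seed, panels = panels, permutations = permutations,
              n_boot = n_boot, correction = correction, metric = metric,
              direction = direction, pseudo_frac = pseudo_frac)
  stochastic <- !is.null(simulate) && !isFALSE(simulate) ||
    permutations > 0 || n_boot > 0
  if (stochastic && is.null(seed))
    stop("seed is required: the run includes stochastic stages")
  if (is.null(simulate) || isFALSE(simulate)) {
    need <- c("counts", "metadata", "qpcr", "copy_numbers", "carbonyl")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0)
      stop("inputs missing: ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> normalize -> analyze -> report. Emits a
#' deterministic TSV bundle into `config$out_dir`:
#' `table1` (per-niche abundance class, percent change with age, Wilcoxon
#' q, per-taxon two-way F/p for age), `mancova` (Pillai terms per niche),
#' `pearson_carbonyl`, `ordination` (PCA scores + explained variance +
#' carbonyl vector), `anosim_distlm`, `sparcc_edges`, `prevalence` (+
#' `specificity` when a worker table is supplied), `whole_gut`,
#' `alpha_diversity`, and `run_log.txt` recording every analysis decision
#' and seed. Two runs with identical config and seed produce
#' byte-identical bundles.
#'
#' @param config a [run_config()].
#' @return invisibly, the list of result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  say("apicomp pipeline run")
  say("seed: %s", config$seed %||% "none")

  if (!is.null(config$simulate) && !isFALSE(config$simulate)) {
    sc_args <- if (isTRUE(config$simulate)) list() else config$simulate
    for (nm in c("n_queens", "concentration", "depth_mean", "qpcr_mean"))
      if (is.list(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
    sc_args$seed <- config$seed
    scfg <- do.call(study_config, sc_args)
    say("stage simulate: %d queens x %d niches", sum(scfg$n_queens),
        length(scfg$niches))
    study <- generate_study(scfg)
    otu <- study$otu
    qpcr <- study$qpcr
    carbonyl <- study$carbonyl
    copy_map <- default_copy_numbers()
  } else {
    say("stage load: %s", config$inputs$counts)
    meta <- read_metadata(config$inputs$metadata)
    otu <- read_otu_table(config$inputs$counts, metadata = meta)
    qpcr <- read_qpcr(config$inputs$qpcr)
    copy_map <- read_copy_numbers(config$inputs$copy_numbers)
    carbonyl <- read_carbonyl(config$inputs$carbonyl)
  }
  otu <- suppressMessages(drop_empty_samples(otu))
  say("retained samples: %d", nrow(otu$counts))
  unmapped <- setdiff(colnames(otu$counts), names(copy_map$copies))
  if (length(unmapped) > 0)
    say("taxa without copy numbers (default %.1f used): %d",
        copy_map$default_mean, length(unmapped))
  say("normalization direction: %s; CLR pseudo_frac: %g; metric: %s",
      config$direction, config$pseudo_frac, config$metric)
  say("panels: top %d (+other), mid %d, network %d; permutations: %d; boot: %d",
      config$panels$top, config$panels$mid, config$panels$network,
      config$permutations, config$n_boot)

  logcarb_of <- function(meta) {
    cb <- carbonyl$carbonyl_nmol_per_mg[match(meta$queen_id,
                                              carbonyl$queen_id)]
    suppressWarnings(log_carbonyl(cb))
  }
  ranked <- rank_otus(otu) # dataset-wide ranking defines every panel
  top_panel <- ranked[seq_len(min(config$panels$top, length(ranked)))]
  niches <- intersect(NICHE_LEVELS, unique(otu$metadata$niche))
  tab1 <- manc <- pear <- ords <- adlm <- edges <- list()
  ca_all <- cell_abundance(otu, qpcr, copy_map, panel = top_panel)

  for (ni in niches) {
    sub <- subset_samples(otu, otu$metadata$niche == ni)
    ca <- cell_abundance(sub, qpcr, copy_map, panel = top_panel)
    clr <- clr_of_cells(ca, pseudo_frac = config$pseudo_frac)
    meta <- ca$metadata
    z_panel <- clr$z[, setdiff(colnames(clr$z), "other"), drop = FALSE]
    lc <- logcarb_of(meta)

    # Table-1-style per-taxon summary
    old <- meta$age_class == "old"
    mean_old <- colMeans(ca$cells[old, , drop = FALSE])
    mean_young <- colMeans(ca$cells[!old, , drop = FALSE])
    share <- colMeans(ca$cells / rowSums(ca$cells))
    wil <- wilcoxon_by_taxon(ca$cells, meta$age_class)
    qcol <- paste0("p_", config$correction)
    per_taxon_F <- t(vapply(colnames(z_panel), function(t) {
      mv <- manova_pillai(clr$z[, t], meta, ~ age_class * source)
      unlist(mv[mv$term == "age_class", c("approx_F", "p_value")])
    }, numeric(2)))
    tab1[[ni]] <- data.frame(
      niche = ni, taxon = colnames(ca$cells),
      abundance_class = ifelse(share < 0.01, "L", "H"),
      percent_change = percent_change_with_age(mean_old, mean_young),
      wilcoxon_W = wil$W, wilcoxon_q = wil[[qcol]],
      manova_F = per_taxon_F[match(colnames(ca$cells),
                                   rownames(per_taxon_F)), 1],
      manova_p = per_taxon_F[match(colnames(ca$cells),
                                   rownames(per_taxon_F)), 2],
      row.names = NULL, stringsAsFactors = FALSE)

    mv <- mancova_pillai(z_panel, meta, lc, covariate_name = "log_carbonyl")
    manc[[ni]] <- cbind(niche = ni, as.data.frame(mv))
    pc <- pearson_clr_carbonyl(z_panel, lc)
    pear[[ni]] <- cbind(niche = ni, pc)

    ord <- pca_clr(z_panel, carbonyl = lc)
    ords[[ni]] <- data.frame(
      niche = ni, sample_id = meta$sample_id,
      PC1 = ord$scores[, 1], PC2 = ord$scores[, 2],
      explained_PC1 = ord$explained[1], explained_PC2 = ord$explained[2],
      carbonyl_PC1 = ord$carbonyl_vector[1],
      carbonyl_PC2 = ord$carbonyl_vector[2],
      row.names = NULL, stringsAsFactors = FALSE)

    mid_panel <- ranked[seq_len(min(config$panels$mid, length(ranked)))]
    cn_mid <- suppressWarnings(copy_numbers_for(copy_map, mid_panel))
    q_mid <- t(apply(sub$counts[, mid_panel, drop = FALSE], 1,
                     function(r) copy_corrected_proportions(r / sum(r), cn_mid)))
    d <- distance_matrix(q_mid, metric = if (config$metric == "euclidean")
      "euclidean" else "bray_curtis")
    an_age <- anosim_test(d, meta$age_class, config$permutations)
    an_src <- anosim_test(d, meta$source, config$permutations)
    dl <- distlm(d, lc, config$permutations)
    adlm[[ni]] <- data.frame(
      niche = ni,
      test = c("anosim_age", "anosim_source", "distlm_carbonyl"),
      statistic = c(an_age$R, an_src$R, dl$pseudo_F),
      p_value = c(an_age$p_value, an_src$p_value, dl$p_value),
      R2 = c(NA, NA, dl$R2), row.names = NULL, stringsAsFactors = FALSE)

    net_panel <- ranked[seq_len(min(config$panels$network, length(ranked)))]
    sp <- withCallingHandlers(
      sparcc(sub$counts[, net_panel, drop = FALSE], n_boot = config$n_boot),
      warning = function(w) {
        say("sparcc %s: %s", ni, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    say("sparcc %s: sparsity %.3f reliability_flag %s", ni,
        sp$sparsity_fraction, sp$reliability_flag)
    edges[[ni]] <- cbind(niche = ni, sparcc_edges(sp))
  }

  prev <- data.frame(
    taxon = ranked,
    prevalence_rel_abund = prevalence(otu$counts[, ranked, drop = FALSE],
                                      "rel_abund_ge_0.5pct"),
    prevalence_reads_ge_2 = prevalence(otu$counts[, ranked, drop = FALSE],
                                       "reads_ge_2"),
    row.names = NULL, stringsAsFactors = FALSE)
  wg <- whole_gut_projection(ca_all)
  wg_df <- cbind(queen_id = rownames(wg),
                 as.data.frame(wg, optional = TRUE))
  rownames(wg_df) <- NULL
  alpha <- alpha_diversity(otu$counts)

  tables <- list(table1 = do.call(rbind, tab1),
                 mancova = do.call(rbind, manc),
                 pearson_carbonyl = do.call(rbind, pear),
                 ordination = do.call(rbind, ords),
                 anosim_distlm = do.call(rbind, adlm),
                 sparcc_edges = do.call(rbind, edges),
                 prevalence = prev,
                 whole_gut = wg_df,
                 alpha_diversity = alpha)
  write_results(tables, config$out_dir)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(tables)
}
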