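#' Core taxon panel of the queen gut
#'
#' The nine conspicuous OTUs that dominate queen alimentary-tract
#' communities, in the package's canonical order.
#'
#' @return character vector of taxon ids.
#' @export
core_taxa <- function() {
  c("L_firm5", "P_apium", "L_kunkeei", "L_firm4", "Alpha2.1",
    "B_asteroides", "S_alvi", "G_apicola", "Delftia")
}

default_composition <- function() {
  taxa <- core_taxa()
  comp <- rbind(
    mouth  = c(0.030, 0.790, 0.130, 0.005, 0.030, 0.004, 0.002, 0.001, 0.008),
    midgut = c(0.050, 0.620, 0.250, 0.010, 0.040, 0.015, 0.004, 0.003, 0.008),
    ileum  = c(0.600, 0.150, 0.050, 0.070, 0.045, 0.050, 0.020, 0.008, 0.007),
    rectum = c(0.565, 0.090, 0.030, 0.160, 0.060, 0.070, 0.015, 0.007, 0.003))
  colnames(comp) <- taxa
  comp
}

#' Default 16S copy-number map for the core panel
#'
#' Four copies for core species, 5 for *L. kunkeei*, 2 for
#' *B. asteroides*, 1 for *P. apium* and Alpha 2.1 (assigned the value of
#' its closest characterized relative); pooled-tail mean 4.2.
#'
#' @return a [copy_number_map()].
#' @export
default_copy_numbers <- function() {
  copy_number_map(c(L_firm5 = 4, P_apium = 1, L_kunkeei = 5, L_firm4 = 4,
                    Alpha2.1 = 1, B_asteroides = 2, S_alvi = 4,
                    G_apicola = 4, Delftia = 4),
                  default_mean = 4.2)
}

#' Configuration of a synthetic queen-microbiota study
#'
#' Encodes the study design the generator emulates: 63 queens in four
#' (age class x source) cohorts (CA young/old n = 16 each, AZ young n = 15,
#' AZ old n = 16), each sampled in four gut niches. Counts are
#' Dirichlet-multinomial around niche-specific base compositions; qPCR
#' totals are lognormal around the niche community sizes (geometric means
#' 1.4e6 mouth, 1.42e7 midgut, 1.79e7 ileum, 1.212e8 rectum gene copies);
#' sequencing depths are Poisson around the niche library sizes (21k/25k/
#' 30k/38k reads). Age and source act as log2 fold changes on taxon
#' proportions before renormalization; carbonyl is Gaussian around
#' age-class means with an optional source shift and CLR-mediated taxon
#' links.
#'
#' @param n_queens named integer vector of cohort sizes, names
#'   `<age_class>_<source>`.
#' @param niches gut niches to simulate.
#' @param base_composition niche x taxon proportion matrix (rows sum to 1).
#' @param rare_mass fraction of each community in the rare tail (default
#'   0.012, the rare-biosphere mass of the core panel).
#' @param n_rare_otus number of sparse tail OTUs.
#' @param rare_prevalence per-sample presence probability of each tail OTU
#'   (kept at or below 0.10: tail OTUs are sporadic).
#' @param age_log2_effects,source_log2_effects niche x taxon matrices of
#'   log2 fold changes applied to old queens / CA-source queens.
#' @param concentration named per-niche Dirichlet concentration (larger =
#'   less compositional overdispersion).
#' @param depth_mean named per-niche expected reads per library.
#' @param qpcr_mean named per-niche geometric-mean total 16S copies.
#' @param qpcr_sdlog lognormal sdlog of qPCR totals.
#' @param carbonyl list with `young_mean`, `old_mean`, `source_shift`
#'   (added for CA queens), `sd`, `taxon_link` (named slopes on the queen's
#'   rectum CLR scores), and assay constants `protein_mg`, `volume_ul`,
#'   `path_cm` used to back-calculate plausible A345 readings.
#' @param seed integer RNG seed; every draw in [generate_study()] descends
#'   from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_queens = c(young_CA = 16, old_CA = 16,
                                      young_AZ = 15, old_AZ = 16),
                         niches = NICHE_LEVELS,
                         base_composition = default_composition(),
                         rare_mass = 0.012,
                         n_rare_otus = 60,
                         rare_prevalence = 0.08,
                         age_log2_effects = NULL,
                         source_log2_effects = NULL,
                         concentration = c(mouth = 50, midgut = 50,
                                           ileum = 50, rectum = 50),
                         depth_mean = c(mouth = 21000, midgut = 25000,
                                        ileum = 30000, rectum = 38000),
                         qpcr_mean = c(mouth = 1.4e6, midgut = 1.42e7,
                                       ileum = 1.79e7, rectum = 1.212e8),
                         qpcr_sdlog = 0.5,
                         carbonyl = list(young_mean = 2, old_mean = 4,
                                         source_shift = 0.5, sd = 0.75,
                                         taxon_link = numeric(0),
                                         protein_mg = 0.5, volume_ul = 100,
                                         path_cm = 1),
                         seed = 1L) {
  taxa <- colnames(base_composition)
  zero_fx <- matrix(0, nrow = length(niches), ncol = length(taxa),
                    dimnames = list(niches, taxa))
  if (is.null(age_log2_effects)) age_log2_effects <- zero_fx
  if (is.null(source_log2_effects)) source_log2_effects <- zero_fx
  cfg <- structure(list(
    n_queens = n_queens, niches = niches, taxa = taxa,
    base_composition = base_composition, rare_mass = rare_mass,
    n_rare_otus = n_rare_otus, rare_prevalence = rare_prevalence,
    age_log2_effects = age_log2_effects,
    source_log2_effects = source_log2_effects,
    concentration = concentration, depth_mean = depth_mean,
    qpcr_mean = qpcr_mean, qpcr_sdlog = qpcr_sdlog,
    carbonyl = carbonyl, seed = as.integer(seed)), class = "study_config")
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  stopifnot(length(cfg$n_queens) >= 1, all(cfg$n_queens >= 1))
  if (is.null(names(cfg$n_queens)) ||
      !all(grepl("^(young|old)_", names(cfg$n_queens))))
    stop("n_queens must be named '<age_class>_<source>'")
  comp <- cfg$base_composition
  if (!all(cfg$niches %in% rownames(comp)))
    stop("base_composition must have a row per niche")
  if (any(comp < 0)) stop("compositions must be non-negative")
  if (any(abs(rowSums(comp) - 1) > 1e-6))
    stop("base_composition rows must sum to 1")
  if (cfg$rare_mass < 0 || cfg$rare_mass >= 1) stop("rare_mass must be in [0, 1)")
  if (cfg$rare_prevalence < 0 || cfg$rare_prevalence > 0.10)
    stop("rare_prevalence must be in [0, 0.10] (tail OTUs are sporadic)")
  for (nm in c("concentration", "depth_mean", "qpcr_mean")) {
    v <- cfg[[nm]]
    if (!all(cfg$niches %in% names(v)))
      stop(nm, " must be named by niche")
    if (any(v[cfg$niches] <= 0)) stop(nm, " must be positive")
  }
  if (any(cfg$depth_mean[cfg$niches] < 100))
    stop("depth_mean must be at least 100 reads")
  if (cfg$qpcr_sdlog < 0) stop("qpcr_sdlog must be non-negative")
  if (cfg$carbonyl$sd < 0) stop("carbonyl sd must be non-negative")
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config: %d queens x %d niches, %d core + %d rare taxa, seed %d\n",
              sum(x$n_queens), length(x$niches), length(x$taxa),
              x$n_rare_otus, x$seed))
  invisible(x)
}

#' Read a study configuration from YAML
#'
#' Any field of [study_config()] may be overridden; matrices
#' (`base_composition`, effects) are given as named maps of named maps.
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  as_mat <- function(lst, niches, taxa, fill = 0) {
    m <- matrix(fill, length(niches), length(taxa),
                dimnames = list(niches, taxa))
    for (n in names(lst)) for (t in names(lst[[n]])) m[n, t] <- lst[[n]][[t]]
    m
  }
  niches <- raw$niches %||% NICHE_LEVELS
  taxa <- if (!is.null(raw$base_composition))
    unique(unlist(lapply(raw$base_composition, names))) else core_taxa()
  for (nm in c("n_queens", "concentration", "depth_mean", "qpcr_mean"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  for (nm in c("rare_mass", "n_rare_otus", "rare_prevalence", "qpcr_sdlog", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$niches)) args$niches <- niches
  if (!is.null(raw$base_composition))
    args$base_composition <- as_mat(raw$base_composition, niches, taxa)
  for (nm in c("age_log2_effects", "source_log2_effects"))
    if (!is.null(raw[[nm]])) args[[nm]] <- as_mat(raw[[nm]], niches, taxa)
  if (!is.null(raw$carbonyl)) {
    cb <- utils::modifyList(formals(study_config)$carbonyl |> eval(), raw$carbonyl)
    cb$taxon_link <- unlist(cb$taxon_link) %||% numeric(0)
    args$carbonyl <- cb
  }
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) stop("degenerate Dirichlet draw: all-zero concentration")
  g / sum(g)
}

#' Effect-shifted expected composition for one cohort
#'
#' Applies the configured age and source log2 fold changes
#' multiplicatively to the niche base composition and renormalizes.
#'
#' @param config a [study_config()].
#' @param niche,age_class,source cohort descriptors.
#' @return named proportion vector over the core taxa (summing to 1).
#' @export
expected_composition <- function(config, niche, age_class, source) {
  comp <- config$base_composition[niche, ]
  lfc <- numeric(length(comp))
  if (age_class == "old") lfc <- lfc + config$age_log2_effects[niche, ]
  if (source == "CA") lfc <- lfc + config$source_log2_effects[niche, ]
  comp <- comp * 2^lfc
  if (sum(comp) == 0) stop("all-zero composition after effects")
  comp / sum(comp)
}

#' Simulate OTU read counts for one cohort and niche
#'
#' For each sample: the core composition is shifted by the cohort's
#' effects, the rare-tail mass is split among the tail OTUs active in that
#' sample (each active independently with probability `rare_prevalence`),
#' a Dirichlet draw at the niche concentration supplies compositional
#' overdispersion, and reads are multinomial at a Poisson depth.
#'
#' @param config a [study_config()].
#' @param niche,age_class,source cohort descriptors.
#' @param n number of samples.
#' @param sample_ids optional row names.
#' @return integer count matrix, n x (core + rare) OTUs.
#' @export
generate_counts <- function(config, niche, age_class, source, n,
                            sample_ids = NULL) {
  if (!niche %in% config$niches) stop("unknown niche: ", niche)
  core <- expected_composition(config, niche, age_class, source)
  n_rare <- config$n_rare_otus
  rare_ids <- if (n_rare > 0)
    sprintf("rare%03d", seq_len(n_rare)) else character(0)
  otus <- c(names(core), rare_ids)
  out <- matrix(0L, nrow = n, ncol = length(otus),
                dimnames = list(sample_ids, otus))
  conc <- config$concentration[niche]
  depth_mean <- config$depth_mean[niche]
  for (i in seq_len(n)) {
    active <- if (n_rare > 0)
      stats::runif(n_rare) < config$rare_prevalence else logical(0)
    rare_p <- numeric(n_rare)
    mass <- config$rare_mass
    if (any(active)) {
      rare_p[active] <- mass * rdirichlet1(rep(1, sum(active)))
      comp <- c(core * (1 - mass), rare_p)
    } else {
      comp <- c(core, rare_p) # no tail drawn: core carries full mass
    }
    alpha <- conc * comp
    p <- numeric(length(alpha))
    pos <- alpha > 0
    p[pos] <- rdirichlet1(alpha[pos])
    depth <- stats::rpois(1, depth_mean)
    if (depth < 1) depth <- 1
    out[i, ] <- stats::rmultinom(1, size = depth, prob = p)
  }
  out
}

#' Simulate qPCR community sizes
#'
#' Lognormal totals with geometric mean equal to the niche's configured
#' community size.
#'
#' @param config a [study_config()].
#' @param niche niche name.
#' @param n number of samples.
#' @param sample_ids optional names.
#' @return named positive numeric vector of total 16S copies.
#' @export
generate_qpcr <- function(config, niche, n, sample_ids = NULL) {
  x <- stats::rlnorm(n, meanlog = log(config$qpcr_mean[niche]),
                     sdlog = config$qpcr_sdlog)
  names(x) <- sample_ids
  x
}

#' Simulate per-queen carbonyl records
#'
#' carbonyl = age-class mean + source shift (CA) + sum of taxon-link
#' slopes times the queen's rectum CLR score of each linked taxon +
#' Gaussian noise, truncated at zero (with a count of truncations
#' reported as attribute `n_truncated`). Assay readings (A345) consistent
#' with the value are back-calculated from the configured constants so the
#' record round-trips through [carbonyl_per_mg()].
#'
#' @param config a [study_config()].
#' @param queens data.frame with `queen_id`, `age_class`, `source`.
#' @param clr_link optional matrix of queen x taxon CLR scores (rectum)
#'   used by `taxon_link`; required when links are configured.
#' @return data.frame of carbonyl records (one per queen).
#' @export
generate_carbonyl <- function(config, queens, clr_link = NULL) {
  cb <- config$carbonyl
  mu <- ifelse(queens$age_class == "old", cb$old_mean, cb$young_mean) +
    ifelse(queens$source == "CA", cb$source_shift, 0)
  if (length(cb$taxon_link) > 0) {
    if (is.null(clr_link))
      stop("taxon_link configured but no CLR scores supplied")
    for (t in names(cb$taxon_link))
      mu <- mu + cb$taxon_link[[t]] * clr_link[queens$queen_id, t]
  }
  value <- mu + stats::rnorm(nrow(queens), 0, cb$sd)
  n_trunc <- sum(value < 0)
  if (n_trunc > 0) warning(n_trunc, " carbonyl draw(s) truncated at 0")
  value <- pmax(value, 0)
  out <- data.frame(
    queen_id = queens$queen_id,
    A345 = value * cb$protein_mg * 22 * cb$path_cm / cb$volume_ul,
    path_cm = cb$path_cm, volume_ul = cb$volume_ul,
    protein_mg = cb$protein_mg,
    carbonyl_nmol_per_mg = value,
    stringsAsFactors = FALSE)
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Generate a complete synthetic study
#'
#' One sample per queen x niche (252 at the default design), with qPCR
#' totals, metadata, and carbonyl records, plus a `truth` list recording
#' every nonzero injected effect for recovery testing. Fully reproducible:
#' the RNG is seeded from `config$seed` (or the `seed` argument).
#'
#' @param config a [study_config()].
#' @param seed optional override of `config$seed`.
#' @return list with elements `otu` ([otu_table()]), `qpcr`
#'   ([qpcr_table()]), `metadata`, `carbonyl` (data.frame), `truth`.
#' @export
generate_study <- function(config = study_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  cohorts <- do.call(rbind, lapply(names(config$n_queens), function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    data.frame(age_class = parts[1], source = paste(parts[-1], collapse = "_"),
               n = config$n_queens[[nm]], stringsAsFactors = FALSE)
  }))
  age_months_for <- function(age_class, source) {
    # cohort sampling ages: CA young 4.5, AZ young 5.7, CA old 16.5, AZ old 18
    ifelse(age_class == "young",
           ifelse(source == "CA", 4.5, 5.7),
           ifelse(source == "CA", 16.5, 18))
  }
  queens <- do.call(rbind, lapply(seq_len(nrow(cohorts)), function(i) {
    data.frame(age_class = cohorts$age_class[i], source = cohorts$source[i],
               idx = seq_len(cohorts$n[i]), stringsAsFactors = FALSE)
  }))
  queens$queen_id <- sprintf("Q%03d", seq_len(nrow(queens)))
  queens$age_months <- age_months_for(queens$age_class, queens$source)

  meta_list <- list()
  count_list <- list()
  qpcr_vec <- numeric(0)
  for (niche in config$niches) {
    ids <- paste(queens$queen_id, niche, sep = "_")
    for (i in seq_len(nrow(queens))) {
      count_list[[ids[i]]] <- generate_counts(
        config, niche, queens$age_class[i], queens$source[i], 1,
        sample_ids = ids[i])
    }
    qpcr_vec <- c(qpcr_vec, generate_qpcr(config, niche, nrow(queens), ids))
    meta_list[[niche]] <- data.frame(
      sample_id = ids, queen_id = queens$queen_id, niche = niche,
      age_class = queens$age_class, source = queens$source,
      age_months = queens$age_months, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, count_list)
  metadata <- do.call(rbind, meta_list)
  rownames(metadata) <- NULL
  otu <- otu_table(counts, metadata)

  clr_link <- NULL
  if (length(config$carbonyl$taxon_link) > 0) {
    rect <- counts[paste(queens$queen_id, "rectum", sep = "_"),
                   config$taxa, drop = FALSE]
    clr_link <- rbind(clr_transform(rect)$z)
    rownames(clr_link) <- queens$queen_id
  }
  carbonyl <- generate_carbonyl(config, queens, clr_link)

  fx <- function(m) {
    nz <- which(m != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(niche = rownames(m)[nz[, 1]], taxon = colnames(m)[nz[, 2]],
               log2_effect = m[nz], stringsAsFactors = FALSE)
  }
  truth <- list(age_effects = fx(config$age_log2_effects),
                source_effects = fx(config$source_log2_effects),
                carbonyl_age_difference =
                  config$carbonyl$old_mean - config$carbonyl$young_mean,
                carbonyl_source_shift = config$carbonyl$source_shift,
                carbonyl_taxon_link = config$carbonyl$taxon_link,
                seed = if (is.null(seed)) config$seed else seed)
  list(otu = otu, qpcr = qpcr_table(qpcr_vec), metadata = metadata,
       carbonyl = carbonyl, truth = truth)
}

#' Write a synthetic study to disk in the package's file formats
#'
#' Emits `counts.csv`, `metadata.csv`, `qpcr.csv`, `carbonyl.csv`,
#' `copy_numbers.csv` into `out_dir` so a simulated study can be rerun
#' through the file-based interface.
#'
#' @param study result of [generate_study()].
#' @param out_dir output directory.
#' @param copy_map copy-number map to write (default
#'   [default_copy_numbers()]).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, out_dir, copy_map = default_copy_numbers()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- as.data.frame(study$otu$counts)
  counts <- cbind(sample_id = rownames(counts), counts)
  utils::write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(study$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = names(study$qpcr$totals),
                              total_copies = unname(study$qpcr$totals)),
                   file.path(out_dir, "qpcr.csv"), row.names = FALSE)
  utils::write.csv(study$carbonyl[, c("queen_id", "A345", "path_cm",
                                      "volume_ul", "protein_mg")],
                   file.path(out_dir, "carbonyl.csv"), row.names = FALSE)
  utils::write.csv(data.frame(taxon = names(copy_map$copies),
                              copies = unname(copy_map$copies)),
                   file.path(out_dir, "copy_numbers.csv"), row.names = FALSE)
  invisible(out_dir)
}
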