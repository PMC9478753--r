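#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with defaults equal
#' to the individual functions' defaults, so a default `run_config()`
#' reproduces exactly what the stage functions do on their own. The
#' configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param out_dir Output directory.
#' @param seed Root seed; all stage RNG streams derive from it.
#' @param bin_size Grid bin size in bp.
#' @param n_chrom,chrom_length Synthetic genome shape.
#' @param n_cell_types Total cell types (reference + differentiated).
#' @param category_fractions Planted category proportions.
#' @param mean_segment_len Mean planted segment length (bins).
#' @param discordant Plant the reference-cell compartment discordance.
#' @param depth,dispersion,rt_log2_effect,contact_depth,decay_exponent,plaid_strength,tad_boost,mark_effect
#'   Passed to [sim_params()].
#' @param pseudocount RT and degree pseudocount.
#' @param span Smoothing span (bins).
#' @param alpha,min_seg,n_perm Segmentation controls.
#' @param coarse_factor Coarse/fine resolution ratio for compartment
#'   refinement (default 5, i.e. 500 kb over 100 kb).
#' @param tad_windows,boundary_quantile,min_child Domain-caller controls.
#' @param epsilon Classification dead zone.
#' @param counts,matrix_triples,matrix_chrom_sizes,reference_track
#'   Input paths for user-data mode (`counts` is a character vector of
#'   phase-count TSVs, reference cell type first).
#' @return A list of class `rt_run_config`.
#' @export
run_config <- function(out_dir = tempfile("rtarchitect_run_"), seed = 1L,
                       bin_size = 1e5, n_chrom = 1, chrom_length = 1e7,
                       n_cell_types = 5,
                       category_fractions = c(CE = 0.3, CL = 0.3, EtoL = 0.15,
                                              LtoE = 0.15, other = 0.1),
                       mean_segment_len = 5, discordant = FALSE,
                       depth = 100, dispersion = 0.02, rt_log2_effect = 1,
                       contact_depth = 50, decay_exponent = -1,
                       plaid_strength = 3, tad_boost = 2, mark_effect = 2,
                       pseudocount = 1, span = 3,
                       alpha = 0.01, min_seg = 3, n_perm = 1000,
                       coarse_factor = 5,
                       tad_windows = c(20, 10, 5), boundary_quantile = 0.1,
                       min_child = 3, epsilon = 0,
                       counts = NULL, matrix_triples = NULL,
                       matrix_chrom_sizes = NULL, reference_track = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "rt_run_config")
}

#' @rdname run_config
#' @param cfg A `rt_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$category_fractions <- as.list(out$category_fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm == "category_fractions") v <- unlist(v)
    base[[nm]] <- v
  }
  base
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' Sums `factor x factor` blocks of the count matrix, producing the
#' matrix that would have been observed at `factor`-times-coarser bins.
#'
#' @param m A [contact_matrix()].
#' @param factor Integer aggregation factor (>= 1).
#' @return A coarser [contact_matrix()].
#' @export
aggregate_contacts <- function(m, factor) {
  stopifnot(inherits(m, "contact_matrix"), factor >= 1)
  n <- n_bins(m)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  nc <- max(grp)
  agg <- rowsum(t(rowsum(m$counts, grp)), grp)
  contact_matrix(as.matrix(agg), chrom = m$chrom,
                 resolution = m$resolution * factor)
}

log_stage <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate -> RT -> compartments -> TADs -> features ->
#' comparisons in dependency order, writing every intermediate in its
#' standard plain-text format under `cfg$out_dir` and returning a run
#' manifest (inputs, outputs, parameters, seed, stage checksums, and —
#' in synthetic mode — recovery metrics against the planted truth).
#'
#' @param cfg A [run_config()].
#' @param mode `"synthetic"` (generate coupled inputs with planted
#'   truth) or `"user-data"` (read the paths named in `cfg`).
#' @return The manifest, invisibly also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_all <- function(cfg, mode = c("synthetic", "user-data")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "rt_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  outputs <- character(0)
  add_out <- function(p) outputs <<- c(outputs, p)
  params <- sim_params(depth = cfg$depth, dispersion = cfg$dispersion,
                       rt_log2_effect = cfg$rt_log2_effect,
                       contact_depth = cfg$contact_depth,
                       decay_exponent = cfg$decay_exponent,
                       plaid_strength = cfg$plaid_strength,
                       tad_boost = cfg$tad_boost,
                       mark_effect = cfg$mark_effect, seed = cfg$seed)
  metrics <- list()

  if (mode == "synthetic") {
    log_stage(log_path, "simulate", "building grid and planting truth")
    grid <- build_genome(cfg$n_chrom, cfg$chrom_length, cfg$bin_size)
    truth <- plant_truth(grid, cfg$category_fractions, cfg$mean_segment_len,
                         cfg$n_cell_types, seed = cfg$seed,
                         discordant = cfg$discordant)
    counts <- lapply(truth$cell_types, function(ct)
      simulate_phase_counts(truth, params, ct))
    names(counts) <- truth$cell_types
    for (ct in truth$cell_types)
      add_out(write_phase_counts(counts[[ct]],
                                 file.path(cfg$out_dir,
                                           paste0("counts_", ct, ".tsv"))))
    m_fine <- simulate_contacts(truth, params, "ref")
    write_contacts(m_fine, file.path(cfg$out_dir, "contacts_ref"))
    add_out(file.path(cfg$out_dir, "contacts_ref.triples.tsv"))
    orient_ref <- simulate_mark_signal(truth, params, "active", "ref")
  } else {
    for (p in c(cfg$counts, cfg$matrix_triples, cfg$matrix_chrom_sizes,
                cfg$reference_track)) {
      if (!is.null(p) && !file.exists(p))
        stop(sprintf("input file does not exist: %s", p), call. = FALSE)
    }
    if (length(cfg$counts) < 2)
      stop("user-data mode needs >= 2 phase-count files (reference first)",
           call. = FALSE)
    log_stage(log_path, "load", "reading user inputs")
    counts <- lapply(cfg$counts, read_phase_counts)
    names(counts) <- c("ref", paste0("diff", seq_along(cfg$counts)[-1] - 1))
    first <- counts[[1]]
    grid <- build_genome(length(unique(first$chrom)),
                         as.numeric(tapply(first$end, first$chrom, max)),
                         cfg$bin_size,
                         chrom_names = unique(first$chrom))
    truth <- NULL
    m_fine <- if (!is.null(cfg$matrix_triples))
      read_contacts(cfg$matrix_triples, cfg$matrix_chrom_sizes, cfg$bin_size)
    else NULL
    orient_ref <- if (!is.null(cfg$reference_track)) {
      bg <- read_bedgraph(cfg$reference_track)
      bin_signal_sum(bg, grid, label = "reference")
    } else NULL
  }

  log_stage(log_path, "rt", "computing and classifying RT profiles")
  profiles <- lapply(counts, function(pc)
    compute_rt(combine_phases(pc), pseudocount = cfg$pseudocount))
  profiles <- normalize_profiles(profiles)
  smoothed <- lapply(profiles, smooth_profile, span = cfg$span)
  for (ct in names(profiles))
    add_out(write_bedgraph(profiles[[ct]],
                           file.path(cfg$out_dir, paste0("rt_", ct, ".bedgraph"))))
  categories <- classify_rt(profiles[[1]], profiles[-1], epsilon = cfg$epsilon)
  cat_bed <- dplyr::mutate(categories, name = as.character(category))
  add_out(write_bed(cat_bed, file.path(cfg$out_dir, "rt_categories.bed")))
  segs <- segment_profile(smoothed[[1]], alpha = cfg$alpha,
                          min_seg = cfg$min_seg, n_perm = cfg$n_perm,
                          seed = cfg$seed)
  add_out(write_bed(segs, file.path(cfg$out_dir, "rt_segments_ref.bed")))

  compartments <- NULL
  degree <- NULL
  tads <- NULL
  if (!is.null(m_fine) && !is.null(orient_ref)) {
    log_stage(log_path, "compartments", "calling A/B compartments and degree")
    m_coarse <- aggregate_contacts(m_fine, cfg$coarse_factor)
    sel <- grid$chrom == m_fine$chrom
    compartments <- compartments_at_resolution(m_coarse, m_fine,
                                               orient_ref[sel, ])
    comp_track <- binned_signal(grid[sel, ], compartments$eigenvector,
                                label = "eigenvector")
    add_out(write_bedgraph(comp_track,
                           file.path(cfg$out_dir, "eigenvector.bedgraph")))
    degree <- compartmentalization_degree(m_fine, compartments,
                                          pseudocount = cfg$pseudocount)
    deg_track <- binned_signal(grid[sel, ], degree$degree, label = "degree")
    add_out(write_bedgraph(deg_track,
                           file.path(cfg$out_dir, "degree.bedgraph")))

    log_stage(log_path, "tads", "calling hierarchical domains")
    windows <- cfg$tad_windows[cfg$tad_windows * 2 + 1 <= n_bins(m_fine)]
    tads <- call_hierarchical_domains(m_fine, windows,
                                      cfg$boundary_quantile, cfg$min_child)
    tad_tbl <- dplyr::mutate(tads,
                             start = start_bin * cfg$bin_size,
                             end = end_bin * cfg$bin_size,
                             name = as.character(level))
    add_out(write_bed(tad_tbl, file.path(cfg$out_dir, "tads.bed")))
    readr::write_tsv(tads, file.path(cfg$out_dir, "tads.tsv"))
    add_out(file.path(cfg$out_dir, "tads.tsv"))
  }

  log_stage(log_path, "features", "assembling the feature table")
  signals <- list()
  if (mode == "synthetic") {
    for (mk in c("active", "repressive", "accessibility"))
      signals[[mk]] <- simulate_mark_signal(truth, params, mk, "ref")
  }
  chrom1 <- if (!is.null(m_fine)) m_fine$chrom else grid$chrom[1]
  sel <- grid$chrom == chrom1
  ft <- build_feature_table(
    categories[sel, ],
    compartments = compartments,
    degree = degree,
    rt_profiles = lapply(profiles, function(p) p[sel, ]),
    signals = lapply(signals, function(s) s[sel, ])
  )
  readr::write_tsv(ft, file.path(cfg$out_dir, "feature_table.tsv"))
  add_out(file.path(cfg$out_dir, "feature_table.tsv"))

  log_stage(log_path, "compare", "category comparisons")
  comparisons <- NULL
  if (length(signals) > 0) {
    comparisons <- dplyr::bind_rows(lapply(names(signals), function(nm)
      category_comparisons(ft, nm)))
    readr::write_tsv(comparisons, file.path(cfg$out_dir, "comparisons.tsv"))
    add_out(file.path(cfg$out_dir, "comparisons.tsv"))
  }
  composition <- NULL
  if (!is.null(compartments)) {
    composition <- compartment_composition(categories[sel, ], compartments)
    readr::write_tsv(composition, file.path(cfg$out_dir,
                                            "compartment_composition.tsv"))
    add_out(file.path(cfg$out_dir, "compartment_composition.tsv"))
  }

  if (mode == "synthetic") {
    log_stage(log_path, "score", "scoring recovery against planted truth")
    metrics$category_accuracy <-
      mean(as.character(categories$category) ==
             truth$categories$category)
    if (!is.null(compartments)) {
      tc <- truth$compartments$ref[sel]
      pc <- compartments$compartment
      ok <- pc %in% c("A", "B")
      metrics$compartment_agreement <- mean(pc[ok] == tc[ok])
    }
    if (!is.null(tads)) {
      tb <- sort(unique(c(truth$tads$ref$start_bin[truth$tads$ref$chrom == chrom1])))
      cb <- sort(unique(tads$start_bin[tads$level == 0]))
      if (length(cb) > 0 && length(tb) > 0)
        metrics$tad_boundary_mae <-
          mean(vapply(cb, function(b) min(abs(tb - b)), numeric(1)))
    }
  }

  manifest <- list(
    mode = mode, seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs)),
    metrics = metrics
  )
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(log_path, "done", sprintf("outputs in %s", cfg$out_dir))
  invisible(manifest)
}
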