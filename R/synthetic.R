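#' Simulation parameters for the coupled synthetic generators
#'
#' Bundles every tunable of the synthetic Repli-seq / Hi-C / chromatin-mark
#' generators. Defaults are the package's reference study conditions: a
#' sequencing depth and signal-to-noise at which the planted architecture
#' is recoverable by the downstream pipeline, with overdispersion and
#' distance decay in the range routinely seen in binned sequencing data.
#'
#' @param depth Mean Repli-seq reads per bin per S-phase fraction
#'   (default 100).
#' @param dispersion Negative-binomial overdispersion of read counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param rt_log2_effect Planted RT effect size: early bins have expected
#'   combined-early over combined-late ratio `2^rt_log2_effect`
#'   (default 1, i.e. |E[RT]| of about 1 log2 unit).
#' @param contact_depth Expected Hi-C contacts between adjacent bins
#'   before structural boosts (default 50).
#' @param decay_exponent Power-law exponent of contact distance decay;
#'   must be negative (default -1).
#' @param plaid_strength Multiplicative boost for contacts between bins in
#'   the same planted compartment; >= 1, 1 disables the plaid
#'   (checkerboard) pattern.
#' @param tad_boost Multiplicative intra-domain contact boost applied once
#'   per shared nesting level; >= 1, 1 disables domains.
#' @param mark_effect Mean shift of a chromatin-mark signal between its
#'   preferred and non-preferred RT state (default 2).
#' @param mark_baseline Baseline mark signal mean (default 5).
#' @param mark_sd Gaussian standard deviation of mark signal (default 1).
#' @param seed Root RNG seed for all generators using these parameters.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(depth = 100, dispersion = 0.02, rt_log2_effect = 1,
                       contact_depth = 50, decay_exponent = -1,
                       plaid_strength = 1, tad_boost = 1,
                       mark_effect = 2, mark_baseline = 5, mark_sd = 1,
                       seed = 1L) {
  if (depth < 0) stop("`depth` must be non-negative", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be non-negative", call. = FALSE)
  if (decay_exponent >= 0) stop("`decay_exponent` must be negative", call. = FALSE)
  if (plaid_strength < 1) stop("`plaid_strength` must be >= 1", call. = FALSE)
  if (tad_boost < 1) stop("`tad_boost` must be >= 1", call. = FALSE)
  structure(
    list(depth = depth, dispersion = dispersion,
         rt_log2_effect = rt_log2_effect, contact_depth = contact_depth,
         decay_exponent = decay_exponent, plaid_strength = plaid_strength,
         tad_boost = tad_boost, mark_effect = mark_effect,
         mark_baseline = mark_baseline, mark_sd = mark_sd,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Deterministic sub-seed so each generator/cell-type pair gets its own
# reproducible stream from one root seed. Kept below 2^31.
derive_seed <- function(seed, ...) {
  tag <- paste(..., collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 268435399
  as.integer((as.numeric(seed) * 7919 + h) %% 268435399)
}

rt_categories <- c("CE", "CL", "EtoL", "LtoE", "other")

#' Plant a ground-truth genome architecture on a bin grid
#'
#' Draws contiguous segments of RT categories (geometric segment lengths),
#' derives per-cell-type early/late RT states from the category
#' definitions, ties A/B compartment labels to RT state, and nests
#' domain (TAD) truth with small nested domains over early regions and
#' large flat domains over late regions. Everything downstream of the
#' generators can be scored against this object.
#'
#' Category semantics across one reference (stem) cell type and `n - 1`
#' differentiated types: `CE` is early everywhere, `CL` late everywhere,
#' `EtoL` early in the reference and late in every differentiated type,
#' `LtoE` the converse, and `other` bins get independent random states.
#'
#' @param grid A [build_genome()] bin grid.
#' @param category_fractions Named or positional proportions over
#'   `c("CE","CL","EtoL","LtoE","other")`; must sum to 1.
#' @param mean_segment_len Mean category segment length in bins
#'   (geometric; default 5 bins = 500 kb at 100-kb resolution, the scale
#'   of replication domains).
#' @param n_cell_types Total cell types including the reference
#'   (default 5: one stem + four differentiated).
#' @param seed RNG seed.
#' @param discordant If `TRUE`, reproduce the discordance scenario in the
#'   reference cell type: `EtoL` bins are planted in compartment B and
#'   `LtoE` bins in compartment A there, decoupling structure from the
#'   reference RT state (differentiated types stay concordant).
#'
#' @return A list of class `architecture_truth` with elements `grid`,
#'   `categories` (per-bin tibble), `rt_state` (per-bin tibble, one column
#'   per cell type, values "early"/"late"), `compartments` (same shape,
#'   values "A"/"B"), `tads` (named list of domain tibbles per cell
#'   type), `cell_types`, `seed`.
#' @export
plant_truth <- function(grid, category_fractions = c(CE = 0.3, CL = 0.3,
                                                     EtoL = 0.15, LtoE = 0.15,
                                                     other = 0.1),
                        mean_segment_len = 5, n_cell_types = 5,
                        seed = 1L, discordant = FALSE) {
  stopifnot(inherits(grid, "bin_grid"))
  if (n_cell_types < 2)
    stop("`n_cell_types` must be >= 2 (one reference + >= 1 differentiated)",
         call. = FALSE)
  fr <- category_fractions
  if (is.null(names(fr))) names(fr) <- rt_categories
  fr <- fr[rt_categories]
  if (anyNA(fr) || abs(sum(fr) - 1) > 1e-9)
    stop("`category_fractions` must cover CE/CL/EtoL/LtoE/other and sum to 1",
         call. = FALSE)

  cell_types <- c("ref", paste0("diff", seq_len(n_cell_types - 1)))
  set.seed(derive_seed(seed, "plant_truth"))

  category <- character(nrow(grid))
  for (chr in unique(grid$chrom)) {
    n <- sum(grid$chrom == chr)
    cat_chr <- character(0)
    while (length(cat_chr) < n) {
      len <- 1L + stats::rgeom(1, 1 / mean_segment_len)
      cat_chr <- c(cat_chr, rep(sample(rt_categories, 1, prob = fr), len))
    }
    category[grid$chrom == chr] <- cat_chr[seq_len(n)]
  }

  ref_state <- function(cat) ifelse(cat %in% c("CE", "EtoL"), "early", "late")
  diff_state <- function(cat) ifelse(cat %in% c("CE", "LtoE"), "early", "late")
  rt_state <- tibble::as_tibble(stats::setNames(
    lapply(cell_types, function(ct) {
      s <- if (ct == "ref") ref_state(category) else diff_state(category)
      oth <- category == "other"
      s[oth] <- sample(c("early", "late"), sum(oth), replace = TRUE)
      s
    }),
    cell_types
  ))

  compartments <- tibble::as_tibble(lapply(rt_state, function(s)
    ifelse(s == "early", "A", "B")))
  if (discordant) {
    compartments$ref[category == "EtoL"] <- "B"
    compartments$ref[category == "LtoE"] <- "A"
  }

  tads <- stats::setNames(
    lapply(cell_types, function(ct) plant_tads(grid, rt_state[[ct]])),
    cell_types
  )

  structure(
    list(grid = grid,
         categories = dplyr::mutate(tibble::as_tibble(grid), category = category),
         rt_state = rt_state, compartments = compartments, tads = tads,
         cell_types = cell_types, discordant = discordant, seed = seed),
    class = "architecture_truth"
  )
}

# Deterministic domain truth: early runs carry ~10-bin parents split into
# two nested children; late runs carry ~20-bin flat parents.
plant_tads <- function(grid, state, early_parent = 10L, late_parent = 20L,
                       min_child = 3L) {
  out <- list()
  for (chr in unique(grid$chrom)) {
    s <- state[grid$chrom == chr]
    r <- rle(s)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths  # 0-based bin offsets
    for (k in seq_along(r$lengths)) {
      size <- if (r$values[k] == "early") early_parent else late_parent
      a <- run_start[k]
      while (a < run_end[k]) {
        b <- min(a + size, run_end[k])
        if (run_end[k] - b < 2 * min_child) b <- run_end[k]
        dom <- tibble::tibble(chrom = chr, start_bin = a, end_bin = b,
                              level = 0L, parent = NA_integer_)
        if (r$values[k] == "early" && (b - a) >= 2 * min_child) {
          mid <- a + (b - a) %/% 2
          dom <- dplyr::bind_rows(
            dom,
            tibble::tibble(chrom = chr,
                           start_bin = c(a, mid), end_bin = c(mid, b),
                           level = 1L, parent = 0L)
          )
        }
        out[[length(out) + 1]] <- dom
        a <- b
      }
    }
  }
  doms <- dplyr::bind_rows(out)
  doms$domain_id <- seq_len(nrow(doms)) - 1L
  # resolve parent references: a level-1 child's parent is the preceding level-0 row
  parent_id <- rep(NA_integer_, nrow(doms))
  last_l0 <- NA_integer_
  for (i in seq_len(nrow(doms))) {
    if (doms$level[i] == 0L) last_l0 <- doms$domain_id[i]
    else parent_id[i] <- last_l0
  }
  doms$parent <- parent_id
  doms[, c("domain_id", "parent", "chrom", "start_bin", "end_bin", "level")]
}

#' Simulate binned Repli-seq S-phase fraction counts
#'
#' Draws negative-binomial read counts for the four S-phase fractions
#' (S1-S4) per bin. Early bins put the planted share of reads into
#' S1+S2 (split evenly), late bins into S3+S4, so that the expected
#' combined log2 ratio equals `+/- rt_log2_effect`.
#'
#' @param truth An [plant_truth()] architecture.
#' @param params A [sim_params()] object.
#' @param cell_type One of `truth$cell_types`.
#' @return A tibble with the grid columns plus `S1..S4` and `cell_type`.
#' @export
simulate_phase_counts <- function(truth, params, cell_type) {
  stopifnot(inherits(truth, "architecture_truth"), inherits(params, "sim_params"))
  if (!cell_type %in% truth$cell_types)
    stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE)
  set.seed(derive_seed(params$seed, "phase_counts", cell_type))

  n <- nrow(truth$grid)
  early <- truth$rt_state[[cell_type]] == "early"
  total <- 4 * params$depth
  p_early <- 2^params$rt_log2_effect / (1 + 2^params$rt_log2_effect)
  mu_early_side <- total * ifelse(early, p_early, 1 - p_early)
  mu_late_side <- total - mu_early_side

  draw <- function(mu) {
    if (params$depth == 0) return(integer(length(mu)))
    if (params$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
  }
  out <- tibble::as_tibble(truth$grid)
  out$S1 <- draw(mu_early_side / 2)
  out$S2 <- draw(mu_early_side / 2)
  out$S3 <- draw(mu_late_side / 2)
  out$S4 <- draw(mu_late_side / 2)
  out$cell_type <- cell_type
  out
}

#' Simulate an intra-chromosomal Hi-C contact matrix
#'
#' Expected contacts follow a power-law distance decay, multiplied by
#' `plaid_strength` when two bins share a planted compartment label and by
#' `tad_boost` once per planted domain (at any nesting level) containing
#' both bins; observed counts are Poisson. The matrix is symmetric by
#' construction.
#'
#' @inheritParams simulate_phase_counts
#' @param chrom Chromosome to simulate (default: first in the grid).
#' @return A [contact_matrix()].
#' @export
simulate_contacts <- function(truth, params, cell_type, chrom = NULL) {
  stopifnot(inherits(truth, "architecture_truth"), inherits(params, "sim_params"))
  if (!cell_type %in% truth$cell_types)
    stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE)
  grid <- truth$grid
  if (is.null(chrom)) chrom <- grid$chrom[1]
  sel <- grid$chrom == chrom
  n <- sum(sel)
  set.seed(derive_seed(params$seed, "contacts", cell_type, chrom))

  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- params$contact_depth * (1 + d)^params$decay_exponent

  comp <- truth$compartments[[cell_type]][sel]
  same <- outer(comp, comp, "==")
  mu <- mu * params$plaid_strength^same

  doms <- truth$tads[[cell_type]]
  doms <- doms[doms$chrom == chrom, ]
  if (nrow(doms) > 0 && params$tad_boost > 1) {
    shared <- matrix(0L, n, n)
    for (i in seq_len(nrow(doms))) {
      inside <- seq_len(n) > doms$start_bin[i] &
        seq_len(n) <= doms$end_bin[i]  # 1-based rows vs 0-based bins
      shared <- shared + outer(inside, inside)
    }
    mu <- mu * params$tad_boost^shared
  }

  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), mu[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom = chrom, resolution = bin_size_of(grid))
}

#' Simulate a binned chromatin-mark signal
#'
#' Gaussian per-bin signal (truncated at zero) whose mean is shifted by
#' `mark_effect` on the bins the mark prefers: early bins for an active
#' mark (e.g. H3K4me3) or an accessibility track (DHS), late bins for a
#' repressive heterochromatin mark (e.g. H3K9me3).
#'
#' @inheritParams simulate_phase_counts
#' @param mark One of `"active"`, `"repressive"`, `"accessibility"`.
#' @return A binned-signal tibble (grid columns plus `value`), with the
#'   mark role recorded in attribute `label`.
#' @export
simulate_mark_signal <- function(truth, params, mark = c("active", "repressive",
                                                         "accessibility"),
                                 cell_type) {
  mark <- match.arg(mark)
  stopifnot(inherits(truth, "architecture_truth"), inherits(params, "sim_params"))
  if (!cell_type %in% truth$cell_types)
    stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE)
  set.seed(derive_seed(params$seed, "mark", mark, cell_type))

  early <- truth$rt_state[[cell_type]] == "early"
  preferred <- if (mark == "repressive") !early else early
  mu <- params$mark_baseline + params$mark_effect * preferred
  val <- pmax(0, stats::rnorm(nrow(truth$grid), mu, params$mark_sd))
  binned_signal(truth$grid, val, label = mark)
}

#' Construct a binned signal track
#'
#' @param grid A `bin_grid`.
#' @param value Per-bin numeric values (NA = missing).
#' @param label Track label (e.g. `"gene_density"`, `"gc"`).
#' @return A tibble with the grid columns plus `value`; label kept in
#'   attribute `label`.
#' @export
binned_signal <- function(grid, value, label = "signal") {
  stopifnot(length(value) == nrow(grid))
  out <- dplyr::mutate(tibble::as_tibble(grid), value = as.numeric(value))
  attr(out, "label") <- label
  attr(out, "bin_size") <- bin_size_of(grid)
  out
}
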