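#' Bin interval features onto the grid
#'
#' Aggregates an interval set (genes, repeats, peaks) per bin. In
#' `count` mode a feature is assigned to the single bin containing its
#' midpoint (so gene density is "genes per bin" with no double
#' counting); in `coverage` mode each bin receives the number of feature
#' bp overlapping it, split exactly at bin boundaries.
#'
#' @param features A tibble with `chrom`, `start`, `end` (0-based
#'   half-open intervals).
#' @param grid A `bin_grid`.
#' @param mode `"count"` or `"coverage"`.
#' @param label Track label for the output.
#' @return A binned-signal tibble.
#' @export
bin_interval_density <- function(features, grid, mode = c("count", "coverage"),
                                 label = NULL) {
  mode <- match.arg(mode)
  if (is.null(label)) label <- paste0("density_", mode)
  check_intervals_on_grid(features, grid)
  val <- numeric(nrow(grid))
  if (mode == "count") {
    mid <- floor((features$start + features$end) / 2)
    idx <- bin_of_position(grid, features$chrom, mid)
    tab <- table(idx)
    val[as.integer(names(tab))] <- as.numeric(tab)
  } else {
    ov <- overlap_by_bin(features, grid)
    agg <- tapply(ov$overlap, ov$row, sum)
    val[as.integer(names(agg))] <- as.numeric(agg)
  }
  binned_signal(grid, val, label = label)
}

check_intervals_on_grid <- function(features, grid, bounds = TRUE) {
  cs <- chrom_sizes_of(grid)
  bad_chr <- !features$chrom %in% names(cs)
  if (any(bad_chr))
    stop(sprintf("interval on unknown chromosome: %s:%d-%d",
                 features$chrom[bad_chr][1],
                 features$start[bad_chr][1], features$end[bad_chr][1]),
         call. = FALSE)
  if (bounds) {
    off <- features$start < 0 | features$end > cs[features$chrom] |
      features$end <= features$start
    if (any(off))
      stop(sprintf("interval off chromosome: %s:%d-%d",
                   features$chrom[off][1], features$start[off][1],
                   features$end[off][1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Split intervals at bin boundaries: returns tibble(row = grid row,
# feature = feature row, overlap = bp).
overlap_by_bin <- function(features, grid) {
  bs <- bin_size_of(grid)
  pieces <- purrr::pmap_dfr(
    list(features$chrom, features$start, features$end, seq_len(nrow(features))),
    function(chr, s, e, fi) {
      b0 <- floor(s / bs)
      b1 <- floor((e - 1) / bs)
      b <- b0:b1
      ps <- pmax(s, b * bs)
      pe <- pmin(e, (b + 1) * bs)
      tibble::tibble(chrom = chr, bin = b, feature = fi, overlap = pe - ps)
    }
  )
  pieces$row <- match(paste(pieces$chrom, pieces$bin),
                      paste(grid$chrom, grid$bin))
  pieces[!is.na(pieces$row), ]
}

#' GC content per bin
#'
#' Fraction (G+C)/(A+C+G+T) of each bin's sequence; N and other ambiguous
#' bases are excluded from the denominator, and bins with no informative
#' base are missing.
#'
#' @param sequences A named [Biostrings::DNAStringSet] (names matching
#'   grid chromosomes), or a named character vector of sequences.
#' @param grid A `bin_grid`.
#' @return A binned-signal tibble labelled `"gc"`, values in `[0, 1]`.
#' @export
gc_per_bin <- function(sequences, grid) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  cs <- chrom_sizes_of(grid)
  for (chr in names(cs)) {
    if (!chr %in% names(sequences))
      stop(sprintf("no sequence for %s", chr), call. = FALSE)
    if (length(sequences[[chr]]) != cs[[chr]])
      stop(sprintf("sequence length mismatch for %s: %d vs %d", chr,
                   length(sequences[[chr]]), cs[[chr]]), call. = FALSE)
  }
  val <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    sub <- Biostrings::subseq(sequences[[grid$chrom[i]]],
                              grid$start[i] + 1L, grid$end[i])
    fr <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    informative <- sum(fr)
    if (informative == 0) return(NA_real_)
    unname((fr["G"] + fr["C"]) / informative)
  })
  binned_signal(grid, val, label = "gc")
}

#' Sum a coverage track into bins
#'
#' For a bedGraph-style track (non-overlapping intervals with a value),
#' each bin receives `sum(value * overlap_bp)` over the track intervals
#' it intersects, so the genome-wide total `sum(value * length)` is
#' conserved by binning.
#'
#' @param cov A tibble with `chrom`, `start`, `end`, `value`.
#' @param grid A `bin_grid`.
#' @param label Output label.
#' @return A binned-signal tibble.
#' @export
bin_signal_sum <- function(cov, grid, label = "signal_sum") {
  check_intervals_on_grid(cov, grid, bounds = FALSE)
  ord <- order(cov$chrom, cov$start)
  cc <- cov[ord, ]
  same <- cc$chrom[-1] == cc$chrom[-nrow(cc)]
  if (nrow(cc) > 1 && any(same & cc$start[-1] < cc$end[-nrow(cc)]))
    stop("overlapping intervals in coverage track", call. = FALSE)
  ov <- overlap_by_bin(cov, grid)
  contrib <- ov$overlap * cov$value[ov$feature]
  val <- numeric(nrow(grid))
  agg <- tapply(contrib, ov$row, sum)
  val[as.integer(names(agg))] <- as.numeric(agg)
  binned_signal(grid, val, label = label)
}

#' Subtract a scaled input track from a ChIP track
#'
#' The input (control) track is scaled so its genome-wide sum matches the
#' ChIP sum, then subtracted bin-wise; negative values are retained so
#' downstream rank comparisons are unaffected by flooring.
#'
#' @param chip,input Binned-signal tibbles on the same grid.
#' @return A binned-signal tibble; if the input sums to zero the
#'   subtraction is skipped, the result equals `chip` and attribute
#'   `input_subtracted` is `FALSE` (with a warning).
#' @export
subtract_input <- function(chip, input) {
  if (nrow(chip) != nrow(input) || !identical(chip$chrom, input$chrom))
    stop("chip and input are not on the same grid", call. = FALSE)
  s_chip <- sum(chip$value, na.rm = TRUE)
  s_input <- sum(input$value, na.rm = TRUE)
  if (s_input == 0) {
    warning("input track sums to zero; subtraction skipped", call. = FALSE)
    out <- chip
    attr(out, "input_subtracted") <- FALSE
    return(out)
  }
  out <- chip
  out$value <- chip$value - input$value * (s_chip / s_input)
  attr(out, "label") <- paste0(attr(chip, "label"), "_minus_input")
  attr(out, "input_subtracted") <- TRUE
  out
}

#' Restrict a signal to open-chromatin regions
#'
#' Either restricts a raw coverage track to the bp inside DHS peaks
#' before binning (`mode = "raw"`), or multiplies an already-binned
#' signal by the per-bin open-chromatin fraction (`mode = "binned"`).
#'
#' @param signal A coverage tibble (`raw` mode: `chrom`,`start`,`end`,
#'   `value`) or a binned-signal tibble (`binned` mode).
#' @param dhs A peak tibble with `chrom`, `start`, `end`.
#' @param grid A `bin_grid`.
#' @param mode `"raw"` or `"binned"`.
#' @return A binned-signal tibble with attribute `open_chromatin_mode`.
#' @export
mask_to_open_chromatin <- function(signal, dhs, grid,
                                   mode = c("raw", "binned")) {
  mode <- match.arg(mode)
  if (nrow(dhs) == 0) {
    warning("empty peak set; returning all-missing signal", call. = FALSE)
    out <- binned_signal(grid, rep(NA_real_, nrow(grid)), label = "masked")
    attr(out, "open_chromatin_mode") <- mode
    return(out)
  }
  check_intervals_on_grid(dhs, grid)
  if (mode == "raw") {
    clipped <- intersect_with_peaks(signal, dhs)
    out <- if (nrow(clipped) == 0)
      binned_signal(grid, numeric(nrow(grid)), label = "masked")
    else bin_signal_sum(clipped, grid, label = paste0(attr(signal, "label"),
                                                      "_open"))
  } else {
    open_frac <- bin_interval_density(merge_intervals(dhs), grid,
                                      mode = "coverage")
    open_frac$value <- open_frac$value / (grid$end - grid$start)
    out <- signal
    out$value <- signal$value * open_frac$value
  }
  attr(out, "open_chromatin_mode") <- mode
  out
}

# union of possibly-overlapping intervals, per chromosome
merge_intervals <- function(x) {
  dplyr::bind_rows(lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }))
}

# clip a valued track to the union of peak intervals
intersect_with_peaks <- function(track, peaks) {
  pk <- merge_intervals(peaks)
  dplyr::bind_rows(lapply(split(track, track$chrom), function(d) {
    p <- pk[pk$chrom == d$chrom[1], ]
    if (nrow(p) == 0) return(NULL)
    tr <- IRanges::IRanges(d$start + 1, d$end)
    pr <- IRanges::IRanges(p$start + 1, p$end)
    hits <- IRanges::findOverlaps(tr, pr)
    if (length(hits) == 0) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble::tibble(
      chrom = d$chrom[1],
      start = pmax(d$start[qi], p$start[si]),
      end = pmin(d$end[qi], p$end[si]),
      value = d$value[qi]
    )
  }))
}

#' Genomic annotation composition of RT categories
#'
#' For each RT category, the fraction of its bp lying in promoters,
#' exons, introns or intergenic space, with overlapping bp resolved by
#' the precedence promoter > exon > intron > intergenic. Fractions sum
#' to 1 per category.
#'
#' @param categories A category map from [classify_rt()] (or a truth
#'   categories tibble).
#' @param genes A tibble with `chrom`, `start`, `end`, `strand`; the TSS
#'   is `start` on `+` and `end - 1` on `-`.
#' @param exons Optional exon tibble (`chrom`, `start`, `end`); defaults
#'   to whole gene bodies (i.e. no introns).
#' @param promoter_flank Promoter half-width around the TSS in bp
#'   (default 1000).
#' @return A tibble with one row per category and columns `promoter`,
#'   `exon`, `intron`, `intergenic`, `total_bp`.
#' @export
annotation_composition <- function(categories, genes, exons = NULL,
                                   promoter_flank = 1000) {
  if (is.null(exons)) exons <- genes[, c("chrom", "start", "end")]
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  promoters <- tibble::tibble(chrom = genes$chrom,
                              start = pmax(0, tss - promoter_flank),
                              end = tss + promoter_flank)
  rows <- list()
  for (cat in levels(factor(categories$category))) {
    sel <- categories$category == cat
    if (!any(sel)) next
    bins <- categories[sel, ]
    ir_bins <- split_iranges(bins)
    total <- sum(bins$end - bins$start)
    ir_prom <- split_iranges(promoters)
    ir_exon <- split_iranges(exons)
    ir_gene <- split_iranges(genes)
    bp_prom <- overlap_bp(ir_bins, ir_prom)
    ir_exon_np <- chr_setdiff(ir_exon, ir_prom)
    bp_exon <- overlap_bp(ir_bins, ir_exon_np)
    ir_intron <- chr_setdiff(chr_setdiff(ir_gene, ir_exon), ir_prom)
    bp_intron <- overlap_bp(ir_bins, ir_intron)
    rows[[cat]] <- tibble::tibble(
      category = cat,
      promoter = bp_prom / total, exon = bp_exon / total,
      intron = bp_intron / total,
      intergenic = (total - bp_prom - bp_exon - bp_intron) / total,
      total_bp = total
    )
  }
  dplyr::bind_rows(rows)
}

split_iranges <- function(x) {
  lapply(split(x, x$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(d$start + 1, d$end)))
}

chr_setdiff <- function(a, b) {
  out <- lapply(names(a), function(chr) {
    if (is.null(b[[chr]])) a[[chr]] else IRanges::setdiff(a[[chr]], b[[chr]])
  })
  stats::setNames(out, names(a))
}

overlap_bp <- function(a, b) {
  sum(vapply(names(a), function(chr) {
    if (is.null(b[[chr]])) return(0)
    sum(IRanges::width(IRanges::intersect(a[[chr]], b[[chr]])))
  }, numeric(1)))
}

#' Signal meta-profile anchored at TSSs
#'
#' Mean signal in step-sized offset windows from `-flank` to `+flank`
#' around a set of anchors (TSSs), with minus-strand anchors reversed so
#' upstream is always on the left. Track gaps count as signal 0.
#'
#' @param track A coverage tibble (`chrom`, `start`, `end`, `value`),
#'   non-overlapping within the track.
#' @param anchors A tibble with `chrom`, `pos` (0-based bp), `strand`.
#' @param flank Half-width in bp; must be a multiple of `step`.
#' @param step Offset window size in bp.
#' @return A tibble with `offset` (window start relative to the anchor,
#'   bp) and `mean_signal`.
#' @export
anchored_profile <- function(track, anchors, flank = 1000, step = 50) {
  if (nrow(anchors) == 0) stop("no anchors supplied", call. = FALSE)
  if (flank %% step != 0)
    stop("`flank` must be a multiple of `step`", call. = FALSE)
  offsets <- seq(-flank, flank - step, by = step)
  acc <- matrix(0, nrow(anchors), length(offsets))
  for (i in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[i]; pos <- anchors$pos[i]
    tr <- track[track$chrom == chr, ]
    for (k in seq_along(offsets)) {
      a <- offsets[k]; b <- a + step
      if (anchors$strand[i] == "+") {
        gs <- pos + a; ge <- pos + b
      } else {
        gs <- pos - b + 1; ge <- pos - a + 1
      }
      ov <- pmin(tr$end, ge) - pmax(tr$start, gs)
      ov[ov < 0] <- 0
      acc[i, k] <- sum(ov * tr$value) / step
    }
  }
  tibble::tibble(offset = offsets, mean_signal = colMeans(acc))
}
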