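#' Combine the four S-phase fractions into early and late pools
#'
#' Repli-seq fractionates S-phase into four windows S1-S4; the two early
#' fractions and the two late fractions behave near-identically and are
#' pooled: `early = S1 + S2`, `late = S3 + S4`.
#'
#' @param pc A phase-count tibble (grid columns plus `S1..S4`), e.g. from
#'   [simulate_phase_counts()] or [read_phase_counts()].
#' @param grid Optional `bin_grid` to check alignment against.
#' @return The input tibble with `S1..S4` replaced by `early` and `late`.
#' @export
combine_phases <- function(pc, grid = NULL) {
  need <- c("S1", "S2", "S3", "S4")
  if (!all(need %in% names(pc)))
    stop("phase counts must have columns S1..S4", call. = FALSE)
  if (!is.null(grid)) check_grid_alignment(pc, grid, "phase counts")
  if (any(pc$S1 < 0 | pc$S2 < 0 | pc$S3 < 0 | pc$S4 < 0, na.rm = TRUE))
    stop("phase counts must be non-negative", call. = FALSE)
  dplyr::mutate(pc, early = S1 + S2, late = S3 + S4,
                .keep = "unused")
}

#' Pairwise similarity of the four S-phase fractions
#'
#' Computes the Spearman correlation over bins for every pair of
#' fractions and reports whether (S1, S2) and (S3, S4) are each other's
#' nearest fractions — the empirical justification for pooling them.
#'
#' @param pc A phase-count tibble with columns `S1..S4`.
#' @return A list with `correlation` (symmetric 4x4 matrix),
#'   `s1_s2_mutual` and `s3_s4_mutual` (logicals), and `constant_tracks`
#'   (names of fractions with zero variance, whose correlations are NA).
#' @export
phase_similarity <- function(pc) {
  x <- as.matrix(pc[, c("S1", "S2", "S3", "S4")])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 10) stop("need >= 10 non-missing bins", call. = FALSE)
  const <- colnames(x)[apply(x, 2, stats::sd) == 0]
  cm <- suppressWarnings(stats::cor(x, method = "spearman"))
  mutual_top <- function(a, b) {
    ra <- cm[a, setdiff(colnames(cm), a)]
    rb <- cm[b, setdiff(colnames(cm), b)]
    !anyNA(c(ra, rb)) && names(which.max(ra)) == b && names(which.max(rb)) == a
  }
  list(correlation = cm,
       s1_s2_mutual = mutual_top("S1", "S2"),
       s3_s4_mutual = mutual_top("S3", "S4"),
       constant_tracks = const)
}

#' Compute the per-bin replication-timing score
#'
#' `RT = log2((early + pseudocount) / (late + pseudocount))`: positive
#' scores mean early replication, negative scores late replication. Bins
#' with zero counts in both pools carry no evidence and are set missing.
#'
#' @param tp A combined-phase tibble from [combine_phases()] (columns
#'   `early`, `late`), or a raw phase-count tibble (combined on the fly).
#' @param pseudocount Non-negative pseudocount (default 1), guarding
#'   against zero denominators while preserving the sign convention.
#' @param cell_type Optional cell-type label; taken from the input's
#'   `cell_type` column if present.
#' @return An RT-profile tibble: grid columns plus `rt` and `cell_type`,
#'   with attributes `normalized = FALSE`, `smoothed = FALSE`.
#' @export
compute_rt <- function(tp, pseudocount = 1, cell_type = NULL) {
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  if (all(c("S1", "S2", "S3", "S4") %in% names(tp))) tp <- combine_phases(tp)
  if (!all(c("early", "late") %in% names(tp)))
    stop("input must have `early` and `late` columns", call. = FALSE)
  if (is.null(cell_type))
    cell_type <- if ("cell_type" %in% names(tp)) tp$cell_type[1] else "sample"

  rt <- log2((tp$early + pseudocount) / (tp$late + pseudocount))
  rt[tp$early == 0 & tp$late == 0] <- NA_real_
  out <- tp
  out$early <- NULL
  out$late <- NULL
  out$rt <- rt
  out$cell_type <- cell_type
  attr(out, "normalized") <- FALSE
  attr(out, "smoothed") <- FALSE
  out
}

#' Quantile-normalize RT profiles across cell types
#'
#' Makes the RT score distributions of two or more cell types directly
#' comparable by quantile normalization over the bins where every profile
#' is non-missing (via limma). Rank order within each profile is
#' preserved; after normalization the sorted values of all profiles are
#' identical.
#'
#' @param profiles A list of RT-profile tibbles on the same grid.
#' @return The list with `rt` values normalized and attribute
#'   `normalized = TRUE`.
#' @export
normalize_profiles <- function(profiles) {
  if (length(profiles) < 2) {
    warning("fewer than 2 profiles; returning input unchanged", call. = FALSE)
    return(profiles)
  }
  n <- nrow(profiles[[1]])
  for (p in profiles) {
    if (nrow(p) != n || !identical(p$chrom, profiles[[1]]$chrom))
      stop("profiles are not on the same grid", call. = FALSE)
  }
  m <- vapply(profiles, function(p) p$rt, numeric(n))
  shared <- stats::complete.cases(m)
  m[shared, ] <- limma::normalizeQuantiles(m[shared, , drop = FALSE])
  purrr::imap(profiles, function(p, i) {
    p$rt[shared] <- m[shared, i]
    attr(p, "normalized") <- TRUE
    p
  })
}

#' Smooth an RT profile with a running mean
#'
#' Running mean over an odd window of bins, applied within each
#' chromosome; missing bins are excluded from the window average, and a
#' span of 1 is the identity.
#'
#' @param p An RT-profile tibble.
#' @param span Odd window width in bins (default 3).
#' @return The profile with smoothed `rt` and attribute `smoothed = span`.
#' @export
smooth_profile <- function(p, span = 3) {
  if (span < 1 || span %% 2 == 0)
    stop("`span` must be odd and >= 1", call. = FALSE)
  if (span == 1) return(p)
  half <- (span - 1) / 2
  out <- p
  for (chr in unique(p$chrom)) {
    sel <- which(p$chrom == chr)
    x <- p$rt[sel]
    v <- ifelse(is.na(x), 0, x)
    w <- as.numeric(!is.na(x))
    k <- length(x)
    csum <- cumsum(c(0, v))
    cw <- cumsum(c(0, w))
    lo <- pmax(seq_len(k) - half, 1)
    hi <- pmin(seq_len(k) + half, k)
    tot <- csum[hi + 1] - csum[lo]
    nn <- cw[hi + 1] - cw[lo]
    sm <- ifelse(nn > 0, tot / nn, NA_real_)
    sm[is.na(x)] <- NA_real_
    out$rt[sel] <- sm
  }
  attr(out, "smoothed") <- span
  out
}

#' Classify bins into constitutive and switching RT categories
#'
#' Across one reference (stem) profile and one or more differentiated
#' profiles, each bin is labelled by the sign pattern of its RT scores:
#' `CE` (constitutive early) if RT is positive in the reference and in
#' every differentiated type; `CL` if negative everywhere; `EtoL` if
#' positive in the reference but negative in every differentiated type;
#' `LtoE` for the converse; `other` for any remaining pattern, any bin
#' with a missing profile, or any score inside the optional dead zone.
#'
#' @param reference RT profile of the reference cell type.
#' @param differentiated A list of RT profiles of differentiated types
#'   (order is irrelevant to the labels).
#' @param epsilon Dead-zone half-width: bins with any `|rt| < epsilon`
#'   are sent to `other` (default 0, i.e. strict sign).
#' @return A category-map tibble: grid columns plus `category`, a factor
#'   over `CE, CL, EtoL, LtoE, other`.
#' @export
classify_rt <- function(reference, differentiated, epsilon = 0) {
  if (length(differentiated) == 0)
    stop("need at least one differentiated profile", call. = FALSE)
  for (p in differentiated) {
    if (nrow(p) != nrow(reference) || !identical(p$chrom, reference$chrom) ||
        !identical(as.numeric(p$start), as.numeric(reference$start)))
      stop("profiles do not share the reference grid", call. = FALSE)
  }
  dm <- vapply(differentiated, function(p) p$rt, numeric(nrow(reference)))
  dm <- matrix(dm, nrow = nrow(reference))
  r <- reference$rt

  any_na <- is.na(r) | apply(dm, 1, anyNA)
  dead <- !any_na & (abs(r) < epsilon | apply(abs(dm) < epsilon, 1, any))
  pos_ref <- r > 0
  neg_ref <- r < 0
  all_pos <- apply(dm > 0, 1, all)
  all_neg <- apply(dm < 0, 1, all)

  category <- rep("other", nrow(reference))
  ok <- !any_na & !dead
  category[ok & pos_ref & all_pos] <- "CE"
  category[ok & neg_ref & all_neg] <- "CL"
  category[ok & pos_ref & all_neg] <- "EtoL"
  category[ok & neg_ref & all_pos] <- "LtoE"

  out <- reference[, intersect(c("chrom", "start", "end", "bin"), names(reference))]
  out$category <- factor(category, levels = rt_categories)
  out
}
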