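#' Segment an RT profile into replication domains
#'
#' Recursive binary segmentation with a permutation test, in the spirit
#' of circular binary segmentation: within each current segment the split
#' maximizing the two-sample t statistic is tested against `n_perm`
#' within-segment permutations and accepted when its permutation p-value
#' falls below `alpha`. Segments shorter than `min_seg` are merged into
#' the neighbour with the closer mean. Each final segment is called
#' `early` if its mean RT is positive, else `late`.
#'
#' @param p An RT-profile tibble (grid columns plus `rt`).
#' @param alpha Permutation significance level for accepting a split
#'   (default 0.01).
#' @param min_seg Minimum segment length in bins (default 3).
#' @param n_perm Number of permutations per tested split (default 1000).
#' @param seed RNG seed for the permutation test.
#' @return A tibble of class `rt_segments`: one row per segment with
#'   `chrom`, `start_bin`, `end_bin` (0-based half-open, in bin units),
#'   `start`, `end` (bp), `n_bins`, `mean_rt`, `call`. Chromosomes whose
#'   profile is entirely missing contribute no rows.
#' @export
segment_profile <- function(p, alpha = 0.01, min_seg = 3, n_perm = 1000,
                            seed = 1L) {
  stopifnot(all(c("chrom", "start", "end", "rt") %in% names(p)))
  if (!"bin" %in% names(p)) {
    p <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(p, chrom),
                                      bin = dplyr::row_number() - 1L))
  }
  set.seed(derive_seed(seed, "segment"))
  segs <- list()
  for (chr in unique(p$chrom)) {
    sel <- which(p$chrom == chr)
    x <- p$rt[sel]
    obs <- which(!is.na(x))
    if (length(obs) == 0) next
    if (length(obs) < 2 * min_seg) {
      bounds <- c(1, length(obs) + 1)
    } else {
      bounds <- sort(unique(c(1, length(obs) + 1,
                              rbs_splits(x[obs], alpha, min_seg, n_perm))))
      bounds <- merge_short_segments(x[obs], bounds, min_seg)
    }
    for (k in seq_len(length(bounds) - 1)) {
      idx <- obs[bounds[k]:(bounds[k + 1] - 1)]
      segs[[length(segs) + 1]] <- tibble::tibble(
        chrom = chr,
        start_bin = p$bin[sel[idx[1]]],
        end_bin = p$bin[sel[idx[length(idx)]]] + 1L,
        start = p$start[sel[idx[1]]],
        end = p$end[sel[idx[length(idx)]]],
        n_bins = length(idx),
        mean_rt = mean(p$rt[sel[idx]])
      )
    }
  }
  out <- dplyr::bind_rows(segs)
  if (nrow(out) > 0) out$call <- ifelse(out$mean_rt > 0, "early", "late")
  class(out) <- c("rt_segments", class(out))
  out
}

# Max |t| split scan over a numeric vector; returns t and split index
# (split before position k+1), restricted so both sides have >= min_seg.
best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  k <- seq_len(n - 1)
  csum <- cumsum(x)
  csq <- cumsum(x^2)
  n1 <- k
  n2 <- n - k
  s1 <- csum[k]
  s2 <- csum[n] - s1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss <- (csq[n] - (s1^2 / n1 + s2^2 / n2))
  ok <- n1 >= min_seg & n2 >= min_seg & n > 2
  pooled_var <- pmax(ss, 0) / (n - 2)
  delta <- abs(m1 - m2)
  tstat <- delta / sqrt(pooled_var * (1 / n1 + 1 / n2))
  # guard against cumsum cancellation noise: a mean shift at rounding scale
  # is no shift, and zero residual variance with a real shift is a perfect step
  scale <- max(abs(x), 1)
  tstat[is.nan(tstat) | is.na(tstat)] <- -Inf
  tstat[ok & pooled_var <= 1e-8 * scale^2 & delta > 1e-6 * scale] <- Inf
  tstat[delta <= 1e-6 * scale] <- -Inf
  tstat[!ok] <- -Inf
  if (max(tstat) == -Inf) return(NULL)
  j <- which.max(tstat)
  list(t = tstat[j], split = j)
}

# Recursive binary segmentation on a fully observed vector: returns the
# interior split positions (1-based index of the first element of the
# right segment).
rbs_splits <- function(x, alpha, min_seg, n_perm, offset = 0) {
  bs <- best_split(x, min_seg)
  if (is.null(bs) || is.na(bs$t) || bs$t <= 0) return(integer(0))
  if (is.infinite(bs$t)) {
    p <- 0  # zero within-segment variance with a real mean shift
  } else {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      bp <- best_split(sample(x), min_seg)
      if (!is.null(bp) && !is.na(bp$t) && bp$t >= bs$t) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  if (p >= alpha) return(integer(0))
  left <- x[seq_len(bs$split)]
  right <- x[(bs$split + 1):length(x)]
  c(rbs_splits(left, alpha, min_seg, n_perm, offset),
    offset + bs$split + 1L,
    rbs_splits(right, alpha, min_seg, n_perm, offset + bs$split))
}

# Merge segments shorter than min_seg into the neighbour with the closer
# mean. bounds are 1-based segment starts plus the terminal n+1.
merge_short_segments <- function(x, bounds, min_seg) {
  repeat {
    lens <- diff(bounds)
    if (length(lens) <= 1 || all(lens >= min_seg)) return(bounds)
    i <- which.min(lens)  # merge the shortest offender first
    if (lens[i] >= min_seg) return(bounds)
    seg_mean <- function(k) mean(x[bounds[k]:(bounds[k + 1] - 1)])
    drop_left <- if (i == 1) FALSE
      else if (i == length(lens)) TRUE
      else abs(seg_mean(i) - seg_mean(i - 1)) <= abs(seg_mean(i) - seg_mean(i + 1))
    bounds <- bounds[-(if (drop_left) i else i + 1)]
  }
}
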