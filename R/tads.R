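#' Insulation track of a contact matrix
#'
#' For each bin i, the mean contact count in the `window x window` square
#' upstream-by-downstream of i (rows i-window..i-1, columns
#' i+1..i+window), log2-normalized by the chromosome mean of the raw
#' track. Lower values mean fewer contacts crossing the bin, i.e. a
#' stronger domain boundary. Bins whose full square does not fit inside
#' the chromosome are missing.
#'
#' @param m A [contact_matrix()].
#' @param window Window half-size in bins (>= 1).
#' @return A tibble with columns `bin` (0-based), `raw`, `insulation`.
#' @export
insulation_track <- function(m, window) {
  stopifnot(inherits(m, "contact_matrix"))
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  n <- n_bins(m)
  if (n < 2 * window + 1)
    stop("`window` too large for this chromosome", call. = FALSE)
  raw <- rep(NA_real_, n)
  for (i in (window + 1):(n - window)) {
    raw[i] <- mean(m$counts[(i - window):(i - 1), (i + 1):(i + window)])
  }
  mu <- mean(raw, na.rm = TRUE)
  ins <- if (mu > 0) log2(raw / mu) else raw * NA
  tibble::tibble(bin = seq_len(n) - 1L, raw = raw, insulation = ins)
}

# Boundary rows from an insulation track: local minima at or below `thr`.
# A run of exactly equal low values (a plateau, as produced by noiseless
# constructions and structure-free gaps) contributes its edges: the break
# sits after the last low row when the track rises on the right, and
# before the row following the first low row when it falls in from the
# left; a single-bin minimum needs both neighbours strictly higher.
# Returned values are 1-based rows r meaning "break before row r".
insulation_minima <- function(tr, thr) {
  n <- length(tr)
  r <- rle(ifelse(is.na(tr), NA, tr))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (is.na(v) || v > thr) next
    a <- starts[k]; b <- ends[k]
    left_higher <- a > 1 && !is.na(tr[a - 1]) && tr[a - 1] > v
    right_higher <- b < n && !is.na(tr[b + 1]) && tr[b + 1] > v
    if (b == a) {
      if (left_higher && right_higher) out <- c(out, a)
    } else {
      if (right_higher) out <- c(out, b)
      if (left_higher) out <- c(out, a + 1L)
    }
  }
  sort(unique(out))
}

#' Call hierarchical (nested) domains from multiscale insulation
#'
#' Multiscale insulation caller for layered domains: the coarsest window
#' defines level-0 domains (boundaries at strict local insulation minima
#' lying at or below the track's `boundary_quantile` quantile); each
#' successively finer window subdivides existing leaf domains into
#' children one level deeper, keeping only subdivisions that create at
#' least two children of at least `min_child` bins. Level 0 is the
#' outermost (parentless) layer; the level number grows with nesting
#' depth.
#'
#' @param m A [contact_matrix()].
#' @param windows Strictly decreasing insulation window sizes in bins
#'   (default `c(20, 10, 5)`, resolving roughly 0.5-2 Mb domains at
#'   100 kb resolution).
#' @param boundary_quantile Quantile of the insulation track at or below
#'   which a local minimum counts as a boundary (default 0.1).
#' @param min_child Minimum child-domain size in bins (default 3).
#' @return A tibble of class `tad_tree`: `domain_id`, `parent`
#'   (NA for level 0), `chrom`, `start_bin`, `end_bin` (0-based
#'   half-open), `level`, `n_bins`.
#' @export
call_hierarchical_domains <- function(m, windows = c(20, 10, 5),
                                      boundary_quantile = 0.1,
                                      min_child = 3) {
  stopifnot(inherits(m, "contact_matrix"))
  if (length(windows) == 0) stop("`windows` must be non-empty", call. = FALSE)
  if (length(windows) > 1 && any(diff(windows) >= 0))
    stop("`windows` must be strictly decreasing", call. = FALSE)
  n <- n_bins(m)

  tracks <- lapply(windows, function(w) insulation_track(m, w)$insulation)

  # level-0 partition: boundaries against the chromosome-wide quantile
  tr0 <- tracks[[1]]
  b0 <- insulation_minima(
    tr0, stats::quantile(tr0, boundary_quantile, na.rm = TRUE, names = FALSE))
  edges <- sort(unique(c(1L, b0, n + 1L)))
  # enforce minimum level-0 span of 2*min_child, greedily from the left
  keep <- c(TRUE, rep(FALSE, length(edges) - 2), TRUE)
  last <- 1L
  if (length(edges) > 2) {
    for (k in 2:(length(edges) - 1)) {
      if (edges[k] - last >= 2 * min_child && (n + 1L) - edges[k] >= 2 * min_child) {
        keep[k] <- TRUE
        last <- edges[k]
      }
    }
  }
  edges <- edges[keep]

  doms <- tibble::tibble(
    start = edges[-length(edges)], stop = edges[-1], level = 0L,
    parent = NA_integer_
  )
  doms$domain_id <- seq_len(nrow(doms)) - 1L

  next_id <- nrow(doms)
  leaves <- doms
  for (lev in seq_along(windows)[-1]) {
    trw <- tracks[[lev]]
    new_leaves <- list()
    for (r in seq_len(nrow(leaves))) {
      a <- leaves$start[r]; b <- leaves$stop[r]
      # judge candidate breaks against the insulation distribution of the
      # parent's interior, keeping clear of its own (already low) edges
      a2 <- a + min_child; b2 <- b - min_child
      if (b2 - a2 < 1) next
      sub <- trw[a2:b2]
      if (all(is.na(sub))) next
      thr <- stats::quantile(sub, boundary_quantile, na.rm = TRUE,
                             names = FALSE)
      inner <- insulation_minima(sub, thr) + a2 - 1L
      inner <- inner[inner >= a + min_child & inner <= b - min_child]
      # keep inner breaks pairwise >= min_child apart, greedily
      sel <- integer(0)
      for (cb in sort(inner)) {
        if (length(sel) == 0 || cb - sel[length(sel)] >= min_child)
          sel <- c(sel, cb)
      }
      if (length(sel) >= 1) {
        ed <- c(a, sel, b)
        kids <- tibble::tibble(
          start = ed[-length(ed)], stop = ed[-1],
          level = leaves$level[r] + 1L, parent = leaves$domain_id[r]
        )
        if (nrow(kids) >= 2 && all(kids$stop - kids$start >= min_child)) {
          kids$domain_id <- next_id + seq_len(nrow(kids)) - 1L
          next_id <- next_id + nrow(kids)
          doms <- dplyr::bind_rows(doms, kids)
          new_leaves[[length(new_leaves) + 1]] <- kids
        }
      }
    }
    if (length(new_leaves) == 0) break
    leaves <- dplyr::bind_rows(new_leaves)
  }

  out <- tibble::tibble(
    domain_id = doms$domain_id, parent = doms$parent, chrom = m$chrom,
    start_bin = doms$start - 1L, end_bin = doms$stop - 1L,
    level = doms$level
  )
  out$n_bins <- out$end_bin - out$start_bin
  class(out) <- c("tad_tree", class(out))
  out
}

#' Check the structural invariants of a domain tree
#'
#' Any two domains must be disjoint or strictly nested; children must lie
#' within their parents with level exactly one deeper; parentless domains
#' must be level 0.
#'
#' @param tree A `tad_tree` tibble.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_tad_tree <- function(tree) {
  if (nrow(tree) == 0) return(invisible(TRUE))
  if (any(tree$level[is.na(tree$parent)] != 0))
    stop("parentless domains must be level 0", call. = FALSE)
  idx <- match(tree$parent, tree$domain_id)
  has_parent <- !is.na(tree$parent)
  if (any(is.na(idx[has_parent])))
    stop("dangling parent reference", call. = FALSE)
  if (any(tree$level[has_parent] != tree$level[idx[has_parent]] + 1L))
    stop("child level must be parent level + 1", call. = FALSE)
  if (any(tree$start_bin[has_parent] < tree$start_bin[idx[has_parent]] |
          tree$end_bin[has_parent] > tree$end_bin[idx[has_parent]]))
    stop("child interval must lie within its parent", call. = FALSE)
  for (chr in unique(tree$chrom)) {
    tt <- tree[tree$chrom == chr, ]
    nr <- nrow(tt)
    if (nr < 2) next
    for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
      a1 <- tt$start_bin[i]; b1 <- tt$end_bin[i]
      a2 <- tt$start_bin[j]; b2 <- tt$end_bin[j]
      disjoint <- b1 <= a2 || b2 <= a1
      nested <- (a1 <= a2 && b2 <= b1) || (a2 <= a1 && b1 <= b2)
      if (!disjoint && !nested)
        stop(sprintf("domains %d and %d overlap without nesting",
                     tt$domain_id[i], tt$domain_id[j]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Summarize domains against RT and category maps
#'
#' Per domain: its size in bp, hierarchy level, mean RT over its bins and
#' the majority RT category of its bins (ties labelled `"mixed"`).
#' Grouped summaries — domain-size distribution per category and RT
#' distribution per level — are attached as attributes
#' `size_by_category` and `rt_by_level`.
#'
#' @param tree A `tad_tree`.
#' @param rt An RT-profile tibble on the grid the tree was called on.
#' @param categories Optional category map from [classify_rt()].
#' @return A tibble with one row per domain.
#' @export
summarize_tad_rt <- function(tree, rt, categories = NULL) {
  bs <- attr(rt, "bin_size")
  if (is.null(bs)) bs <- stats::median(rt$end - rt$start)
  out <- tree
  per_dom <- purrr::map(seq_len(nrow(tree)), function(i) {
    sel <- rt$chrom == tree$chrom[i] &
      rt$bin >= tree$start_bin[i] & rt$bin < tree$end_bin[i]
    if (!any(sel))
      stop(sprintf("domain %d lies outside the grid", tree$domain_id[i]),
           call. = FALSE)
    mean_rt <- mean(rt$rt[sel], na.rm = TRUE)
    majority <- NA_character_
    if (!is.null(categories)) {
      tab <- table(as.character(categories$category[sel]))
      top <- names(tab)[tab == max(tab)]
      majority <- if (length(top) == 1) top else "mixed"
    }
    list(size = sum(rt$end[sel] - rt$start[sel]), mean_rt = mean_rt,
         majority = majority)
  })
  out$size_bp <- purrr::map_dbl(per_dom, "size")
  out$mean_rt <- purrr::map_dbl(per_dom, "mean_rt")
  out$majority_category <- purrr::map_chr(per_dom, "majority")

  if (!is.null(categories)) {
    attr(out, "size_by_category") <- out |>
      dplyr::filter(!is.na(majority_category)) |>
      dplyr::group_by(majority_category) |>
      dplyr::summarise(n = dplyr::n(),
                       median_size_bp = stats::median(size_bp),
                       mean_size_bp = mean(size_bp), .groups = "drop")
  }
  attr(out, "rt_by_level") <- out |>
    dplyr::group_by(level) |>
    dplyr::summarise(n = dplyr::n(), median_rt = stats::median(mean_rt),
                     mean_rt = mean(mean_rt), .groups = "drop")
  out
}
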