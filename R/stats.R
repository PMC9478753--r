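#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with an explicit method policy: the exact
#' null distribution is used when both samples have at most 10 values
#' and there are no ties; otherwise the normal approximation with
#' midranks, tie-corrected variance and continuity correction is used.
#' The method actually applied is recorded in the result.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Largest per-group size for which the exact
#'   distribution is used (default 10).
#' @return A list of class `rank_sum` with elements `statistic` (the
#'   rank sum W of `x` in the pooled sample), `u` (the Mann-Whitney U),
#'   `p_value`, `method` (`"exact"` or `"normal-approximation"`),
#'   `n_x`, `n_y`, `ties`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must contain at least one value", call. = FALSE)
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(n)])
  u <- w - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && n <= exact_max && m <= exact_max

  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  structure(
    list(statistic = w, u = u, p_value = ht$p.value,
         method = if (use_exact) "exact" else "normal-approximation",
         n_x = n, n_y = m, ties = has_ties),
    class = "rank_sum"
  )
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g (n = %d, m = %d), p = %.4g [%s]\n",
              x$statistic, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' @method tidy rank_sum
#' @export
tidy.rank_sum <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, u = x$u, p_value = x$p_value,
                 method = x$method, n_x = x$n_x, n_y = x$n_y, ties = x$ties)
}

#' @method glance rank_sum
#' @export
glance.rank_sum <- function(x, ...) tidy.rank_sum(x)

star_label <- function(p) {
  dplyr::case_when(p < 1e-10 ~ "***", p < 1e-5 ~ "**", p < 1e-3 ~ "*",
                   TRUE ~ "ns")
}

#' Pairwise category comparisons of a feature
#'
#' Runs a two-sided rank-sum test on a feature column of the per-bin
#' feature table for each requested pair of RT categories, annotating
#' each raw p-value with the significance bands used throughout the
#' analysis (`*` p < 1e-3, `**` p < 1e-5, `***` p < 1e-10). Raw
#' p-values are reported; Benjamini-Hochberg adjustment is available but
#' off by default.
#'
#' @param ft A feature table (one row per bin) with a `category` column.
#' @param feature Name of the feature column to compare.
#' @param pairs A list of 2-element character vectors of categories
#'   (default: all pairs among CE, CL, EtoL, LtoE present in the table).
#' @param adjust If `TRUE`, add a BH-adjusted p column.
#' @return A tibble with one row per pair: group labels, group sizes,
#'   statistic, p-value, method, stars.
#' @export
category_comparisons <- function(ft, feature, pairs = NULL, adjust = FALSE) {
  stopifnot("category" %in% names(ft), feature %in% names(ft))
  present <- intersect(c("CE", "CL", "EtoL", "LtoE"),
                       unique(as.character(ft$category)))
  if (is.null(pairs))
    pairs <- utils::combn(present, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- ft[[feature]][ft$category == pr[1]]
    b <- ft[[feature]][ft$category == pr[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      warning(sprintf("empty category in pair %s vs %s; skipped",
                      pr[1], pr[2]), call. = FALSE)
      next
    }
    rs <- rank_sum_test(a, b)
    rows[[length(rows) + 1]] <- tibble::tibble(
      feature = feature, group1 = pr[1], group2 = pr[2],
      n1 = rs$n_x, n2 = rs$n_y, statistic = rs$statistic,
      p_value = rs$p_value, method = rs$method,
      stars = star_label(rs$p_value)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (adjust && nrow(out) > 0)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Compartment composition of RT categories
#'
#' For each RT category, the fraction of its unmasked bins lying in the
#' A and B compartments (fractions sum to 1 per row). This is the
#' table behind the discordance analysis: in the stem cell type,
#' early-to-late switching regions sit mostly in B and late-to-early
#' regions mostly in A, ahead of their RT switch.
#'
#' @param categories A category map from [classify_rt()].
#' @param cp A `compartment_profile` on the same bins.
#' @return A tibble with columns `category`, `n_bins`, `A`, `B`.
#' @export
compartment_composition <- function(categories, cp) {
  if (nrow(categories) != nrow(cp))
    stop("category map and compartment profile are not on the same bins",
         call. = FALSE)
  lab <- cp$compartment
  rows <- list()
  for (cat in levels(factor(categories$category))) {
    sel <- categories$category == cat & lab %in% c("A", "B")
    if (!any(sel)) next
    nA <- sum(lab[sel] == "A")
    nB <- sum(lab[sel] == "B")
    rows[[cat]] <- tibble::tibble(category = cat, n_bins = nA + nB,
                                  A = nA / (nA + nB), B = nB / (nA + nB))
  }
  dplyr::bind_rows(rows)
}

#' Assemble the per-bin feature table
#'
#' Joins the category map, compartment profile, degree track, RT
#' profiles and any number of binned signals into one tibble with one
#' row per grid bin — the table every category comparison runs on.
#'
#' @param categories Category map from [classify_rt()].
#' @param compartments Optional `compartment_profile` (adds
#'   `compartment` and `eigenvector`). For multi-chromosome grids supply
#'   a vector/tibble covering all bins.
#' @param degree Optional degree track from
#'   [compartmentalization_degree()] (adds `degree`).
#' @param rt_profiles Optional named list of RT profiles (adds one
#'   `rt_<cell_type>` column each).
#' @param signals Optional named list of binned signals (adds one column
#'   per signal, named by its label or list name).
#' @return A tibble with one row per bin.
#' @export
build_feature_table <- function(categories, compartments = NULL, degree = NULL,
                                rt_profiles = NULL, signals = NULL) {
  out <- tibble::as_tibble(categories)
  if (!is.null(compartments)) {
    stopifnot(nrow(compartments) == nrow(out))
    out$compartment <- compartments$compartment
    out$eigenvector <- compartments$eigenvector
  }
  if (!is.null(degree)) {
    stopifnot(nrow(degree) == nrow(out))
    out$degree <- degree$degree
  }
  for (nm in names(rt_profiles)) {
    p <- rt_profiles[[nm]]
    stopifnot(nrow(p) == nrow(out))
    out[[paste0("rt_", nm)]] <- p$rt
  }
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    stopifnot(nrow(s) == nrow(out))
    nm <- names(signals)[i]
    if (is.null(nm) || nm == "") nm <- attr(s, "label")
    out[[nm]] <- s$value
  }
  out
}
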