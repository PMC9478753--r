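#' Intra-chromosomal Hi-C contact matrix
#'
#' Light container for a symmetric per-chromosome contact-count matrix on
#' the bin grid, with a mask of excluded bins. Masked bins contribute
#' nothing to any downstream statistic.
#'
#' @param counts Symmetric non-negative numeric matrix.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param mask Logical vector, `TRUE` for excluded bins (default: none).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", resolution = 1e5,
                           mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contact matrix must be square", call. = FALSE)
  if (max(abs(counts - t(counts))) > 0)
    stop("contact matrix must be symmetric", call. = FALSE)
  if (any(counts < 0)) stop("contact counts must be non-negative", call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, nrow(counts))
  stopifnot(length(mask) == nrow(counts))
  structure(list(counts = counts, chrom = chrom,
                 resolution = resolution, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d x %d bins at %s bp, %d masked\n",
              x$chrom, nrow(x$counts), ncol(x$counts),
              format(x$resolution, big.mark = ","), sum(x$mask)))
  invisible(x)
}

#' @rdname contact_matrix
#' @param x A `contact_matrix`.
#' @export
n_bins <- function(x) nrow(x$counts)

#' Mask bins with zero marginal contacts
#'
#' Bins whose row sum is zero give constant rows in the O/E matrix and
#' break the Pearson correlation step, so they are excluded up front.
#'
#' @param m A [contact_matrix()].
#' @return The matrix with its mask extended to zero-marginal bins.
#' @export
mask_empty_bins <- function(m) {
  m$mask <- m$mask | rowSums(m$counts) == 0
  m
}

#' Tidy a contact matrix into long form
#'
#' @param x A [contact_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `bin_i`, `bin_j` (0-based), `count`,
#'   upper triangle (including the diagonal) only.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0, arr.ind = TRUE)
  tibble::tibble(chrom = x$chrom,
                 bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                 count = x$counts[idx])
}

#' Expected contact count per genomic distance
#'
#' The distance-decay model underlying the distance-normalized (observed
#' over expected) transform: the expected value at distance `d` bins is
#' the mean of all unmasked matrix entries with `|i - j| = d`.
#'
#' @param m A [contact_matrix()].
#' @return A tibble with columns `distance` (bins) and `expected`
#'   (NA where no unmasked entry exists at that distance).
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  keep <- !m$mask
  if (sum(keep) < 2)
    stop("need at least 2 unmasked bins", call. = FALSE)
  n <- n_bins(m)
  sub <- m$counts[keep, keep, drop = FALSE]
  pos <- which(keep)
  d_sub <- abs(outer(pos, pos, "-"))
  sums <- tapply(sub, d_sub, sum)
  cnts <- table(d_sub)
  expd <- rep(NA_real_, n)  # distances 0 .. n-1
  have <- as.integer(names(sums))
  expd[have + 1L] <- as.numeric(sums) / as.numeric(cnts)
  tibble::tibble(distance = 0:(n - 1L), expected = expd)
}

#' Distance-normalize a contact matrix (observed / expected)
#'
#' @param m A [contact_matrix()].
#' @return An object of class `oe_matrix` (same container shape); entries
#'   at distances with expected 0 or masked bins are NA. Every unmasked
#'   diagonal of the result has mean 1 by construction.
#' @export
oe_transform <- function(m) {
  ed <- expected_by_distance(m)
  n <- n_bins(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expm <- matrix(ed$expected[d + 1L], n, n)
  oe <- m$counts / expm
  oe[expm == 0] <- NA
  oe[m$mask, ] <- NA
  oe[, m$mask] <- NA
  structure(list(oe = oe, chrom = m$chrom, resolution = m$resolution,
                 mask = m$mask),
            class = "oe_matrix")
}

#' Pearson correlation matrix of an O/E matrix
#'
#' Entry (i, j) is the Pearson correlation of O/E rows i and j over
#' unmasked columns; this is the matrix whose leading eigenvector defines
#' the A/B compartment partition.
#'
#' @param oe An [oe_transform()] result.
#' @return A symmetric correlation matrix with unit diagonal; masked or
#'   constant rows are NA throughout.
#' @export
correlation_matrix <- function(oe) {
  stopifnot(inherits(oe, "oe_matrix"))
  keep <- !oe$mask
  if (sum(keep) < 3) stop("need at least 3 unmasked bins", call. = FALSE)
  sub <- oe$oe[keep, keep, drop = FALSE]
  const <- apply(sub, 1, function(r) stats::sd(r, na.rm = TRUE)) == 0
  if (all(const)) stop("all O/E rows are constant", call. = FALSE)
  cm_sub <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
  cm_sub[const, ] <- NA
  cm_sub[, const] <- NA
  diag(cm_sub)[!const] <- 1
  n <- length(oe$mask)
  cm <- matrix(NA_real_, n, n)
  cm[keep, keep] <- cm_sub
  mask_full <- rep(TRUE, n)
  mask_full[which(keep)[!const]] <- FALSE
  attr(cm, "mask") <- mask_full
  cm
}

#' Leading eigenvector of a correlation matrix
#'
#' The eigenvector of the largest algebraic eigenvalue, unit-normalized,
#' with NA at masked bins. Its sign is arbitrary at this stage; see
#' [orient_compartments()].
#'
#' @param cm A [correlation_matrix()] result (or any symmetric matrix
#'   with optional `mask` attribute).
#' @return Numeric vector of per-bin eigenvector values (NA = masked).
#' @export
leading_eigenvector <- function(cm) {
  mask <- attr(cm, "mask")
  if (is.null(mask)) mask <- apply(cm, 1, function(r) all(is.na(r)))
  keep <- !mask
  sub <- cm[keep, keep, drop = FALSE]
  if (any(is.na(sub)))
    sub[is.na(sub)] <- 0
  sub <- (sub + t(sub)) / 2
  es <- tryCatch(eigen(sub, symmetric = TRUE),
                 error = function(e) stop("eigendecomposition failed: ",
                                          conditionMessage(e), call. = FALSE))
  v <- es$vectors[, which.max(es$values)]
  v <- v / sqrt(sum(v^2))
  out <- rep(NA_real_, nrow(cm))
  out[keep] <- v
  out
}
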