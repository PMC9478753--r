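#' Orient an eigenvector and label A/B compartments
#'
#' The sign of a leading eigenvector is arbitrary, so it is oriented
#' against an external per-bin reference that is higher in active
#' chromatin (gene density or expression): if the Spearman correlation
#' between the eigenvector and the reference is negative, every
#' eigenvector value is negated. Positive bins are then labelled A
#' (active, gene-dense) and negative bins B; exact zeros and masked bins
#' stay unlabelled.
#'
#' @param ev Per-bin eigenvector values (NA = masked), or a
#'   `compartment_profile` to re-orient.
#' @param reference A binned-signal tibble (or bare numeric vector)
#'   aligned to the same bins.
#' @return A tibble of class `compartment_profile` with columns
#'   `eigenvector` and `compartment` (`"A"`, `"B"` or `"masked"`), plus
#'   attributes `orientation_flipped` and `orientation_uncertain`. When
#'   `|rho| < 0.1` (or rho is undefined) the orientation is flagged
#'   uncertain, the sign is left unchanged and a warning is emitted.
#' @export
orient_compartments <- function(ev, reference) {
  if (inherits(ev, "compartment_profile")) ev <- ev$eigenvector
  ref <- if (is.data.frame(reference)) reference$value else as.numeric(reference)
  if (length(ref) != length(ev))
    stop("reference is not aligned to the eigenvector bins", call. = FALSE)
  ok <- !is.na(ev) & !is.na(ref)
  if (sum(ok) < 10)
    stop("need >= 10 shared unmasked bins to orient", call. = FALSE)

  rho <- if (stats::sd(ref[ok]) == 0 || stats::sd(ev[ok]) == 0) NA_real_
         else suppressWarnings(stats::cor(ev[ok], ref[ok], method = "spearman"))
  flipped <- FALSE
  uncertain <- FALSE
  if (is.na(rho) || abs(rho) < 0.1) {
    uncertain <- TRUE
    warning("compartment orientation uncertain (|rho| < 0.1 or undefined); ",
            "sign left unchanged", call. = FALSE)
  } else if (rho < 0) {
    ev <- -ev
    flipped <- TRUE
  }

  comp <- dplyr::case_when(
    is.na(ev) ~ "masked",
    ev > 0 ~ "A",
    ev < 0 ~ "B",
    TRUE ~ "masked"
  )
  out <- tibble::tibble(eigenvector = ev, compartment = comp)
  attr(out, "orientation_flipped") <- flipped
  attr(out, "orientation_uncertain") <- uncertain
  attr(out, "orientation_rho") <- rho
  class(out) <- c("compartment_profile", class(out))
  out
}

#' Call A/B compartments from a contact matrix
#'
#' Convenience wrapper running the full per-chromosome pipeline:
#' zero-marginal bins are masked, the matrix is distance-normalized
#' (observed/expected), rows are correlated, the leading eigenvector is
#' extracted and oriented against the reference track.
#'
#' @param m A [contact_matrix()].
#' @param reference Binned reference signal (gene density or expression)
#'   aligned to the matrix bins.
#' @return A `compartment_profile` tibble (see [orient_compartments()]).
#' @export
call_compartments <- function(m, reference) {
  m <- mask_empty_bins(m)
  ev <- leading_eigenvector(correlation_matrix(oe_transform(m)))
  orient_compartments(ev, reference)
}

#' Refine compartments at a finer resolution
#'
#' Runs the compartment pipeline at a coarse resolution (classically
#' 500 kb) and again at a finer one (100 kb), orients both against the
#' reference, and then checks the fine profile for per-chromosome sign
#' agreement with the coarse profile by majority vote over the fine bins
#' nested in each coarse bin. If the majority of fine calls disagree with
#' their coarse parents, the fine chromosome's signs are flipped and the
#' flip is flagged.
#'
#' @param m_coarse,m_fine [contact_matrix()] objects for the same
#'   chromosome; the fine resolution must divide the coarse one.
#' @param reference_fine Reference signal on the fine bins.
#' @param reference_coarse Reference signal on the coarse bins (default:
#'   fine reference averaged into coarse bins).
#' @return The fine-bin `compartment_profile`, with attribute
#'   `coarse_flip` recording whether a flip was applied and
#'   `coarse_agreement` the post-alignment agreement fraction.
#' @export
compartments_at_resolution <- function(m_coarse, m_fine, reference_fine,
                                       reference_coarse = NULL) {
  if (m_fine$resolution <= 0 || m_coarse$resolution %% m_fine$resolution != 0)
    stop("fine resolution must divide the coarse resolution", call. = FALSE)
  ratio <- m_coarse$resolution / m_fine$resolution

  if (is.null(reference_coarse)) {
    refv <- if (is.data.frame(reference_fine)) reference_fine$value
            else as.numeric(reference_fine)
    grp <- (seq_along(refv) - 1L) %/% ratio
    reference_coarse <- as.numeric(tapply(refv, grp, mean, na.rm = TRUE))
  }

  coarse <- call_compartments(m_coarse, reference_coarse)
  fine <- call_compartments(m_fine, reference_fine)

  parent <- (seq_len(nrow(fine)) - 1L) %/% ratio + 1L
  parent[parent > nrow(coarse)] <- nrow(coarse)
  cc <- coarse$compartment[parent]
  fc <- fine$compartment
  comparable <- fc %in% c("A", "B") & cc %in% c("A", "B")
  agree <- mean(fc[comparable] == cc[comparable])

  flipped <- FALSE
  if (!is.nan(agree) && !is.na(agree) && agree < 0.5) {
    fine$eigenvector <- -fine$eigenvector
    fine$compartment <- dplyr::case_when(
      fine$compartment == "A" ~ "B",
      fine$compartment == "B" ~ "A",
      TRUE ~ fine$compartment
    )
    flipped <- TRUE
    agree <- 1 - agree
  }
  attr(fine, "coarse_flip") <- flipped
  attr(fine, "coarse_agreement") <- agree
  fine
}

#' Per-bin degree of compartmentalization
#'
#' For each unmasked bin i with compartment label L, sums its contacts to
#' other bins sharing L (`same`) and to bins of the opposite label
#' (`opp`), excluding the bin's own diagonal entry, and scores
#' `log2((same + pseudocount) / (opp + pseudocount))`. A value of 0 means
#' the bin interacts equally with both compartments; bins where both sums
#' are zero, or which are masked/unlabelled, are missing.
#'
#' @param m A [contact_matrix()].
#' @param cp A `compartment_profile` on the same bins.
#' @param pseudocount Non-negative pseudocount (default 1).
#' @return A tibble with columns `compartment`, `same`, `opp`, `degree`.
#' @export
compartmentalization_degree <- function(m, cp, pseudocount = 1) {
  stopifnot(inherits(m, "contact_matrix"))
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  lab <- if (is.data.frame(cp)) cp$compartment else as.character(cp)
  if (length(lab) != n_bins(m))
    stop("matrix and compartment profile are not on the same bins", call. = FALSE)
  usable <- lab %in% c("A", "B") & !m$mask
  if (!any(usable)) stop("compartment profile is entirely masked", call. = FALSE)

  cnt <- m$counts
  diag(cnt) <- 0
  cnt[, !usable] <- 0
  isA <- usable & lab == "A"
  isB <- usable & lab == "B"
  to_a <- rowSums(cnt[, isA, drop = FALSE])
  to_b <- rowSums(cnt[, isB, drop = FALSE])
  same <- ifelse(lab == "A", to_a, to_b)
  opp <- ifelse(lab == "A", to_b, to_a)
  degree <- log2((same + pseudocount) / (opp + pseudocount))
  degree[!usable] <- NA
  degree[usable & same == 0 & opp == 0] <- NA
  same[!usable] <- NA
  opp[!usable] <- NA
  tibble::tibble(compartment = ifelse(usable, lab, "masked"),
                 same = same, opp = opp, degree = degree)
}
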