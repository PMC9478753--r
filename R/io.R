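#' Read and write the pipeline's plain-text interchange formats
#'
#' All coordinates are 0-based half-open (BED convention). Phase counts
#' travel as TSV (`chrom start end S1 S2 S3 S4`), per-bin tracks as
#' 4-column bedGraph, interval labels as BED with the label in the name
#' column, and contact matrices as sparse triple text
#' (`bin_i TAB bin_j TAB count`, upper triangle, 0-based bins) next to a
#' `chrom.sizes` file.
#'
#' @param pc A phase-count tibble.
#' @param path Output file path.
#' @name rt_io
NULL

#' @rdname rt_io
#' @export
write_phase_counts <- function(pc, path) {
  readr::write_tsv(pc[, c("chrom", "start", "end", "S1", "S2", "S3", "S4")],
                   path, col_names = TRUE)
  invisible(path)
}

#' @rdname rt_io
#' @param grid Optional `bin_grid` to align and validate against.
#' @export
read_phase_counts <- function(path, grid = NULL) {
  pc <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          .default = readr::col_double()))
  pc <- dplyr::mutate(dplyr::group_by(pc, chrom),
                      bin = dplyr::row_number() - 1L)
  pc <- dplyr::ungroup(pc)
  pc <- pc[, c("chrom", "start", "end", "bin",
               setdiff(names(pc), c("chrom", "start", "end", "bin")))]
  if (!is.null(grid)) check_grid_alignment(pc, grid, "phase counts file")
  pc
}

#' @rdname rt_io
#' @param signal A binned-signal or RT-profile tibble; the `value`
#'   (or `rt`) column is written.
#' @export
write_bedgraph <- function(signal, path) {
  v <- if ("value" %in% names(signal)) signal$value else signal$rt
  keep <- !is.na(v)
  readr::write_tsv(
    tibble::tibble(chrom = signal$chrom[keep],
                   start = signal$start[keep], end = signal$end[keep],
                   value = v[keep]),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname rt_io
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  comment = "track", show_col_types = FALSE,
                  col_types = "cddd")
}

#' @rdname rt_io
#' @param intervals A tibble with `chrom`, `start`, `end` and a label
#'   column (`name`, `category`, `call` or `compartment`).
#' @export
write_bed <- function(intervals, path) {
  nm_col <- intersect(c("name", "category", "call", "compartment", "level"),
                      names(intervals))[1]
  nm <- if (is.na(nm_col)) "." else as.character(intervals[[nm_col]])
  readr::write_tsv(
    tibble::tibble(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end, name = nm),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname rt_io
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                  show_col_types = FALSE, col_types = "cddc")
}

#' @rdname rt_io
#' @param m A [contact_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.triples.tsv` and
#'   `<prefix>.chrom.sizes`.
#' @export
write_contacts <- function(m, prefix) {
  tr <- tidy.contact_matrix(m)
  readr::write_tsv(tr[, c("bin_i", "bin_j", "count")],
                   paste0(prefix, ".triples.tsv"), col_names = FALSE)
  readr::write_tsv(
    tibble::tibble(chrom = m$chrom, size = n_bins(m) * m$resolution),
    paste0(prefix, ".chrom.sizes"), col_names = FALSE)
  invisible(prefix)
}

#' @rdname rt_io
#' @param triples_path,chrom_sizes_path Paths to the sparse triple file
#'   and the chrom.sizes file.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome to load (default: first in chrom.sizes).
#' @export
read_contacts <- function(triples_path, chrom_sizes_path, resolution,
                          chrom = NULL) {
  cs <- readr::read_tsv(chrom_sizes_path, col_names = c("chrom", "size"),
                        show_col_types = FALSE, col_types = "cd")
  if (is.null(chrom)) chrom <- cs$chrom[1]
  size <- cs$size[cs$chrom == chrom]
  if (length(size) != 1) stop("chromosome not in chrom.sizes", call. = FALSE)
  n <- ceiling(size / resolution)
  tr <- readr::read_tsv(triples_path, col_names = c("bin_i", "bin_j", "count"),
                        show_col_types = FALSE, col_types = "ddd")
  if (any(tr$bin_i >= n | tr$bin_j >= n | tr$bin_i < 0 | tr$bin_j < 0))
    stop("triple bin index outside chromosome", call. = FALSE)
  cnt <- matrix(0, n, n)
  cnt[cbind(tr$bin_i + 1, tr$bin_j + 1)] <- tr$count
  cnt[cbind(tr$bin_j + 1, tr$bin_i + 1)] <- tr$count
  contact_matrix(cnt, chrom = chrom, resolution = resolution)
}

#' Write a category map, segment set or compartment profile as BED
#'
#' @param x A tibble with grid columns and a label column.
#' @param path Output path.
#' @export
write_labels_bed <- function(x, path) write_bed(x, path)
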