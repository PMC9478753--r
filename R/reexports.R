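#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

utils::globalVariables(c(
  "S1", "S2", "S3", "S4", "start", "end", "rt", "category", "count",
  "bin_i", "bin_j", "fraction", "compartment", "majority_category",
  "size_bp", "level", "mean_rt"
))
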