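#' Read / write burst tables
#'
#' Delimited text with header columns `burst_id`, `duration_ms`, `I_DD`,
#' `I_DA`, `I_AA` (tab-separated).  Extra columns (e.g. ground truth from
#' the generators) are carried through.
#'
#' @param path file path.
#' @return A tibble of bursts.
#' @export
read_burst_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("burst_id", "duration_ms", "I_DD", "I_DA", "I_AA") %in%
                  names(x)))
  x
}

#' @rdname read_burst_table
#' @param bursts a burst tibble.
#' @export
write_burst_table <- function(bursts, path) {
  readr::write_tsv(bursts, path)
  invisible(path)
}

#' Read a construct measurement table
#'
#' Tab-separated text with header `label`, `string_length_nt`, `mean_E`,
#' `methylation_sites` (the on-disk column `string_length_nt` maps to the
#' in-memory `string_length`).
#'
#' @param path file path.
#' @return A tibble with columns `label`, `string_length`, `mean_E`,
#'   `methylation_sites`.
#' @export
read_construct_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if ("string_length_nt" %in% names(x)) {
    x <- dplyr::rename(x, string_length = "string_length_nt")
  }
  stopifnot(all(c("string_length", "mean_E", "methylation_sites") %in%
                  names(x)))
  x
}

#' @rdname read_construct_table
#' @param measurements a construct tibble.
#' @export
write_construct_table <- function(measurements, path) {
  out <- dplyr::rename(as_tibble(measurements),
                       string_length_nt = "string_length")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a melting curve from two-column delimited text
#'
#' Columns `temperature_C` and `fluorescence` (tab- or comma-separated;
#' a headerless two-column file is also accepted).
#'
#' @param path file path.
#' @return A [melting_curve()].
#' @export
read_melting_curve <- function(path) {
  x <- readr::read_delim(path, show_col_types = FALSE)
  if (!all(c("temperature_C", "fluorescence") %in% names(x))) {
    x <- readr::read_delim(path, col_names = c("temperature_C",
                                               "fluorescence"),
                           show_col_types = FALSE)
  }
  melting_curve(x$temperature_C, x$fluorescence)
}

#' @rdname read_melting_curve
#' @param curve a [melting_curve()].
#' @export
write_melting_curve <- function(curve, path) {
  readr::write_tsv(as_tibble(curve), path)
  invisible(path)
}
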