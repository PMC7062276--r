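#' Read a per-particle sizing CSV
#'
#' Expects the interchange format with header `technique,replicate,diameter_nm`
#' (diameters in nm) and returns one [diameter_dataset()] per technique, in
#' order of first appearance. Malformed rows are rejected with the offending
#' row number.
#'
#' @param path Path to a CSV file.
#' @return Named list of [diameter_dataset()]s.
#' @export
read_sizing_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e))))
  req <- c("technique", "replicate", "diameter_nm")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop(sprintf("empty sizing file: %s", path))
  d <- suppressWarnings(as.numeric(df$diameter_nm))
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad)) {
    stop(sprintf(
      "invalid diameter in '%s' at data row %s (value '%s'): diameters must be positive numbers",
      path, bad[1], df$diameter_nm[bad[1]]))
  }
  rep_id <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_id)) {
    stop(sprintf("non-integer replicate id in '%s' at data row %d",
                 path, which(is.na(rep_id))[1]))
  }
  out <- lapply(split(seq_len(nrow(df)),
                      factor(df$technique, levels = unique(df$technique))),
                function(i) diameter_dataset(df$technique[i], rep_id[i], d[i]))
  out
}

#' Write diameter datasets to a sizing CSV
#'
#' Inverse of [read_sizing_csv()]: concatenates the datasets into one CSV
#' with columns `technique,replicate,diameter_nm`. Output is byte-stable for
#' identical inputs (fixed 15-significant-digit formatting, no row names).
#'
#' @param datasets A [diameter_dataset()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sizing_csv <- function(datasets, path) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(technique = d$technique, replicate = d$replicate,
               diameter_nm = format(d$diameter_nm, digits = 15,
                                    scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
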