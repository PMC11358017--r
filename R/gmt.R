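#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`, returning a named list of
#' character vectors (one element per gene set).
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  stop_if_not(file.exists(path), "GMT file not found: %s", path)
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT files requires the 'fgsea' package", call. = FALSE)
  }
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param description Either one string recycled over sets or a character
#'   vector parallel to `sets` (the second GMT column).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "") {
  stop_if_not(is.list(sets) && length(sets) > 0 && !is.null(names(sets)),
              "`sets` must be a non-empty named list")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    genes <- unique(as.character(sets[[i]]))
    stop_if_not(length(genes) > 0, "gene set '%s' is empty", names(sets)[i])
    paste(c(names(sets)[i], description[i], genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
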