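#' Read and write fingerprint files
#'
#' The `.fps` format is a TSV with columns `mol_id`, `scheme`, `values`,
#' where `values` is a comma-separated list in the scheme's fixed bit order.
#' Integer-valued schemes are written without decimals; real-valued schemes
#' (PMIfp, USR, USRCAT) with six significant digits.
#'
#' @param fps list of [fingerprint] objects.
#' @param path file path.
#' @return `write_fps` invisibly returns `path`; `read_fps` returns a list
#'   of [fingerprint] objects.
#' @export
write_fps <- function(fps, path) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  rows <- vapply(fps, function(fp) {
    v <- as.numeric(fp)
    vs <- if (all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
          else formatC(v, digits = 6, format = "g")
    paste(fp_id(fp), fp_scheme(fp), paste(vs, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("mol_id\tscheme\tvalues", rows), path)
  invisible(path)
}

#' @rdname write_fps
#' @export
read_fps <- function(path) {
  if (!file.exists(path)) stop("cannot read fingerprint file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(tab)), function(r)
    fingerprint(as.numeric(strsplit(tab$values[r], ",", fixed = TRUE)[[1]]),
                tab$scheme[r], tab$mol_id[r]))
}
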