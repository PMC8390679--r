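#' Read gene sets from a GMT file
#'
#' Each line is tab-separated: set name, description, then gene ids.
#' Duplicate genes within a line are removed with a warning; a line with
#' fewer than three fields is an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of unique gene-id character vectors, with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  descs <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   k, length(f)))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' deduplicated", f[1]))
      genes <- unique(genes)
    }
    out[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  attr(out, "description") <- descs
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-id character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(k) {
    paste(c(names(sets)[k], descriptions[k], sets[[k]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
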