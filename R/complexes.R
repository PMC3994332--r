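#' Protein complex catalog
#'
#' A catalog of protein complexes (CYC2008-style): an ordered list of member
#' sets plus an inverted index from protein to the complexes containing it.
#' Complexes are not filtered by size.
#'
#' @param complexes list of character vectors of member proteins; duplicates
#'   within a complex are collapsed.  Names, if present, label the complexes.
#' @return An object of class `complex_catalog` with `complexes` (list of
#'   sorted member vectors) and `membership` (named list, protein to sorted
#'   integer vector of complex indices).
#' @export
complex_catalog <- function(complexes = list()) {
  stopifnot(is.list(complexes))
  complexes <- lapply(complexes, function(x) sort(unique(as.character(x))))
  keep <- lengths(complexes) >= 1L
  complexes <- complexes[keep]
  members <- unlist(complexes, use.names = FALSE)
  idx <- rep(seq_along(complexes), lengths(complexes))
  membership <- lapply(split(idx, members), function(i) sort(unique(i)))
  structure(list(complexes = complexes, membership = membership),
            class = "complex_catalog")
}

#' Read a complex catalog from a flat file
#'
#' One complex per line, members separated by tabs or spaces.  With
#' `named = TRUE` the first token of each line is the complex name.  Empty
#' lines are skipped with a warning.
#'
#' @param path path to the flat file.
#' @param named whether lines carry a leading name column.
#' @return A [complex_catalog()].
#' @export
read_complexes <- function(path, named = FALSE) {
  if (!file.exists(path)) parse_error(sprintf("cannot read complex file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  empty <- !nzchar(trimws(lines))
  if (any(empty))
    warning(sprintf("complex file '%s': skipped %d empty line(s)",
                    path, sum(empty)))
  fields <- split_fields(lines[!empty])
  nms <- NULL
  if (named) {
    short <- which(lengths(fields) < 2L)
    if (length(short))
      parse_error(sprintf("complex file '%s': a named line has no members", path))
    nms <- vapply(fields, `[`, "", 1L)
    fields <- lapply(fields, `[`, -1L)
  }
  names(fields) <- nms
  complex_catalog(fields)
}

#' Complex-context members of a protein
#'
#' The union of all complexes containing `p` (which therefore includes `p`),
#' or `NULL` when `p` belongs to no complex — the caller then falls back to
#' the interaction neighborhood as context scope.
#'
#' @param cat a [complex_catalog()].
#' @param p protein identifier.
#' @return Sorted character vector, or `NULL` if `p` is in no complex.
#' @export
complex_context <- function(cat, p) {
  stopifnot(inherits(cat, "complex_catalog"))
  idx <- cat$membership[[p]]
  if (is.null(idx)) return(NULL)
  sort(unique(unlist(cat$complexes[idx], use.names = FALSE)))
}

#' @export
#' @method print complex_catalog
print.complex_catalog <- function(x, ...) {
  cat(sprintf("Complex catalog: %d complexes, %d distinct proteins\n",
              length(x$complexes), length(x$membership)))
  invisible(x)
}

#' Write a complex catalog as a flat file
#' @param cat a [complex_catalog()].
#' @param path output path.
#' @param named write complex names (or `cplx<i>`) as a first column.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(cat, path, named = TRUE) {
  stopifnot(inherits(cat, "complex_catalog"))
  nms <- names(cat$complexes) %||% sprintf("cplx%04d", seq_along(cat$complexes))
  if (named && length(cat$complexes) && !length(nms))
    nms <- sprintf("cplx%04d", seq_along(cat$complexes))
  lines <- vapply(seq_along(cat$complexes), function(i) {
    mem <- paste(cat$complexes[[i]], collapse = "\t")
    if (named) paste(nms[i], mem, sep = "\t") else mem
  }, "")
  writeLines(lines, path)
  invisible(path)
}
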