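#' Read a Gene Ontology OBO file (minimal)
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines; obsolete terms are dropped.  Only the
#' parent structure needed for ancestor propagation is retained — this is not
#' a general OBO parser.
#'
#' @param path path to an OBO file.
#' @return An object of class `go_ontology`: `parents`, a named list mapping
#'   each term to its direct `is_a`/`part_of` parents, and `namespace`, a
#'   named character vector.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("cannot read OBO file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  parents <- list(); namespace <- character()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      hit <- block[startsWith(block, paste0(key, ": "))]
      if (length(hit)) sub(paste0("^", key, ": "), "", hit) else character()
    }
    id <- get1("id")[1L]
    if (is.na(id) || !length(id)) next
    if (any(get1("is_obsolete") == "true")) next
    isa <- sub(" !.*$", "", get1("is_a"))
    rel <- get1("relationship")
    po <- sub(" !.*$", "", sub("^part_of ", "", rel[startsWith(rel, "part_of ")]))
    parents[[id]] <- sort(unique(c(isa, po)))
    ns <- get1("namespace")
    if (length(ns)) namespace[id] <- ns[1L]
  }
  structure(list(parents = parents, namespace = namespace,
                 cache = new.env(parent = emptyenv())),
            class = "go_ontology")
}

#' All ancestors of a GO term
#'
#' Transitive closure over `is_a` and `part_of`, the term itself excluded.
#' Terms unknown to the ontology have no ancestors.  Results are memoized on
#' the ontology object.
#'
#' @param ontology a [read_obo()] result.
#' @param term GO term identifier.
#' @return Sorted character vector of ancestor term identifiers.
#' @export
go_ancestors <- function(ontology, term) {
  stopifnot(inherits(ontology, "go_ontology"))
  cached <- ontology$cache[[term]]
  if (!is.null(cached)) return(cached)
  seen <- character()
  frontier <- ontology$parents[[term]] %||% character()
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(ontology$parents[new], use.names = FALSE))
  }
  res <- sort(unique(seen))
  assign(term, res, envir = ontology$cache)
  res
}
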