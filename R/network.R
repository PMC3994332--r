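#' Construct a protein-protein interaction network
#'
#' An undirected, unweighted protein interaction network.  Self-interactions
#' are removed and duplicate edges (in either orientation) collapsed, so the
#' stored edge set is a set of unordered protein pairs.  Proteins with no
#' surviving edge are kept as isolated vertices.  All protein orderings are
#' lexicographic, which makes every downstream tie-break deterministic.
#'
#' @param edges two-column character matrix or data frame of interacting
#'   protein pairs; may be `NULL` for an edgeless network.
#' @param proteins additional protein identifiers to include as (possibly
#'   isolated) vertices.
#' @return An object of class `ppi_network` with elements `proteins` (sorted
#'   character vector), `edges` (two-column character matrix, each row sorted,
#'   rows in lexicographic order) and `adjacency` (named list of sorted
#'   neighbor vectors, self excluded).
#' @seealso [read_ppi_edgelist()], [ppi_neighbors()]
#' @export
ppi_network <- function(edges = NULL, proteins = character()) {
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L)
      parse_error("edge input must have at least two columns")
    edges <- edges[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
  }
  keep <- edges[, 1L] != edges[, 2L]          # drop self-interactions
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges)) {
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  prots <- sort(unique(c(as.character(proteins), as.vector(edges))))
  adjacency <- rep(list(character()), length(prots))
  names(adjacency) <- prots
  if (nrow(edges)) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    nb <- lapply(nb, function(x) sort(unique(x)))
    adjacency[names(nb)] <- nb
  }
  colnames(edges) <- c("protein_a", "protein_b")
  structure(list(proteins = prots, edges = edges, adjacency = adjacency),
            class = "ppi_network")
}

#' Read a PPI network from a whitespace/tab edge list
#'
#' Lines starting with `comment_prefix` and blank lines are skipped; columns
#' beyond the first two are ignored.  Duplicate edges and self-interactions
#' are removed on construction.
#'
#' @param path path to the edge-list file.
#' @param comment_prefix prefix marking comment lines (default `"#"`).
#' @return A [ppi_network()] object.
#' @export
read_ppi_edgelist <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) parse_error(sprintf("cannot read PPI file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- split_fields(lines[keep])
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    parse_error(sprintf("PPI file '%s': line %d has fewer than 2 columns",
                        path, idx[bad[1L]]))
  edges <- do.call(rbind, lapply(fields, `[`, 1:2))
  ppi_network(edges)
}

#' Closed neighborhood of a protein
#'
#' Returns the protein's interaction partners with the protein itself
#' included, so the result is never empty.  This closed neighborhood is the
#' context scope of the neighbor-based similarity.
#'
#' @param net a [ppi_network()].
#' @param p a protein identifier present in `net`.
#' @return Sorted character vector of protein identifiers, containing `p`.
#' @export
ppi_neighbors <- function(net, p) {
  stopifnot(inherits(net, "ppi_network"))
  if (!p %in% net$proteins)
    stop(sprintf("protein '%s' is not in the network", p))
  sort(unique(c(net$adjacency[[p]], p)))
}

#' @export
#' @method print ppi_network
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Write a network back to a two-column edge list
#'
#' Each undirected edge is written once, endpoints in lexicographic order.
#' Isolated proteins are not representable in an edge list and are not
#' written; [write_bundle()] records them in its ground-truth JSON instead.
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edgelist <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Protein-to-domain assignment table
#'
#' Maps each protein to its set of domain-type accessions (Pfam-A style in
#' the intended use, but accessions are opaque strings).  A protein with no
#' assignment maps to the empty set.
#'
#' @param assignments named list, protein identifier to character vector of
#'   domain accessions; duplicates are collapsed.
#' @return An object of class `domain_table`.
#' @export
domain_table <- function(assignments = list()) {
  stopifnot(is.list(assignments))
  if (length(assignments) && is.null(names(assignments)))
    stop("assignments must be a named list")
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  if (length(assignments)) {
    assignments <- assignments[order(names(assignments))]
    assignments <- assignments[lengths(assignments) > 0L]
  }
  structure(list(assignments = assignments), class = "domain_table")
}

#' Read a protein-to-domain table
#'
#' Expects one assignment per line: `protein_id<TAB>domain_accession`
#' (whitespace also accepted).  Repeated rows collapse to one; set semantics
#' throughout.
#'
#' @param path path to the table.
#' @return A [domain_table()].
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("cannot read domain file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- split_fields(lines[keep])
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    parse_error(sprintf("domain file '%s': line %d has fewer than 2 columns",
                        path, idx[bad[1L]]))
  if (!length(fields)) return(domain_table())
  prot <- vapply(fields, `[`, "", 1L)
  dom <- vapply(fields, `[`, "", 2L)
  domain_table(split(dom, prot))
}

# Domain set of one protein (empty set when unassigned).
domains_of <- function(dt, p) {
  stopifnot(inherits(dt, "domain_table"))
  dt$assignments[[p]] %||% character()
}

#' Domain-type universe of a network
#'
#' The universe is the union of domain types over the proteins of the
#' network; its size is the `M` of the hypergeometric similarity score.
#' Assignments for proteins outside the network are ignored.
#'
#' @param net a [ppi_network()].
#' @param dt a [domain_table()].
#' @return Sorted character vector of domain accessions (use `length()` for
#'   the count `M`).
#' @export
domain_universe <- function(net, dt) {
  stopifnot(inherits(net, "ppi_network"), inherits(dt, "domain_table"))
  sort(unique(unlist(dt$assignments[intersect(names(dt$assignments),
                                              net$proteins)],
                     use.names = FALSE)))
}

#' @export
#' @method print domain_table
print.domain_table <- function(x, ...) {
  cat(sprintf("Domain table: %d proteins with domains, %d distinct accessions\n",
              length(x$assignments),
              length(unique(unlist(x$assignments, use.names = FALSE)))))
  invisible(x)
}

#' Write a domain table as `protein<TAB>domain` rows
#' @param dt a [domain_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(dt, path) {
  stopifnot(inherits(dt, "domain_table"))
  rows <- data.frame(
    protein = rep(names(dt$assignments), lengths(dt$assignments)),
    domain = unlist(dt$assignments, use.names = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
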