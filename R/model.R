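#' Fit a domain combination similarity model
#'
#' Builds the similarity model over a PPI network and a protein-to-domain
#' table.  For each protein the model caches its domain *composition* set
#' (the protein's own domain types) and its domain *context* set: under
#' method `"DCS"` the union of domain types over the closed interaction
#' neighborhood; under `"DSCP"` the union over all complexes containing the
#' protein, falling back to the neighborhood for proteins in no complex
#' (experimental complex catalogs cover only part of a network).  The
#' similarity of two proteins is
#' `lambda * f_cont + (1 - lambda) * f_comp`, where each component is the
#' negative log hypergeometric probability of the observed overlap of the
#' corresponding sets within the network-wide universe of `M` domain types
#' (see [hyper_score()]).
#'
#' `M` is always the global network universe, also for complex contexts;
#' complex members absent from the network carry no domain information into
#' a context.  Domain and topology information of *unannotated* proteins is
#' always used — annotation transfer hides labels, not domains or edges.
#'
#' @param network a [ppi_network()].
#' @param domains a [domain_table()].
#' @param complexes a [complex_catalog()]; required for `method = "DSCP"`
#'   (an empty catalog is allowed, making DSCP identical to DCS).
#' @param lambda context weight in `[0, 1]`; the default 0.1 weights
#'   composition heavily.  `lambda = 1` gives the context-only Zhang-DC
#'   similarity.
#' @param method `"DCS"` (neighborhood context) or `"DSCP"` (complex context
#'   with neighborhood fallback).
#' @param log_base `"natural"` or `"ten"`; rescales all scores equally.
#' @return An object of class `dcs`: a list with the inputs plus `proteins`,
#'   `universe`, `M`, and sparse logical protein-by-domain matrices
#'   `composition` and `context`.
#' @seealso [predict.dcs()], [pairwise_similarity()], [cross_validate()]
#' @examples
#' net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
#' dt <- domain_table(list(A = c("d1", "d2"), B = "d2", C = "d3"))
#' fit <- dcs(net, dt, lambda = 0.1)
#' pairwise_similarity(fit)
#' @export
dcs <- function(network, domains, complexes = NULL, lambda = 0.1,
                method = c("DCS", "DSCP"), log_base = c("natural", "ten")) {
  stopifnot(inherits(network, "ppi_network"), inherits(domains, "domain_table"))
  method <- match.arg(method)
  log_base <- match.arg(log_base)
  if (!is_prob(lambda)) usage_error("lambda must lie in [0, 1]")
  if (method == "DSCP" && is.null(complexes))
    usage_error("method 'DSCP' requires a complex catalog (it may be empty)")
  if (!is.null(complexes)) stopifnot(inherits(complexes, "complex_catalog"))

  prots <- network$proteins
  universe <- domain_universe(network, domains)
  n <- length(prots); M <- length(universe)

  comp <- Matrix::sparseMatrix(
    i = integer(), j = integer(), dims = c(n, M),
    dimnames = list(prots, universe))
  assigned <- intersect(names(domains$assignments), prots)
  if (length(assigned) && M > 0) {
    i <- rep(match(assigned, prots), lengths(domains$assignments[assigned]))
    j <- match(unlist(domains$assignments[assigned], use.names = FALSE), universe)
    comp <- Matrix::sparseMatrix(i = i, j = j, dims = c(n, M),
                                 dimnames = list(prots, universe))
  }
  comp <- comp > 0

  # closed-neighborhood incidence: row p marks p and its partners
  nb <- network$adjacency[prots]
  i <- c(seq_len(n), rep(seq_len(n), lengths(nb)))
  j <- c(seq_len(n), match(unlist(nb, use.names = FALSE), prots))
  closed <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                                 dimnames = list(prots, prots))
  ctx <- ((closed %*% comp) > 0)

  if (method == "DSCP" && length(complexes$complexes)) {
    covered <- intersect(names(complexes$membership), prots)
    for (p in covered) {
      members <- intersect(complex_context(complexes, p), prots)
      ctx[p, ] <- Matrix::colSums(comp[members, , drop = FALSE]) > 0
    }
  }

  structure(list(proteins = prots, universe = universe, M = M,
                 lambda = lambda, method = method, log_base = log_base,
                 composition = comp, context = ctx,
                 network = network, domains = domains, complexes = complexes),
            class = "dcs")
}

#' @export
#' @method print dcs
print.dcs <- function(x, ...) {
  cat(sprintf("Domain combination similarity model (%s)\n", x$method))
  cat(sprintf("  proteins: %d   interactions: %d   domain universe M: %d\n",
              length(x$proteins), nrow(x$network$edges), x$M))
  cat(sprintf("  lambda: %g   log base: %s\n", x$lambda, x$log_base))
  if (x$method == "DSCP") {
    cov <- sum(names(x$complexes$membership) %in% x$proteins)
    cat(sprintf("  complex catalog: %d complexes, %d network proteins covered\n",
                length(x$complexes$complexes), cov))
  }
  invisible(x)
}

#' @export
#' @method summary dcs
summary.dcs <- function(object, ...) {
  ctx_sizes <- Matrix::rowSums(object$context)
  comp_sizes <- Matrix::rowSums(object$composition)
  out <- list(method = object$method, lambda = object$lambda, M = object$M,
              n_proteins = length(object$proteins),
              n_edges = nrow(object$network$edges),
              domain_free = sum(comp_sizes == 0),
              context_size = summary(as.numeric(ctx_sizes)),
              composition_size = summary(as.numeric(comp_sizes)),
              complex_coverage = if (object$method == "DSCP")
                sum(names(object$complexes$membership) %in% object$proteins)
              else NA_integer_)
  class(out) <- "summary.dcs"
  out
}

#' @export
#' @method print summary.dcs
print.summary.dcs <- function(x, ...) {
  cat(sprintf("%s model: %d proteins, %d interactions, M = %d, lambda = %g\n",
              x$method, x$n_proteins, x$n_edges, x$M, x$lambda))
  cat(sprintf("  proteins without domain assignment: %d\n", x$domain_free))
  cat("  context set sizes:\n"); print(x$context_size)
  cat("  composition set sizes:\n"); print(x$composition_size)
  if (!is.na(x$complex_coverage))
    cat(sprintf("  proteins covered by a complex: %d\n", x$complex_coverage))
  invisible(x)
}

#' @export
coef.dcs <- function(object, ...) c(lambda = object$lambda)

#' Context domain set of a protein under a model's method
#'
#' @param object a [dcs()] model.
#' @param p protein identifier in the model's network.
#' @return Sorted character vector of domain accessions (possibly empty).
#' @export
context_set <- function(object, p) {
  stopifnot(inherits(object, "dcs"))
  if (!p %in% object$proteins)
    stop(sprintf("protein '%s' is not in the network", p))
  object$universe[as.logical(object$context[p, ])]
}

#' @rdname context_set
#' @export
composition_set <- function(object, p) {
  stopifnot(inherits(object, "dcs"))
  if (!p %in% object$proteins)
    stop(sprintf("protein '%s' is not in the network", p))
  object$universe[as.logical(object$composition[p, ])]
}

# Dense score matrix for one component over the whole network (or a subset
# of row proteins).  S[i, j] = hyper_score(M, |set_i|, |set_j|, |set_i n set_j|).
component_matrix <- function(object, which = c("context", "composition"),
                             rows = NULL) {
  which <- match.arg(which)
  B <- object[[which]] * 1             # logical -> numeric sparse
  sizes <- Matrix::rowSums(B)
  rows <- rows %||% object$proteins
  ri <- match(rows, object$proteins)
  S <- as.matrix(B[ri, , drop = FALSE] %*% Matrix::t(B))
  a <- matrix(sizes[ri], nrow = length(ri), ncol = length(object$proteins))
  b <- matrix(sizes, nrow = length(ri), ncol = length(object$proteins),
              byrow = TRUE)
  M <- object$M
  score <- -(lchoose(M, S) + lchoose(M - S, a - S) + lchoose(M - a, b - S) -
               lchoose(M, a) - lchoose(M, b))
  if (object$log_base == "ten") score <- score / log(10)
  score <- pmax(score, 0)
  dimnames(score) <- list(rows, object$proteins)
  score
}

# Full combined-similarity matrix (dense; intended for networks of up to a
# few thousand proteins, which covers every protocol in the package).
similarity_matrix <- function(object, component = c("sim", "cont", "comp"),
                              rows = NULL) {
  component <- match.arg(component)
  switch(component,
         cont = component_matrix(object, "context", rows),
         comp = component_matrix(object, "composition", rows),
         sim = object$lambda * component_matrix(object, "context", rows) +
           (1 - object$lambda) * component_matrix(object, "composition", rows))
}

#' Pairwise similarities under a fitted model
#'
#' Computes `f_cont`, `f_comp` and the combined `f_sim` for protein pairs.
#' By default all unordered pairs of network proteins are scored, each pair
#' written once with `protein_a < protein_b` lexicographically.
#'
#' @param object a [dcs()] model.
#' @param pairs optional two-column matrix or data frame of protein pairs to
#'   score (order within a pair does not matter — the scores are symmetric).
#' @return A data frame with columns `protein_a`, `protein_b`, `f_cont`,
#'   `f_comp`, `f_sim`.
#' @export
pairwise_similarity <- function(object, pairs = NULL) {
  stopifnot(inherits(object, "dcs"))
  if (is.null(pairs)) {
    n <- length(object$proteins)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pa <- object$proteins[idx[, 1L]]
    pb <- object$proteins[idx[, 2L]]
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) >= 2L)
    pa <- as.character(pairs[, 1L]); pb <- as.character(pairs[, 2L])
    unknown <- setdiff(c(pa, pb), object$proteins)
    if (length(unknown))
      stop(sprintf("protein '%s' is not in the network", unknown[1L]))
    flip <- pa > pb
    tmp <- pa[flip]; pa[flip] <- pb[flip]; pb[flip] <- tmp
  }
  ia <- match(pa, object$proteins); ib <- match(pb, object$proteins)
  score_pairs <- function(B) {
    sizes <- Matrix::rowSums(B)
    s <- Matrix::rowSums(B[ia, , drop = FALSE] & B[ib, , drop = FALSE])
    hyper_score(object$M, sizes[ia], sizes[ib], s, log_base = object$log_base)
  }
  cont <- score_pairs(object$context)
  comp <- score_pairs(object$composition)
  data.frame(protein_a = pa, protein_b = pb,
             f_cont = cont, f_comp = comp,
             f_sim = f_sim(cont, comp, object$lambda))
}

#' Write a pairwise similarity table as TSV
#' @param sim data frame from [pairwise_similarity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  utils::write.table(sim, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
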