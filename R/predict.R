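# Function transfer from nearest similar annotated proteins, plus the two
# classical neighborhood baselines used for comparison.

# Rank candidate reference proteins for `u` by similarity, descending, ties
# broken lexicographically by identifier (the deterministic realization of
# the "first coming" rule).  `simrow` is a named similarity vector.
rank_references <- function(simrow, known) {
  known <- sort(known)                      # lexicographic tie order
  sc <- simrow[known]
  ord <- order(-sc)                         # stable: ties keep sorted id order
  data.frame(protein = known[ord], score = as.numeric(sc[ord]))
}

# Core transfer for one test protein: top-k annotated proteins with score
# strictly > 0; predicted terms are the union of their term sets.
transfer_terms <- function(simrow, known, term_sets, k) {
  ranked <- rank_references(simrow, known)
  ranked <- ranked[ranked$score > 0, , drop = FALSE]
  refs <- utils::head(ranked, k)
  if (!nrow(refs))
    return(list(terms = character(), references = refs, status = "unpredicted"))
  terms <- sort(unique(unlist(term_sets[refs$protein], use.names = FALSE)))
  list(terms = terms, references = refs, status = "predicted")
}

#' Predict GO annotations for unannotated proteins
#'
#' For each query protein the annotated network proteins are ranked by
#' combined similarity `f_sim`; the annotations (in the requested aspect) of
#' the top `k` proteins with strictly positive similarity are transferred as
#' the predicted set.  Ties are broken lexicographically by protein
#' identifier.  A query with no positively similar annotated protein is
#' reported as unpredicted.  Prediction is per aspect: the chosen reference
#' may differ between MF, CC and BP because annotations are filtered per
#' aspect.
#'
#' @param object a [dcs()] model.
#' @param annotations an [annotation_table()] providing the known labels
#'   (apply [filter_annotations()] first if the benchmark filters are
#'   wanted).
#' @param newdata character vector of query proteins; defaults to every
#'   network protein without annotation in `aspect`.  A query may not itself
#'   be annotated in `aspect`.
#' @param aspect `"MF"`, `"CC"` or `"BP"`.
#' @param k number of reference proteins whose term sets are united
#'   (default 1: nearest annotated protein only).
#' @param ... unused.
#' @return An object of class `dcs_prediction`: a data frame with one row
#'   per (protein, term) pair — columns `protein`, `aspect`, `term`,
#'   `reference`, `similarity` — plus attributes `status` (named character:
#'   predicted/unpredicted per query) and `references` (per-query ranked
#'   reference data frames).
#' @export
predict.dcs <- function(object, annotations, newdata = NULL,
                        aspect = c("MF", "CC", "BP"), k = 1L, ...) {
  stopifnot(inherits(annotations, "annotation_table"))
  aspect <- match.arg(aspect)
  if (!is_count(k) || k < 1) usage_error("k must be a positive integer")
  term_sets <- annotations$protein_index[[aspect]]
  known <- intersect(names(term_sets), object$proteins)
  if (is.null(newdata)) newdata <- setdiff(object$proteins, known)
  newdata <- as.character(newdata)
  unknown <- setdiff(newdata, object$proteins)
  if (length(unknown))
    stop(sprintf("protein '%s' is not in the network", unknown[1L]))
  bad <- intersect(newdata, known)
  if (length(bad))
    stop(sprintf("query protein '%s' is annotated in the training view", bad[1L]))
  if (!length(known))
    usage_error("no annotated proteins available as references")

  simmat <- similarity_matrix(object, rows = newdata)
  rows <- list(); status <- character(); refs_out <- list()
  for (u in newdata) {
    res <- transfer_terms(simmat[u, ], known, term_sets, k)
    status[u] <- res$status
    refs_out[[u]] <- res$references
    if (length(res$terms))
      rows[[u]] <- data.frame(protein = u, aspect = aspect, term = res$terms,
                              reference = res$references$protein[1L],
                              similarity = res$references$score[1L])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), aspect = character(), term = character(),
               reference = character(), similarity = numeric())
  rownames(out) <- NULL
  structure(out, status = status, references = refs_out, k = k,
            class = c("dcs_prediction", "data.frame"))
}

#' @export
#' @method print dcs_prediction
print.dcs_prediction <- function(x, ...) {
  st <- attr(x, "status")
  cat(sprintf("Function predictions: %d proteins queried, %d predicted, %d term assignments\n",
              length(st), sum(st == "predicted"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write predictions as TSV
#'
#' Columns: protein, aspect, go_term, reference_protein, similarity.
#'
#' @param pred a [predict.dcs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(as.data.frame(pred), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("protein", "aspect", "go_term",
                                   "reference_protein", "similarity"))
  invisible(path)
}

#' Neighborhood-counting and chi-square term rankers
#'
#' Classical direct neighborhood baselines.  `nc_ranker` scores each GO term
#' by the number of annotated interaction partners of the query carrying it
#' (the query itself excluded).  `chisq_ranker` corrects that count for the
#' background frequency of the term: with `n_f` annotated partners carrying
#' the term and `e_f` the count expected from the term's frequency among all
#' annotated network proteins, the score is `(n_f - e_f)^2 / e_f`.  Both
#' rank descending with lexicographic GO-id tie-break and only return terms
#' with strictly positive score.
#'
#' @param network a [ppi_network()].
#' @return A ranker object usable with [rank_terms()], [cross_validate()]
#'   and [pr_curve()].
#' @export
nc_ranker <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  structure(list(network = network, label = "NC"),
            class = c("nc_ranker", "term_ranker"))
}

#' @rdname nc_ranker
#' @export
chisq_ranker <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  structure(list(network = network, label = "Chi-square"),
            class = c("chisq_ranker", "term_ranker"))
}

#' Rank candidate GO terms for a query protein
#'
#' @param ranker an [nc_ranker()] or [chisq_ranker()].
#' @param u query protein.
#' @param term_sets named list mapping each *known* (annotated) protein to
#'   its term set in the aspect under study; the query must not appear.
#' @return Data frame with columns `term`, `score`, positive scores only,
#'   ranked descending (ties by GO id).
#' @export
rank_terms <- function(ranker, u, term_sets) UseMethod("rank_terms")

neighbor_term_counts <- function(network, u, term_sets) {
  nb <- setdiff(network$adjacency[[u]] %||% character(), u)
  nb <- intersect(nb, names(term_sets))
  counts <- table(unlist(term_sets[nb], use.names = FALSE))
  list(counts = counts, n_annot_neighbors = length(nb))
}

#' @export
rank_terms.nc_ranker <- function(ranker, u, term_sets) {
  ct <- neighbor_term_counts(ranker$network, u, term_sets)$counts
  terms <- sort(names(ct))
  score <- as.numeric(ct[terms])
  ord <- order(-score)
  out <- data.frame(term = terms[ord], score = score[ord])
  out[out$score > 0, , drop = FALSE]
}

#' @export
rank_terms.chisq_ranker <- function(ranker, u, term_sets) {
  obs <- neighbor_term_counts(ranker$network, u, term_sets)
  if (!length(obs$counts))
    return(data.frame(term = character(), score = numeric()))
  n_annotated <- length(term_sets)
  bg <- table(unlist(term_sets, use.names = FALSE)) / n_annotated
  terms <- sort(names(obs$counts))
  n_f <- as.numeric(obs$counts[terms])
  e_f <- obs$n_annot_neighbors * as.numeric(bg[terms])
  keep <- e_f > 0
  terms <- terms[keep]; n_f <- n_f[keep]; e_f <- e_f[keep]
  score <- (n_f - e_f)^2 / e_f
  ord <- order(-score)
  out <- data.frame(term = terms[ord], score = score[ord])
  out[out$score > 0, , drop = FALSE]
}
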