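# Cross-validation protocols and the four benchmark metrics.
#
# Two aggregation modes coexist deliberately: Table-style reports use
# per-GO-term macro averaging within term-size bins (each surviving term is
# one binary classifier accumulated over all validation rounds), while PR
# curves use per-protein micro averaging over a top-K sweep.  They answer
# different questions and are kept as separate entry points.

#' Binary classification metrics
#'
#' Precision (`metric_ppv`), recall (`metric_tpr`), F-measure (`metric_f`,
#' the harmonic mean of the two) and the Matthews correlation coefficient
#' (`metric_mcc`).  Zero-denominator cases return `NA`, are excluded from
#' averages, and the exclusion counts are reported by the summaries.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (vectorized).
#' @param ppv,tpr precision and recall values.
#' @return Numeric vector; `NA` where undefined.
#' @export
metric_ppv <- function(tp, fp) ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)

#' @rdname metric_ppv
#' @export
metric_tpr <- function(tp, fn) ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)

#' @rdname metric_ppv
#' @export
metric_f <- function(ppv, tpr)
  ifelse(!is.na(ppv) & !is.na(tpr) & ppv + tpr > 0,
         2 * ppv * tpr / (ppv + tpr),
         ifelse(!is.na(ppv) & !is.na(tpr), 0, NA_real_))

#' @rdname metric_ppv
#' @export
metric_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  ifelse(den > 0, (tp * tn - fn * fp) / den, NA_real_)
}

#' Bin GO terms by positive size
#'
#' The benchmark partitions surviving terms into four groups by the number
#' of proteins they annotate: `[10-30]`, `(30-50]`, `(50-100]`, `(100-200]`
#' (lower edge closed on the first bin only).
#'
#' @param sizes integer vector of term sizes, all within `[10, 200]`.
#' @return Factor with the four bin labels.
#' @export
bin_go_terms <- function(sizes) {
  if (any(sizes < 10 | sizes > 200))
    stop("term sizes must lie in [10, 200] after filtering")
  cut(sizes, breaks = c(9, 30, 50, 100, 200),
      labels = c("[10-30]", "(30-50]", "(50-100]", "(100-200]"))
}

#' Per-term confusion counts over a set of test proteins
#'
#' For each term, over the test proteins: `tp` annotated and predicted,
#' `fp` predicted but not annotated, `fn` annotated but not predicted,
#' `tn` neither.  An unpredicted protein therefore contributes one `fn` for
#' each of its true terms.
#'
#' @param predicted named list: test protein to predicted term set (missing
#'   or empty entries mean no prediction).
#' @param truth named list: test protein to true term set.
#' @param terms character vector of terms to score.
#' @param test_proteins the test proteins (rows of the implied decision
#'   matrix).
#' @return Data frame with columns `term`, `tp`, `fp`, `fn`, `tn`.
#' @export
term_confusion <- function(predicted, truth, terms, test_proteins) {
  Tm <- membership_matrix(truth, test_proteins, terms)
  Pm <- membership_matrix(predicted, test_proteins, terms)
  data.frame(term = terms,
             tp = colSums(Tm & Pm), fp = colSums(!Tm & Pm),
             fn = colSums(Tm & !Pm), tn = colSums(!Tm & !Pm),
             row.names = NULL)
}

membership_matrix <- function(sets, rows, cols) {
  m <- matrix(FALSE, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (r in rows) {
    s <- intersect(sets[[r]] %||% character(), cols)
    if (length(s)) m[r, s] <- TRUE
  }
  m
}

# Per-term metrics + binned macro summary from a confusion data frame.
# Size bins are only reported when every term size fits the benchmark's
# binnable range [10, 200] (always true after the default filter); the
# "In total" row is reported regardless.
summarize_confusion <- function(conf, sizes) {
  conf$size <- as.integer(sizes[conf$term])
  binnable <- nrow(conf) > 0 && all(conf$size >= 10 & conf$size <= 200)
  conf$bin <- if (binnable) bin_go_terms(conf$size) else
    factor(rep(NA_character_, nrow(conf)),
           levels = c("[10-30]", "(30-50]", "(50-100]", "(100-200]"))
  conf$ppv <- metric_ppv(conf$tp, conf$fp)
  conf$tpr <- metric_tpr(conf$tp, conf$fn)
  conf$f_measure <- metric_f(conf$ppv, conf$tpr)
  conf$mcc <- metric_mcc(conf$tp, conf$tn, conf$fp, conf$fn)
  bins <- if (binnable) c(levels(conf$bin), "In total") else "In total"
  rows <- lapply(bins, function(b) {
    sub <- if (b == "In total") conf else conf[conf$bin == b, , drop = FALSE]
    ppv <- mean(sub$ppv, na.rm = TRUE)
    tpr <- mean(sub$tpr, na.rm = TRUE)
    data.frame(size_bin = b, n_go_terms = nrow(sub),
               ppv = ppv, tpr = tpr, f_measure = metric_f(ppv, tpr),
               mcc = mean(sub$mcc, na.rm = TRUE),
               n_undefined_ppv = sum(is.na(sub$ppv)),
               n_undefined_mcc = sum(is.na(sub$mcc)))
  })
  summary <- do.call(rbind, rows)
  summary[c("ppv", "tpr", "f_measure", "mcc")] <-
    lapply(summary[c("ppv", "tpr", "f_measure", "mcc")],
           function(x) ifelse(is.nan(x), NA_real_, x))
  list(per_term = conf, summary = summary)
}

# Shared preparation: filter annotations against the evaluation network and
# assemble the aspect's term universe, sizes and per-protein term sets.
prepare_eval <- function(predictor, annotations, aspect, filter, ontology) {
  network <- if (inherits(predictor, "dcs")) predictor$network
             else predictor$network
  if (!is.null(filter)) {
    fa <- filter_annotations(annotations, filter, network, ontology)
    tab <- fa$table
    terms <- fa$terms[[aspect]]
    sizes <- fa$sizes[[aspect]]
  } else {
    tab <- annotations
    idx <- tab$term_index[[aspect]]
    sizes <- vapply(idx, function(p) sum(p %in% network$proteins), 0L)
    terms <- sort(names(idx))
    sizes <- sizes[terms]
  }
  term_sets <- tab$protein_index[[aspect]]
  term_sets <- term_sets[intersect(names(term_sets), network$proteins)]
  term_sets <- lapply(term_sets, intersect, y = terms)
  term_sets <- term_sets[lengths(term_sets) > 0L]
  annotated <- sort(names(term_sets))
  list(network = network, terms = terms, sizes = sizes,
       term_sets = term_sets, annotated = annotated)
}

# One round of prediction for a set of test proteins given the training view.
predict_sets <- function(predictor, test, known, term_sets, k,
                         simmat = NULL) {
  out <- list()
  if (inherits(predictor, "dcs")) {
    for (u in test) {
      res <- transfer_terms(simmat[u, ], setdiff(known, u), term_sets, k)
      out[[u]] <- res$terms
    }
  } else {
    for (u in test) {
      ranked <- rank_terms(predictor, u, term_sets[setdiff(known, u)])
      out[[u]] <- utils::head(ranked$term, k)
    }
  }
  out
}

#' Cross-validated function prediction benchmark
#'
#' Evaluates a similarity model (or a baseline term ranker) by hiding
#' annotations and predicting them back.  `scheme = "loo"` hides one
#' annotated protein per round, predicts its terms from all remaining
#' annotated proteins, and accumulates per-term confusion counts over all
#' rounds.  `scheme = "lpo"` hides a random percentage of the annotated
#' proteins per repeat, scores each repeat, and averages the binned metrics
#' over repeats.  Only a protein's *annotations* are hidden — its edges,
#' domains and complex memberships stay visible, as when predicting a
#' genuinely unannotated protein.
#'
#' @param predictor a [dcs()] model, or an [nc_ranker()]/[chisq_ranker()].
#' @param annotations an [annotation_table()] (unfiltered; the filter is
#'   applied internally so term sizes refer to the evaluation network).
#' @param aspect `"MF"`, `"CC"` or `"BP"`.
#' @param scheme `"loo"` or `"lpo"`.
#' @param k number of references (model) or top terms (ranker) per query.
#' @param filter a [term_filter()], or `NULL` to skip filtering.
#' @param ontology optional [read_obo()] ontology for ancestor propagation.
#' @param percent for `"lpo"`: fraction of annotated proteins hidden per
#'   repeat (values above 1 are read as percentages).
#' @param repeats for `"lpo"`: number of repeats.
#' @param seed for `"lpo"`: integer seed for the test-set draws.
#' @return An object of class `dcs_cv`: list with `summary` (binned macro
#'   metrics, Table-style, including an `In total` row), `per_term`
#'   (per-term confusion and metrics; for `"lpo"` from the last repeat),
#'   and the protocol settings.
#' @export
cross_validate <- function(predictor, annotations, aspect = c("MF", "CC", "BP"),
                           scheme = c("loo", "lpo"), k = 1L,
                           filter = term_filter(), ontology = NULL,
                           percent = NULL, repeats = 100L, seed = NULL) {
  aspect <- match.arg(aspect)
  scheme <- match.arg(scheme)
  if (!is_count(k) || k < 1) usage_error("k must be a positive integer")
  prep <- prepare_eval(predictor, annotations, aspect, filter, ontology)
  annotated <- prep$annotated
  if (!length(annotated))
    usage_error("no annotated proteins survive filtering for this aspect")
  simmat <- if (inherits(predictor, "dcs"))
    similarity_matrix(predictor, rows = annotated) else NULL

  if (scheme == "loo") {
    pred <- predict_sets(predictor, annotated, annotated, prep$term_sets, k,
                         simmat)
    conf <- term_confusion(pred, prep$term_sets, prep$terms, annotated)
    res <- summarize_confusion(conf, prep$sizes)
    rounds <- length(annotated)
  } else {
    if (is.null(percent)) usage_error("scheme 'lpo' requires percent")
    if (percent > 1) percent <- percent / 100
    if (!is_prob(percent) || percent <= 0 || percent >= 1)
      usage_error("percent must lie strictly between 0 and 1 (or 0 and 100)")
    if (!is_count(repeats) || repeats < 1)
      usage_error("repeats must be a positive integer")
    if (is.null(seed)) usage_error("scheme 'lpo' requires a seed")
    n_test <- max(1L, round(percent * length(annotated)))
    summaries <- with_seed(seed, lapply(seq_len(repeats), function(r) {
      test <- sort(sample(annotated, n_test))
      known <- setdiff(annotated, test)
      if (!length(known)) return(NULL)
      pred <- predict_sets(predictor, test, known, prep$term_sets, k, simmat)
      conf <- term_confusion(pred, prep$term_sets, prep$terms, test)
      summarize_confusion(conf, prep$sizes)
    }))
    summaries <- Filter(Negate(is.null), summaries)
    res <- list(per_term = summaries[[length(summaries)]]$per_term,
                summary = average_summaries(lapply(summaries, `[[`, "summary")))
    rounds <- length(summaries)
  }
  structure(list(summary = res$summary, per_term = res$per_term,
                 aspect = aspect, scheme = scheme, k = k, rounds = rounds,
                 n_annotated = length(annotated), n_terms = length(prep$terms),
                 predictor = if (inherits(predictor, "dcs"))
                   predictor$method else predictor$label),
            class = "dcs_cv")
}

# Mean of per-repeat binned summaries; F recomputed from averaged PPV/TPR.
average_summaries <- function(summaries) {
  base <- summaries[[1L]]
  num <- c("ppv", "tpr", "mcc", "n_undefined_ppv", "n_undefined_mcc")
  for (col in num) {
    vals <- sapply(summaries, `[[`, col)
    base[[col]] <- rowMeans(matrix(vals, nrow = nrow(base)), na.rm = TRUE)
  }
  base$f_measure <- metric_f(base$ppv, base$tpr)
  base[c("ppv", "tpr", "f_measure", "mcc")] <-
    lapply(base[c("ppv", "tpr", "f_measure", "mcc")],
           function(x) ifelse(is.nan(x), NA_real_, x))
  base
}

#' @export
#' @method print dcs_cv
print.dcs_cv <- function(x, digits = 3, ...) {
  cat(sprintf("%s cross-validation (%s, aspect %s, k = %d): %d rounds, %d annotated proteins, %d GO terms\n",
              toupper(x$scheme), x$predictor, x$aspect, x$k, x$rounds,
              x$n_annotated, x$n_terms))
  s <- x$summary
  s[c("ppv", "tpr", "f_measure", "mcc")] <-
    lapply(s[c("ppv", "tpr", "f_measure", "mcc")], round, digits = digits)
  print.data.frame(s, row.names = FALSE)
  nex <- sum(x$summary$n_undefined_ppv[x$summary$size_bin == "In total"])
  if (isTRUE(nex > 0))
    cat(sprintf("  (%g term(s) with undefined PPV excluded from averages)\n", nex))
  invisible(x)
}

#' Write a binned metrics report as TSV
#' @param cv a [cross_validate()] result.
#' @param path output path.
#' @param method optional method label column.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(cv, path, method = cv$predictor) {
  out <- cbind(method = method, aspect = cv$aspect, cv$summary)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Precision-recall curve over a top-K sweep
#'
#' Leave-one-out protocol: each annotated protein in turn is the single test
#' protein.  For a similarity model the predictions at `K` are the union of
#' the term sets of its top-`K` positively similar annotated proteins; for a
#' term ranker they are its top-`K` positively scored terms.  Per protein
#' and `K`, precision and recall are computed from the predicted-vs-true
#' term sets; curve points are their averages over test proteins (a protein
#' with an empty prediction contributes recall 0 and is excluded from the
#' precision average), and the reported `max_f` is the maximum F-measure
#' over the curve.
#'
#' @inheritParams cross_validate
#' @param k_max largest `K` of the sweep (default 50).
#' @return An object of class `dcs_pr`: data frame with columns `k`, `tpr`,
#'   `ppv`, `f_measure`, plus attribute `max_f`.
#' @export
pr_curve <- function(predictor, annotations, aspect = c("MF", "CC", "BP"),
                     k_max = 50L, filter = term_filter(), ontology = NULL) {
  aspect <- match.arg(aspect)
  if (!is_count(k_max) || k_max < 1) usage_error("k_max must be positive")
  prep <- prepare_eval(predictor, annotations, aspect, filter, ontology)
  annotated <- prep$annotated
  if (!length(annotated))
    usage_error("no annotated proteins survive filtering for this aspect")
  simmat <- if (inherits(predictor, "dcs"))
    similarity_matrix(predictor, rows = annotated) else NULL

  tprs <- matrix(0, length(annotated), k_max)
  ppvs <- matrix(NA_real_, length(annotated), k_max)
  for (i in seq_along(annotated)) {
    u <- annotated[i]
    truth <- prep$term_sets[[u]]
    known <- setdiff(annotated, u)
    if (inherits(predictor, "dcs")) {
      ranked <- rank_references(simmat[u, ], known)
      ranked <- ranked[ranked$score > 0, , drop = FALSE]
      cur <- character()
      for (kk in seq_len(k_max)) {
        if (kk <= nrow(ranked))
          cur <- union(cur, prep$term_sets[[ranked$protein[kk]]])
        if (length(cur)) {
          hits <- length(intersect(cur, truth))
          ppvs[i, kk] <- hits / length(cur)
          tprs[i, kk] <- hits / length(truth)
        }
      }
    } else {
      ranked <- rank_terms(predictor, u, prep$term_sets[known])
      for (kk in seq_len(k_max)) {
        cur <- utils::head(ranked$term, kk)
        if (length(cur)) {
          hits <- length(intersect(cur, truth))
          ppvs[i, kk] <- hits / length(cur)
          tprs[i, kk] <- hits / length(truth)
        }
      }
    }
  }
  curve <- data.frame(k = seq_len(k_max),
                      tpr = colMeans(tprs),
                      ppv = colMeans(ppvs, na.rm = TRUE))
  curve$ppv[is.nan(curve$ppv)] <- NA_real_
  curve$f_measure <- metric_f(curve$ppv, curve$tpr)
  structure(curve, max_f = max(curve$f_measure, na.rm = TRUE),
            aspect = aspect,
            predictor = if (inherits(predictor, "dcs")) predictor$method
                        else predictor$label,
            class = c("dcs_pr", "data.frame"))
}

#' @export
#' @method print dcs_pr
print.dcs_pr <- function(x, ...) {
  cat(sprintf("PR curve (%s, aspect %s): K = 1..%d, max F-measure = %.3f\n",
              attr(x, "predictor"), attr(x, "aspect"), nrow(x),
              attr(x, "max_f")))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat(sprintf("  ... and %d more K values\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
plot.dcs_pr <- function(x, ...) {
  plot(x$tpr, x$ppv, type = "b", xlab = "TPR (recall)", ylab = "PPV (precision)",
       main = sprintf("%s, aspect %s (max F = %.3f)", attr(x, "predictor"),
                      attr(x, "aspect"), attr(x, "max_f")), ...)
  invisible(x)
}

#' Write a PR curve as TSV
#' @param pr a [pr_curve()] result.
#' @param path output path.
#' @param method optional method label column.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(pr, path, method = attr(pr, "predictor")) {
  out <- cbind(method = method, aspect = attr(pr, "aspect"),
               as.data.frame(pr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label-permutation null for the leave-one-out benchmark
#'
#' Shuffles whole per-protein term sets among the annotated proteins and
#' recomputes the leave-one-out macro F-measure for each shuffle.  Because
#' similarities depend only on domains and topology, the reference ranking
#' is fixed under the shuffle; only the transferred labels change, so the
#' null distribution isolates how much of the observed performance is
#' explained by domain--function coupling rather than by term-set sizes.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label shuffles.
#' @param seed integer seed for the shuffles.
#' @return A list with `observed` (macro F of the unshuffled labels), `null`
#'   (numeric vector of length `n_perm`) and `quantile95`.
#' @export
permutation_null <- function(predictor, annotations,
                             aspect = c("MF", "CC", "BP"), k = 1L,
                             n_perm = 100L, seed = 1L,
                             filter = term_filter(), ontology = NULL) {
  stopifnot(inherits(predictor, "dcs"))
  aspect <- match.arg(aspect)
  prep <- prepare_eval(predictor, annotations, aspect, filter, ontology)
  annotated <- prep$annotated
  simmat <- similarity_matrix(predictor, rows = annotated)

  # reference ids per test protein are label-independent: compute once
  refs <- lapply(annotated, function(u) {
    ranked <- rank_references(simmat[u, ], setdiff(annotated, u))
    utils::head(ranked$protein[ranked$score > 0], k)
  })
  names(refs) <- annotated

  macro_f <- function(term_sets) {
    pred <- lapply(refs, function(r)
      sort(unique(unlist(term_sets[r], use.names = FALSE))))
    conf <- term_confusion(pred, term_sets, prep$terms, annotated)
    s <- summarize_confusion(conf, prep$sizes)$summary
    s$f_measure[s$size_bin == "In total"]
  }
  observed <- macro_f(prep$term_sets)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- sample(annotated)
    shuffled <- prep$term_sets[perm]
    names(shuffled) <- annotated
    macro_f(shuffled)
  }, 0))
  list(observed = observed, null = null,
       quantile95 = stats::quantile(null, 0.95, names = FALSE))
}

#' Mean similarity as a function of GO-term overlap
#'
#' Summarizes, over all pairs of annotated network proteins, the mean
#' combined similarity within bins of GO-term overlap (the number of shared
#' terms in the chosen aspect).  When domain composition and function are
#' positively coupled, the mean similarity increases with the overlap,
#' which is the diagnostic that the similarity tracks functional
#' relatedness.
#'
#' @param object a [dcs()] model.
#' @param annotations an [annotation_table()].
#' @param aspect `"MF"`, `"CC"` or `"BP"`.
#' @param max_overlap overlaps at or above this value are pooled into the
#'   top bin (default 2, giving bins `0`, `1`, `2+`).
#' @return Data frame with columns `overlap`, `n_pairs`, `mean_f_sim`.
#' @export
similarity_vs_overlap <- function(object, annotations,
                                  aspect = c("MF", "CC", "BP"),
                                  max_overlap = 2L) {
  stopifnot(inherits(object, "dcs"), inherits(annotations, "annotation_table"))
  aspect <- match.arg(aspect)
  if (!is_count(max_overlap) || max_overlap < 1)
    usage_error("max_overlap must be a positive integer")
  idx <- annotations$protein_index[[aspect]]
  ann <- intersect(names(idx), object$proteins)
  sim <- pairwise_similarity(object)
  keep <- sim$protein_a %in% ann & sim$protein_b %in% ann
  sim <- sim[keep, , drop = FALSE]
  ov <- mapply(function(pa, pb) length(intersect(idx[[pa]], idx[[pb]])),
               sim$protein_a, sim$protein_b)
  labels <- c(as.character(seq_len(max_overlap) - 1L),
              paste0(max_overlap, "+"))
  bin <- cut(pmin(ov, max_overlap), breaks = c(-1, seq_len(max_overlap) - 1L,
                                               max_overlap),
             labels = labels)
  data.frame(overlap = labels,
             n_pairs = as.integer(table(bin)),
             mean_f_sim = as.numeric(tapply(sim$f_sim, bin, mean)))
}
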