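#' Gene Ontology annotation table
#'
#' Stores unique (protein, GO term, aspect, evidence) records, with the three
#' ontology aspects coded `MF` (molecular function), `CC` (cellular
#' component) and `BP` (biological process).
#'
#' @param records data frame with character columns `protein`, `term`,
#'   `aspect`, `evidence`.  Single-letter aspects `F`/`C`/`P` are recoded;
#'   duplicate records are collapsed.
#' @return An object of class `annotation_table`: the deduplicated `records`
#'   data frame (sorted), plus `term_index` and `protein_index`, lists keyed
#'   by aspect mapping terms to annotated proteins and proteins to terms.
#' @export
annotation_table <- function(records = NULL) {
  if (is.null(records))
    records <- data.frame(protein = character(), term = character(),
                          aspect = character(), evidence = character())
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "term", "aspect", "evidence") %in% names(records)))
  records <- records[c("protein", "term", "aspect", "evidence")]
  for (col in names(records)) records[[col]] <- as.character(records[[col]])
  map <- c(F = "MF", C = "CC", P = "BP", MF = "MF", CC = "CC", BP = "BP")
  if (nrow(records)) {
    bad <- !(records$aspect %in% names(map))
    if (any(bad))
      parse_error(sprintf("unknown GO aspect '%s'", records$aspect[which(bad)[1L]]))
    if (any(!nzchar(records$term)))
      parse_error("empty GO term identifier in annotation records")
    records$aspect <- unname(map[records$aspect])
    records <- unique(records)
    records <- records[order(records$aspect, records$protein, records$term,
                             records$evidence), , drop = FALSE]
    rownames(records) <- NULL
  }
  obj <- structure(list(records = records), class = "annotation_table")
  obj$term_index <- index_by(records, "term", "protein")
  obj$protein_index <- index_by(records, "protein", "term")
  obj
}

index_by <- function(records, key, value) {
  out <- list(MF = list(), CC = list(), BP = list())
  for (asp in names(out)) {
    sub <- records[records$aspect == asp, , drop = FALSE]
    if (nrow(sub))
      out[[asp]] <- lapply(split(sub[[value]], sub[[key]]),
                           function(x) sort(unique(x)))
  }
  out
}

#' Terms annotating a protein / proteins annotated by a term
#'
#' Accessors over the per-aspect indexes of an [annotation_table()].
#'
#' @param tab an [annotation_table()].
#' @param aspect one of `"MF"`, `"CC"`, `"BP"`.
#' @param protein,term identifier to look up.
#' @return Sorted character vector (empty when absent).
#' @export
annotated_terms <- function(tab, aspect, protein) {
  stopifnot(inherits(tab, "annotation_table"))
  tab$protein_index[[match.arg(aspect, c("MF", "CC", "BP"))]][[protein]] %||%
    character()
}

#' @rdname annotated_terms
#' @export
annotated_proteins <- function(tab, aspect, term) {
  stopifnot(inherits(tab, "annotation_table"))
  tab$term_index[[match.arg(aspect, c("MF", "CC", "BP"))]][[term]] %||%
    character()
}

#' Read GO annotations from GAF 2.x or a simple TSV
#'
#' For GAF input, `!`-prefixed header lines are skipped and columns 2 (object
#' id), 4 (qualifier), 5 (GO id), 7 (evidence) and 9 (aspect letter) are
#' used; records carrying a `NOT` qualifier are dropped, other qualifiers are
#' ignored.  TSV input has four columns: protein, GO term, aspect, evidence.
#'
#' @param path path to the annotation file.
#' @param format `"gaf"` or `"tsv"`.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    parse_error(sprintf("cannot read annotation file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
    if (!length(lines)) return(annotation_table())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9L)
    if (length(bad))
      parse_error(sprintf("GAF file '%s': a record has fewer than 9 columns", path))
    qualifier <- vapply(fields, `[`, "", 4L)
    not <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                  function(q) any(q == "NOT"), FALSE)
    fields <- fields[!not]
    rec <- data.frame(protein = vapply(fields, `[`, "", 2L),
                      term = vapply(fields, `[`, "", 5L),
                      aspect = vapply(fields, `[`, "", 9L),
                      evidence = vapply(fields, `[`, "", 7L))
  } else {
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    idx <- which(keep)
    fields <- split_fields(lines[keep])
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
      parse_error(sprintf("annotation file '%s': line %d has fewer than 4 columns",
                          path, idx[bad[1L]]))
    if (!length(fields)) return(annotation_table())
    rec <- data.frame(protein = vapply(fields, `[`, "", 1L),
                      term = vapply(fields, `[`, "", 2L),
                      aspect = vapply(fields, `[`, "", 3L),
                      evidence = vapply(fields, `[`, "", 4L))
  }
  annotation_table(rec)
}

#' Write annotations as a four-column TSV
#' @param tab an [annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tab, path) {
  stopifnot(inherits(tab, "annotation_table"))
  utils::write.table(tab$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
#' @method print annotation_table
print.annotation_table <- function(x, ...) {
  n <- vapply(c("MF", "CC", "BP"),
              function(a) sum(x$records$aspect == a), 0L)
  cat(sprintf(
    "GO annotation table: %d records (%d MF, %d CC, %d BP), %d proteins\n",
    nrow(x$records), n[["MF"]], n[["CC"]], n[["BP"]],
    length(unique(x$records$protein))))
  invisible(x)
}

#' GO term filter configuration
#'
#' Reliability and informativeness filter applied before validation: records
#' with excluded evidence codes are dropped, and only terms annotating
#' between `min_size` and `max_size` proteins are kept (terms below are too
#' specific, terms above too general to score).  Defaults follow the common
#' yeast benchmark setup: size window 10--200 and exclusion of IEA (inferred
#' from electronic annotation), ND (no biological data) and NAS
#' (non-traceable author statement) evidence.
#'
#' @param min_size,max_size inclusive bounds on the number of annotated
#'   proteins per surviving term.
#' @param excluded_evidence character vector of evidence codes to drop.
#' @param size_scope `"network"` to count only proteins of the supplied
#'   network when sizing terms (the default), `"corpus"` to count every
#'   annotated protein in the table.
#' @return An object of class `term_filter`.
#' @export
term_filter <- function(min_size = 10L, max_size = 200L,
                        excluded_evidence = c("IEA", "ND", "NAS"),
                        size_scope = c("network", "corpus")) {
  stopifnot(is_count(min_size), is_count(max_size), min_size >= 1,
            min_size <= max_size)
  structure(list(min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 excluded_evidence = as.character(excluded_evidence),
                 size_scope = match.arg(size_scope)),
            class = "term_filter")
}

#' Filter GO annotations for validation
#'
#' Applies, in order: (1) evidence-code exclusion; (2) optional ancestor
#' propagation over `is_a`/`part_of` within each aspect, so a protein
#' annotated with a term is annotated with all its ancestors (evidence
#' filtering comes first so an excluded record cannot seed ancestors);
#' (3) the term-size window of `cfg`, with sizes counted either over the
#' network's proteins or over the whole table.
#'
#' @param tab an [annotation_table()].
#' @param cfg a [term_filter()].
#' @param net a [ppi_network()]; required when `cfg$size_scope` is
#'   `"network"`.
#' @param ontology optional [read_obo()] result enabling propagation.
#' @return A list with `table` (the filtered [annotation_table()]), `terms`
#'   (per-aspect character vectors of surviving terms) and `sizes`
#'   (per-aspect named integer vectors of term sizes).
#' @export
filter_annotations <- function(tab, cfg = term_filter(), net = NULL,
                               ontology = NULL) {
  stopifnot(inherits(tab, "annotation_table"), inherits(cfg, "term_filter"))
  rec <- tab$records
  rec <- rec[!(rec$evidence %in% cfg$excluded_evidence), , drop = FALSE]
  if (!is.null(ontology) && nrow(rec)) {
    anc <- lapply(unique(rec$term), function(t) go_ancestors(ontology, t))
    names(anc) <- unique(rec$term)
    extra <- lapply(seq_len(nrow(rec)), function(i) {
      a <- anc[[rec$term[i]]]
      if (!length(a)) return(NULL)
      data.frame(protein = rec$protein[i], term = a,
                 aspect = rec$aspect[i], evidence = rec$evidence[i])
    })
    rec <- rbind(rec, do.call(rbind, extra))
  }
  tab2 <- annotation_table(rec)
  scope_proteins <- if (cfg$size_scope == "network") {
    if (is.null(net))
      usage_error("size_scope = 'network' requires a ppi_network")
    net$proteins
  } else NULL
  terms <- list(); sizes <- list()
  for (asp in c("MF", "CC", "BP")) {
    idx <- tab2$term_index[[asp]]
    sz <- vapply(idx, function(p) {
      if (is.null(scope_proteins)) length(p)
      else sum(p %in% scope_proteins)
    }, 0L)
    ok <- sz >= cfg$min_size & sz <= cfg$max_size
    terms[[asp]] <- sort(names(idx)[ok])
    sizes[[asp]] <- sz[terms[[asp]]]
  }
  keep <- mapply(function(t, a) t %in% terms[[a]],
                 tab2$records$term, tab2$records$aspect)
  out <- annotation_table(tab2$records[as.logical(keep), , drop = FALSE])
  list(table = out, terms = terms, sizes = sizes)
}
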