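# Shared fixtures and independent oracles for the test suite.

write_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")   # session-lived; cleaned with tempdir
  writeLines(lines, path)
  path
}

# Bundles are deterministic in their config, so cache them across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached_bundle <- function(key, cfg) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_bundle(cfg)
  .fixture_cache[[key]]
}

coupled_bundle <- function() cached_bundle("coupled", synthetic_config(seed = 7))

macro_f <- function(cv) cv$summary$f_measure[cv$summary$size_bin == "In total"]

# Independent oracle: distribution of the overlap between a fixed a-subset
# and every b-subset of a universe of size M, by exhaustive enumeration.
# By exchangeability of universe elements this equals the distribution over
# all subset pairs (the full-pair enumeration is also exercised directly on
# one case in the similarity tests).
enum_overlap_dist <- function(M, a, b) {
  smax <- min(a, b)
  if (M == 0 || b == 0)
    return(stats::setNames(rep(c(1, 0), c(1, smax)), 0:smax))
  subs <- utils::combn(M, b)
  olap <- colSums(subs <= a)
  as.numeric(table(factor(olap, levels = 0:smax))) / ncol(subs)
}

# A 4-module bundle with perfect module/domain/complex/label coupling: every
# in-module transfer is unambiguous ground truth.
perfect_bundle <- function() {
  cached_bundle("perfect", synthetic_config(
    n_proteins = 40, n_modules = 4, n_domain_types = 48,
    module_domain_pool = 12, domain_fidelity = 1, coupling = 1,
    complex_fidelity = 1, p_between = 0, seed = 7))
}

# Annotation view with one protein's labels hidden (the training view used
# when that protein is the test protein).
hide_protein <- function(annotations, p) {
  annotation_table(annotations$records[annotations$records$protein != p, ,
                                       drop = FALSE])
}
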