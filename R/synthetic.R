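#' Configuration for a synthetic benchmark bundle
#'
#' Describes a self-contained fixture: a protein network with planted
#' functional modules in which topology (stochastic block model), domain
#' composition (per-module domain pools), protein complexes (per-module
#' sampling) and GO labels (per-module term profiles) are mutually
#' correlated with tunable strength.  It emulates the modular organization
#' that the similarity transfer exploits — functionally related proteins
#' interacting, sharing domains and co-occurring in complexes — not the
#' degree distribution or annotation sparsity of any real interactome.
#'
#' @param n_proteins number of proteins.
#' @param n_domain_types size of the domain universe.
#' @param n_modules number of planted modules (proteins assigned round-robin,
#'   so module sizes are balanced).
#' @param domains_per_protein length-2 integer range; each protein draws a
#'   count uniformly from it.
#' @param module_domain_pool domains in each module's preferred pool; pools
#'   are disjoint consecutive slices when they fit in the universe and wrap
#'   around (overlapping) otherwise.
#' @param domain_fidelity probability a domain draw comes from the module
#'   pool rather than the whole universe.
#' @param p_within,p_between edge probabilities inside and between modules.
#' @param n_terms_per_aspect GO terms generated per aspect, split round-robin
#'   into disjoint per-module term profiles so correct transfer has an
#'   unambiguous ground truth.
#' @param terms_per_protein term draws per annotated protein and aspect.
#' @param coupling probability a term draw follows the protein's own module
#'   profile rather than the uniform term distribution; 0 decouples labels
#'   from modules entirely.
#' @param complexes_per_module,complex_size complexes generated per module
#'   and the (length-2) range of complex sizes.
#' @param complex_fidelity probability a complex member is drawn from the
#'   complex's home module rather than from all proteins.
#' @param unannotated_fraction fraction of proteins left without any
#'   annotation (exercises the unpredicted/fallback paths).
#' @param seed integer seed; the bundle is a deterministic function of the
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, n_domain_types = 60L,
                             n_modules = 5L, domains_per_protein = c(2L, 4L),
                             module_domain_pool = 12L, domain_fidelity = 0.9,
                             p_within = 0.25, p_between = 0.02,
                             n_terms_per_aspect = 15L, terms_per_protein = 3L,
                             coupling = 0.9, complexes_per_module = 2L,
                             complex_size = c(4L, 8L), complex_fidelity = 1,
                             unannotated_fraction = 0.1, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_domain_types = as.integer(n_domain_types),
              n_modules = as.integer(n_modules),
              domains_per_protein = as.integer(domains_per_protein),
              module_domain_pool = as.integer(module_domain_pool),
              domain_fidelity = domain_fidelity,
              p_within = p_within, p_between = p_between,
              n_terms_per_aspect = as.integer(n_terms_per_aspect),
              terms_per_protein = as.integer(terms_per_protein),
              coupling = coupling,
              complexes_per_module = as.integer(complexes_per_module),
              complex_size = as.integer(complex_size),
              complex_fidelity = complex_fidelity,
              unannotated_fraction = unannotated_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1 || n_modules < 1 || n_modules > n_proteins)
      usage_error("need 1 <= n_modules <= n_proteins")
    if (length(domains_per_protein) != 2L ||
        any(domains_per_protein < 0) || diff(domains_per_protein) < 0)
      usage_error("domains_per_protein must be a non-decreasing range")
    if (module_domain_pool < domains_per_protein[2L])
      usage_error("module domain pool smaller than domains_per_protein")
    if (module_domain_pool > n_domain_types)
      usage_error("module domain pool larger than the domain universe")
    if (length(complex_size) != 2L || any(complex_size < 1) ||
        diff(complex_size) < 0)
      usage_error("complex_size must be a positive non-decreasing range")
    for (p in c(domain_fidelity, p_within, p_between, coupling,
                complex_fidelity, unannotated_fraction))
      if (!is_prob(p)) usage_error("probabilities must lie in [0, 1]")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic benchmark bundle
#'
#' Deterministic given `cfg$seed`.  Proteins are `P0001`... and are assigned
#' to modules round-robin; edges follow a stochastic block model; each
#' protein draws its domain set from its module's pool (with
#' `1 - domain_fidelity` leakage to the whole universe); each annotated
#' protein draws terms from its module's term profile with probability
#' `coupling`, uniformly from all terms otherwise, independently for each of
#' MF, CC and BP; complexes sample members from their home module at
#' `complex_fidelity`.
#'
#' @param cfg a [synthetic_config()].
#' @return An object of class `bundle`: list with `network`
#'   ([ppi_network()]), `domains` ([domain_table()]), `annotations`
#'   ([annotation_table()]), `complexes` ([complex_catalog()]), `modules`
#'   (named integer vector: protein to module) and `config`.
#' @export
generate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    prots <- sprintf("P%04d", seq_len(n))
    modules <- rep_len(seq_len(cfg$n_modules), n)
    names(modules) <- prots
    universe <- sprintf("PFD%04d", seq_len(cfg$n_domain_types))

    # stochastic block model over unordered pairs
    pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
    same <- modules[pair[, 1L]] == modules[pair[, 2L]]
    p <- ifelse(same, cfg$p_within, cfg$p_between)
    keep <- stats::runif(nrow(pair)) < p
    net <- ppi_network(cbind(prots[pair[keep, 1L]], prots[pair[keep, 2L]]),
                       proteins = prots)

    # module domain pools: consecutive slices, wrapping when they overflow
    pool_of <- function(m) {
      start <- (m - 1L) * cfg$module_domain_pool
      universe[(start + seq_len(cfg$module_domain_pool) - 1L) %%
                 cfg$n_domain_types + 1L]
    }
    pools <- lapply(seq_len(cfg$n_modules), pool_of)
    assignments <- lapply(seq_len(n), function(i) {
      nd <- resample(cfg$domains_per_protein[1L]:cfg$domains_per_protein[2L], 1L)
      if (nd == 0L) return(character())
      from_pool <- stats::runif(nd) < cfg$domain_fidelity
      c(resample(pools[[modules[i]]], sum(from_pool)),
        resample(universe, sum(!from_pool)))
    })
    names(assignments) <- prots
    dt <- domain_table(assignments)

    # per-module disjoint term profiles; identical mechanism per aspect
    annotated <- stats::runif(n) >= cfg$unannotated_fraction
    term_id <- 0L
    recs <- list()
    for (asp in c("MF", "CC", "BP")) {
      terms <- sprintf("GO:%07d", term_id + seq_len(cfg$n_terms_per_aspect))
      term_id <- term_id + cfg$n_terms_per_aspect
      profile <- split(terms, rep_len(seq_len(cfg$n_modules), length(terms)))
      for (i in which(annotated)) {
        drawn <- vapply(seq_len(cfg$terms_per_protein), function(j) {
          if (stats::runif(1) < cfg$coupling)
            resample(profile[[modules[i]]], 1L)
          else resample(terms, 1L)
        }, "")
        recs[[length(recs) + 1L]] <-
          data.frame(protein = prots[i], term = unique(drawn),
                     aspect = asp, evidence = "IDA")
      }
    }
    annot <- annotation_table(do.call(rbind, recs))

    # complexes: per-module member sampling with fidelity
    cplx <- list()
    for (m in seq_len(cfg$n_modules)) {
      home <- prots[modules == m]
      for (j in seq_len(cfg$complexes_per_module)) {
        sz <- resample(cfg$complex_size[1L]:cfg$complex_size[2L], 1L)
        from_home <- stats::runif(sz) < cfg$complex_fidelity
        members <- unique(c(resample(home, min(sum(from_home), length(home))),
                            resample(prots, sum(!from_home))))
        cplx[[length(cplx) + 1L]] <- members
      }
    }
    names(cplx) <- sprintf("cplx%04d", seq_along(cplx))
    cat_ <- complex_catalog(cplx)

    structure(list(network = net, domains = dt, annotations = annot,
                   complexes = cat_, modules = modules, config = cfg),
              class = "bundle")
  })
}

#' @export
#' @method print bundle
print.bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic bundle (seed %d): %d proteins, %d modules, %d interactions, %d complexes, %d GO records\n",
    x$config$seed, length(x$network$proteins), x$config$n_modules,
    nrow(x$network$edges), length(x$complexes$complexes),
    nrow(x$annotations$records)))
  invisible(x)
}

#' Write or read a bundle as flat files
#'
#' `write_bundle` emits exactly the external formats the readers consume:
#' `ppi.tsv` (edge list), `domains.tsv`, `annotations.tsv`,
#' `complexes.txt` (named flat file) and `truth.json` (module map plus a
#' configuration echo; also the record of isolated proteins, which an edge
#' list cannot carry).  `read_bundle` reloads the directory into an
#' identical in-memory bundle.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir directory to create/fill.
#' @return `write_bundle`: named character vector of file paths, invisibly.
#'   `read_bundle`: a `bundle` object.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bundle"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", dir))
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             domains = file.path(dir, "domains.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             complexes = file.path(dir, "complexes.txt"),
             truth = file.path(dir, "truth.json"))
  write_ppi_edgelist(bundle$network, paths[["ppi"]])
  write_domain_table(bundle$domains, paths[["domains"]])
  write_annotations(bundle$annotations, paths[["annotations"]])
  write_complexes(bundle$complexes, paths[["complexes"]], named = TRUE)
  truth <- list(modules = as.list(bundle$modules),
                config = unclass(bundle$config))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  modules <- vapply(truth$modules, function(v) as.integer(v), integer(1))
  cfg <- do.call(synthetic_config, lapply(truth$config, unlist))
  net <- read_ppi_edgelist(file.path(dir, "ppi.tsv"))
  net <- ppi_network(net$edges, proteins = names(modules))
  structure(list(network = net,
                 domains = read_domain_table(file.path(dir, "domains.tsv")),
                 annotations = read_annotations(file.path(dir, "annotations.tsv")),
                 complexes = read_complexes(file.path(dir, "complexes.txt"),
                                            named = TRUE),
                 modules = modules[order(names(modules))],
                 config = cfg),
            class = "bundle")
}
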