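#' Negative log hypergeometric overlap score
#'
#' The probability that two domain-type sets of sizes `a` and `b`, drawn
#' uniformly from a universe of `M` types, share exactly `s` types is the
#' hypergeometric PMF
#' \deqn{P(s) = \frac{{M \choose s}{M-s \choose a-s}{M-a \choose b-s}}
#'              {{M \choose a}{M \choose b}},}
#' and the score is `-log P(s)`: a larger score means a less probable — more
#' surprising — overlap.  All binomial coefficients are evaluated in
#' log-gamma space via `lchoose`, so the score is finite and exact to
#' floating precision for any valid counts; it is 0 exactly when the
#' probability is 1 (e.g. one set empty, or both sets the full universe).
#'
#' Note that the score is not globally monotone in `s`: it decreases towards
#' the hypergeometric mode and increases beyond it.  Overlaps used as
#' similarity evidence live in the upper tail, where more shared types do
#' mean a higher score.
#'
#' @param M universe size (number of domain types in the whole network).
#' @param a,b sizes of the two sets.
#' @param s size of their intersection.
#' @param log_base `"natural"` (default) or `"ten"`; a change of base only
#'   rescales all scores by a shared constant.
#' @return Numeric vector of non-negative scores (arguments recycle).
#' @examples
#' hyper_score(10, 3, 4, 2)       # -ln 0.3
#' hyper_score(10, 3, 3, 3)       # ln choose(10, 3)
#' @export
hyper_score <- function(M, a, b, s, log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  n <- max(length(M), length(a), length(b), length(s))
  M <- rep_len(as.numeric(M), n); a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n); s <- rep_len(as.numeric(s), n)
  check_overlap_counts(M, a, b, s)
  score <- -(lchoose(M, s) + lchoose(M - s, a - s) + lchoose(M - a, b - s) -
               lchoose(M, a) - lchoose(M, b))
  if (log_base == "ten") score <- score / log(10)
  pmax(score, 0)  # guard the P(s)=1 cases against -0/rounding
}

check_overlap_counts <- function(M, a, b, s) {
  ints <- c(M, a, b, s)
  if (any(!is.finite(ints)) || any(ints < 0) || any(ints != trunc(ints)))
    stop("overlap counts must be non-negative integers")
  if (any(s > pmin(a, b)))
    stop("invalid overlap counts: s must satisfy s <= min(a, b)")
  if (any(a > M) || any(b > M))
    stop("invalid overlap counts: set sizes must satisfy a <= M and b <= M")
  if (any(a + b - s > M))
    stop("invalid overlap counts: union size must satisfy a + b - s <= M")
  invisible(TRUE)
}

#' Domain context and composition similarity of two set pairs
#'
#' `f_cont` scores the overlap of two domain *context* sets (domains found
#' over each protein's context scope — closed neighborhood or complexes);
#' `f_comp` scores the overlap of the proteins' *own* domain sets.  Both are
#' the [hyper_score()] of `(M, |A|, |B|, |intersect(A, B)|)` and are symmetric
#' in their two set arguments.
#'
#' @param setA,setB character vectors (domain accession sets).
#' @param M universe size; every set must fit in the universe.
#' @param log_base passed to [hyper_score()].
#' @return Non-negative scalar score.
#' @export
f_cont <- function(setA, setB, M, log_base = c("natural", "ten")) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  hyper_score(M, length(setA), length(setB), length(intersect(setA, setB)),
              log_base)
}

#' @rdname f_cont
#' @export
f_comp <- function(setA, setB, M, log_base = c("natural", "ten")) {
  f_cont(setA, setB, M, log_base)
}

#' Combined domain combination similarity
#'
#' Convex combination of the context and composition scores,
#' `lambda * cont + (1 - lambda) * comp`.  `lambda = 1` recovers the
#' context-only similarity (the Zhang-DC configuration), `lambda = 0` the
#' composition-only similarity.
#'
#' @param cont,comp non-negative context and composition scores.
#' @param lambda mixing weight in `[0, 1]` (default 0.1).
#' @return Non-negative combined score (vectorized).
#' @export
f_sim <- function(cont, comp, lambda = 0.1) {
  if (!is_prob(lambda))
    stop("lambda must be a single value in [0, 1]")
  if (any(cont < 0) || any(comp < 0))
    stop("component scores must be non-negative")
  lambda * cont + (1 - lambda) * comp
}
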