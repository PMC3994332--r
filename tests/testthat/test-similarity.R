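test_that("hand-derived overlap scores are reproduced exactly", {
  expect_equal(hyper_score(10, 3, 4, 2), -log(0.3), tolerance = 1e-12)
  expect_equal(hyper_score(10, 3, 3, 3), log(120), tolerance = 1e-12)
  expect_equal(hyper_score(50, 0, 7, 0), 0)           # one set empty -> PMF 1
  expect_equal(hyper_score(10, 10, 10, 10), 0)        # both sets = universe
  expect_equal(hyper_score(10, 3, 4, 2, log_base = "ten"),
               -log10(0.3), tolerance = 1e-12)
})

test_that("the full subset-pair enumeration confirms the (10,3,4,2) probability", {
  A <- utils::combn(10, 3); B <- utils::combn(10, 4)
  overlap <- matrix(0L, ncol(A), ncol(B))
  for (i in seq_len(ncol(A)))
    overlap[i, ] <- colSums(matrix(B %in% A[, i], nrow = 4))
  expect_equal(ncol(A) * ncol(B), 25200)
  expect_equal(sum(overlap == 2) / length(overlap), 0.3, tolerance = 1e-12)
  expect_equal(exp(-hyper_score(10, 3, 4, 2)), 0.3, tolerance = 1e-9)
})

test_that("scores agree with enumeration and normalize over the overlap range", {
  for (M in c(2, 5, 8)) for (a in 0:M) for (b in 0:M) {
    pmf <- exp(-vapply(max(0, a + b - M):min(a, b), function(s)
      hyper_score(M, a, b, s), 0))
    enum <- enum_overlap_dist(M, a, b)
    enum <- enum[enum > 0]                     # infeasible overlaps
    expect_equal(unname(pmf), unname(enum), tolerance = 1e-9)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
  }
})

test_that("the score matches the hypergeometric density on random valid counts", {
  set.seed(1)
  for (i in 1:200) {
    M <- sample(1:500, 1)
    a <- sample.int(M + 1L, 1L) - 1L
    b <- sample.int(M + 1L, 1L) - 1L
    ss <- max(0, a + b - M):min(a, b)
    s <- ss[sample.int(length(ss), 1L)]
    expect_equal(hyper_score(M, a, b, s),
                 -stats::dhyper(s, a, M - a, b, log = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("invalid overlap counts are rejected by name of the constraint", {
  expect_error(hyper_score(10, 3, 4, 5), "s <= min")
  expect_error(hyper_score(10, 12, 4, 2), "a <= M")
  expect_error(hyper_score(10, 6, 6, 1), "a \\+ b - s <= M")
  expect_error(hyper_score(10, -1, 4, 0), "non-negative")
})

test_that("context and composition scores are symmetric set functions", {
  expect_equal(f_cont(c("d1", "d2", "d3"), c("d1", "d2", "d3"), 10),
               log(120), tolerance = 1e-12)
  expect_equal(f_cont(c("d1", "d2"), c("d3", "d4", "d5"), 100),
               f_cont(c("d3", "d4", "d5"), c("d1", "d2"), 100))
  expect_equal(f_comp("d1", "d9", 10), f_comp("d9", "d1", 10))
  expect_equal(f_comp(character(), c("d1", "d2"), 10), 0)
  # single shared domain out of a universe of 10: -log(1/10)
  expect_equal(f_comp("d1", "d1", 10), log(10), tolerance = 1e-12)
})

test_that("disjoint sets approach score zero as the universe grows", {
  scores <- vapply(c(10, 100, 1000, 10000),
                   function(M) f_cont("d1", "d2", M), 0)
  expect_true(all(diff(scores) < 0))
  expect_lt(scores[4], 1e-3)
})

test_that("above the mode the score is non-decreasing in the overlap", {
  for (M in c(6, 9, 12)) for (a in 1:M) for (b in 1:a) {
    ss <- max(0, a + b - M):min(a, b)
    pmf <- enum_overlap_dist(M, a, b)
    pmf <- pmf[pmf > 0]
    mode_s <- ss[which.max(pmf)]
    upper <- ss[ss >= mode_s]
    sc <- vapply(upper, function(s) hyper_score(M, a, b, s), 0)
    expect_true(all(diff(sc) >= -1e-9))
  }
})

test_that("the combined similarity is the stated convex combination", {
  expect_equal(f_sim(1.203973, 4.787492, lambda = 0.1), 4.4291401,
               tolerance = 1e-6)
  expect_equal(f_sim(3.7, 1.1, lambda = 0), 1.1)
  expect_equal(f_sim(3.7, 1.1, lambda = 1), 3.7)
  expect_error(f_sim(1, 1, lambda = 1.2), "lambda")
  expect_error(f_sim(-1, 1, lambda = 0.5), "non-negative")
})

test_that("context sets follow the method and fall back without complexes", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C")), proteins = "X")
  dt <- domain_table(list(A = "d1", B = c("d2", "d3"), C = "d4"))
  fit <- dcs(net, dt)
  expect_equal(context_set(fit, "X"), character())   # isolated, domain-free
  expect_equal(context_set(fit, "A"), c("d1", "d2", "d3"))
  expect_equal(composition_set(fit, "A"), "d1")

  fit_dscp <- dcs(net, dt, complexes = complex_catalog(), method = "DSCP")
  for (p in net$proteins)
    expect_equal(context_set(fit_dscp, p), context_set(fit, p))

  # two proteins whose neighborhoods carry the same five domain types
  net2 <- ppi_network(rbind(c("PA", "n1"), c("PA", "n2"),
                            c("PB", "n3"), c("PB", "n4")))
  dt2 <- domain_table(list(
    PA = "d1", n1 = c("d2", "d3"), n2 = c("d4", "d5"),
    PB = "d1", n3 = c("d2", "d4"), n4 = c("d3", "d5")))
  fit2 <- dcs(net2, dt2)
  ca <- context_set(fit2, "PA"); cb <- context_set(fit2, "PB")
  expect_length(ca, 5)
  expect_length(intersect(ca, cb), 5)
})

test_that("complex contexts use complex members and the global universe", {
  net <- ppi_network(rbind(c("A", "B"), c("C", "D")))
  dt <- domain_table(list(A = "d1", B = "d2", C = "d3", D = "d4"))
  cat_ <- complex_catalog(list(c("A", "C")))
  fit <- dcs(net, dt, complexes = cat_, method = "DSCP")
  expect_equal(context_set(fit, "A"), c("d1", "d3"))  # complex, not neighbors
  expect_equal(context_set(fit, "B"), c("d1", "d2"))  # neighbor fallback
  expect_equal(fit$M, 4)                              # M stays network-wide
})

test_that("pairwise similarity is symmetric, deterministic and order-free", {
  b <- coupled_bundle()
  fit <- dcs(b$network, b$domains)
  pairs <- rbind(c("P0001", "P0002"), c("P0010", "P0003"), c("P0005", "P0005"))
  s1 <- pairwise_similarity(fit, pairs)
  s2 <- pairwise_similarity(fit, pairs[c(2, 1, 3), 2:1])
  expect_equal(s1[order(s1$protein_a, s1$protein_b), ],
               s2[order(s2$protein_a, s2$protein_b), ],
               ignore_attr = TRUE)
  # self-comparison reduces to the identical-set score at the protein's sizes
  a_ctx <- length(context_set(fit, "P0005"))
  a_cmp <- length(composition_set(fit, "P0005"))
  self <- s1[s1$protein_a == "P0005" & s1$protein_b == "P0005", ]
  expect_equal(self$f_cont, hyper_score(fit$M, a_ctx, a_ctx, a_ctx))
  expect_equal(self$f_comp, hyper_score(fit$M, a_cmp, a_cmp, a_cmp))
})
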