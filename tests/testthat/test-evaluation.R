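test_that("metric formulas reproduce hand-computed confusion values", {
  expect_equal(metric_ppv(9, 11), 0.45)
  expect_equal(metric_tpr(19, 31), 0.38)
  expect_equal(metric_mcc(50, 50, 0, 0), 1)                  # perfect
  expect_equal(metric_mcc(8, 80, 2, 10),
               (8 * 80 - 10 * 2) /
                 sqrt(18 * 82 * 10 * 90), tolerance = 1e-12) # ~0.5379
  expect_equal(round(metric_mcc(8, 80, 2, 10), 4), 0.5379)
  # zero denominators are distinguished, not zero
  expect_true(is.na(metric_ppv(0, 0)))
  expect_true(is.na(metric_tpr(0, 0)))
  expect_true(is.na(metric_mcc(0, 5, 0, 0)))
  expect_true(is.na(metric_f(NA_real_, 0.5)))
  expect_equal(metric_f(0, 0), 0)
})

test_that("term-size bins use the benchmark edges", {
  expect_equal(as.character(bin_go_terms(c(10, 30, 31, 50, 51, 100, 101, 200))),
               c("[10-30]", "[10-30]", "(30-50]", "(30-50]",
                 "(50-100]", "(50-100]", "(100-200]", "(100-200]"))
  expect_error(bin_go_terms(9), "\\[10, 200\\]")
  expect_error(bin_go_terms(201), "\\[10, 200\\]")
})

test_that("per-term confusion follows the stated conventions", {
  truth <- list(u1 = c("t1", "t2"), u2 = "t1", u3 = character())
  perfect <- term_confusion(truth, truth, c("t1", "t2", "t3"),
                            c("u1", "u2", "u3"))
  expect_equal(perfect$fp, c(0, 0, 0))
  expect_equal(perfect$fn, c(0, 0, 0))
  # an unpredicted protein contributes a false negative per true term
  none <- term_confusion(list(), truth, c("t1", "t2", "t3"),
                         c("u1", "u2", "u3"))
  expect_equal(none$fn, c(2, 1, 0))
  expect_equal(none$tp, c(0, 0, 0))
  # a term annotating no test protein can only produce tn/fp
  expect_equal(perfect[perfect$term == "t3", c("tp", "fn")],
               data.frame(tp = 0, fn = 0, row.names = 3L))
})

test_that("a lone annotated protein can never be predicted in LOO", {
  net <- ppi_network(rbind(c("A", "B")))
  dt <- domain_table(list(A = "d1", B = "d1"))
  annot <- annotation_table(data.frame(protein = "A", term = "GO:0000001",
                                       aspect = "MF", evidence = "IDA"))
  fit <- dcs(net, dt)
  cv <- cross_validate(fit, annot, aspect = "MF", filter = NULL)
  tot <- cv$summary[cv$summary$size_bin == "In total", ]
  expect_equal(cv$per_term$fn, 1)     # its only term becomes a false negative
  expect_equal(cv$per_term$tp, 0)
  expect_true(is.na(tot$ppv))         # nothing was ever predicted
})

test_that("leave-percent-out is seed-reproducible and degrades with percent", {
  b <- coupled_bundle()
  fit <- dcs(b$network, b$domains)
  a <- cross_validate(fit, b$annotations, aspect = "MF", scheme = "lpo",
                      percent = 20, repeats = 10, seed = 11)
  b2 <- cross_validate(fit, b$annotations, aspect = "MF", scheme = "lpo",
                       percent = 0.2, repeats = 10, seed = 11)
  expect_equal(a$summary, b2$summary)  # 20 == 0.2 and same seed
  lo <- cross_validate(fit, b$annotations, aspect = "MF", scheme = "lpo",
                       percent = 0.1, repeats = 50, seed = 9)
  hi <- cross_validate(fit, b$annotations, aspect = "MF", scheme = "lpo",
                       percent = 0.8, repeats = 50, seed = 9)
  expect_lte(hi$summary$tpr[hi$summary$size_bin == "In total"],
             lo$summary$tpr[lo$summary$size_bin == "In total"])
})

test_that("the neighbor-counting baseline ranks by neighborhood frequency", {
  net <- ppi_network(rbind(c("u", "n1"), c("u", "n2"), c("u", "n3"),
                           c("u", "n4"), c("iso1", "iso2")))
  term_sets <- list(n1 = c("t1"), n2 = c("t1", "t2"), n3 = "t1", n4 = "t2")
  nc <- nc_ranker(net)
  ranked <- rank_terms(nc, "u", term_sets)
  expect_equal(ranked$term[1], "t1")            # 3 neighbors vs 2
  expect_equal(ranked$score, c(3, 2))
  # isolated protein: nothing to count
  expect_equal(nrow(rank_terms(nc, "iso1", term_sets)), 0)
  # ties resolve to the lexicographically first GO id
  tied <- rank_terms(nc, "u", list(n1 = "tB", n2 = "tA"))
  expect_equal(tied$term, c("tA", "tB"))
})

test_that("the chi-square baseline corrects for background frequency", {
  # u's two annotated neighbors both carry tCommon (like everyone) and tRare
  net <- ppi_network(rbind(c("u", "n1"), c("u", "n2"),
                           c("x1", "x2"), c("x3", "x4")))
  term_sets <- list(n1 = c("tCommon", "tRare"), n2 = c("tCommon", "tRare"),
                    x1 = "tCommon", x2 = "tCommon",
                    x3 = "tCommon", x4 = "tCommon")
  ranked <- rank_terms(chisq_ranker(net), "u", term_sets)
  # tCommon: n_f = 2, e_f = 2 * (6/6) = 2 -> score 0 -> excluded
  expect_false("tCommon" %in% ranked$term)
  # tRare: n_f = 2, e_f = 2 * (2/6) -> positive score
  expect_equal(ranked$term, "tRare")
  expect_equal(ranked$score, (2 - 2 * 2 / 6)^2 / (2 * 2 / 6), tolerance = 1e-12)
  # terms absent from the neighborhood are never scored
  expect_false(any(ranked$score <= 0))
})

test_that("recall is non-decreasing along the PR sweep", {
  b <- coupled_bundle()
  fit <- dcs(b$network, b$domains)
  pr <- pr_curve(fit, b$annotations, aspect = "MF", k_max = 8)
  expect_true(all(diff(pr$tpr) >= -1e-12))
  cv1 <- cross_validate(fit, b$annotations, aspect = "MF", k = 1)
  expect_s3_class(pr, "dcs_pr")
  expect_true(attr(pr, "max_f") >= pr$f_measure[1] - 1e-12)
  expect_gt(attr(pr, "max_f"), 0)
  expect_equal(nrow(pr), 8)
  # rankers ride the same protocol
  prnc <- pr_curve(nc_ranker(b$network), b$annotations, aspect = "MF",
                   k_max = 5)
  expect_true(all(diff(prnc$tpr) >= -1e-12))
})
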