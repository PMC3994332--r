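gaf_line <- function(protein, term, evidence, aspect, qualifier = "") {
  paste(c("DB", protein, "SYM", qualifier, term, "REF", evidence, "",
          aspect, rep("", 8)), collapse = "\t")
}

test_that("GAF loading keeps unique records, maps aspects and drops NOT", {
  path <- write_lines(c(
    "!gaf-version: 2.1",
    gaf_line("P1", "GO:0000001", "IDA", "F"),
    gaf_line("P1", "GO:0000001", "IDA", "F"),      # duplicate
    gaf_line("P2", "GO:0000002", "IMP", "P"),
    gaf_line("P3", "GO:0000003", "IDA", "C", qualifier = "NOT")))
  tab <- read_annotations(path, format = "gaf")
  expect_equal(nrow(tab$records), 2)
  expect_setequal(tab$records$aspect, c("MF", "BP"))
  expect_equal(annotated_terms(tab, "MF", "P1"), "GO:0000001")
})

test_that("header-only files and aspect/term validation behave", {
  only_header <- write_lines(c("!gaf-version: 2.1", "! nothing else"))
  expect_equal(nrow(read_annotations(only_header, "gaf")$records), 0)
  expect_error(annotation_table(data.frame(
    protein = "P1", term = "GO:1", aspect = "Q", evidence = "IDA")),
    "unknown GO aspect")
  expect_error(annotation_table(data.frame(
    protein = "P1", term = "", aspect = "MF", evidence = "IDA")),
    "empty GO term")
})

test_that("TSV records are retained at load time regardless of evidence", {
  path <- write_lines("P1\tGO:0000001\tMF\tIEA")
  tab <- read_annotations(path, format = "tsv")
  expect_equal(nrow(tab$records), 1)  # filtering is a separate step
  expect_equal(tab$records$evidence, "IEA")
})

make_tab <- function(n_prot, term, aspect = "MF", evidence = "IDA") {
  annotation_table(data.frame(protein = sprintf("P%02d", seq_len(n_prot)),
                              term = term, aspect = aspect,
                              evidence = evidence))
}

test_that("term-size filtering drops terms outside the window", {
  net <- ppi_network(proteins = sprintf("P%02d", 1:20))
  tab9 <- make_tab(9, "GO:0000009")
  fa <- filter_annotations(tab9, term_filter(min_size = 10), net)
  expect_length(fa$terms$MF, 0)       # 9 annotated proteins < 10
  tab10 <- make_tab(10, "GO:0000010")
  fa10 <- filter_annotations(tab10, term_filter(min_size = 10), net)
  expect_equal(fa10$terms$MF, "GO:0000010")
  expect_equal(unname(fa10$sizes$MF), 10L)
})

test_that("excluded evidence is dropped before size counting", {
  net <- ppi_network(proteins = sprintf("P%02d", 1:20))
  rec <- rbind(make_tab(10, "GO:0000010")$records,
               data.frame(protein = "P11", term = "GO:0000010",
                          aspect = "MF", evidence = "IEA"))
  fa <- filter_annotations(annotation_table(rec),
                           term_filter(min_size = 11), net)
  expect_length(fa$terms$MF, 0)       # the IEA record must not count
})

test_that("the identity configuration returns the input annotations", {
  tab <- make_tab(5, "GO:0000005")
  fa <- filter_annotations(tab, term_filter(min_size = 1, max_size = 10^6,
                                            excluded_evidence = character()),
                           ppi_network(proteins = sprintf("P%02d", 1:5)))
  expect_equal(fa$table$records, tab$records)
})

test_that("network-restricted sizes always land inside the window", {
  b <- coupled_bundle()
  cfg <- term_filter(min_size = 10, max_size = 200)
  fa <- filter_annotations(b$annotations, cfg, b$network)
  for (asp in c("MF", "CC", "BP")) {
    sz <- fa$sizes[[asp]]
    expect_true(all(sz >= cfg$min_size & sz <= cfg$max_size))
  }
})

obo_fixture <- function() {
  write_lines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003",
    "relationship: part_of GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000004", "is_a: GO:0000003", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"))
}

test_that("OBO parsing and ancestor closure follow is_a and part_of", {
  ont <- read_obo(obo_fixture())
  expect_equal(go_ancestors(ont, "GO:0000003"), c("GO:0000001", "GO:0000002"))
  expect_equal(go_ancestors(ont, "GO:0000001"), character())
  expect_false("GO:0000004" %in% names(ont$parents))  # obsolete dropped
  expect_equal(go_ancestors(ont, "GO:9999999"), character())
})

test_that("ancestor propagation is monotone and respects evidence exclusion", {
  ont <- read_obo(obo_fixture())
  rec <- data.frame(protein = c("P1", "P2"),
                    term = c("GO:0000003", "GO:0000002"),
                    aspect = "MF", evidence = c("IDA", "IEA"))
  tab <- annotation_table(rec)
  fa <- filter_annotations(tab, term_filter(min_size = 1, max_size = 10^6),
                           ppi_network(proteins = c("P1", "P2")), ont)
  # P1's record propagates up to the root
  expect_setequal(annotated_terms(fa$table, "MF", "P1"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  # P2's IEA record is excluded first and must not seed ancestors
  expect_length(annotated_terms(fa$table, "MF", "P2"), 0)
  # monotone: post-propagation term sets contain the retained originals
  expect_true(all(c("GO:0000003") %in% annotated_terms(fa$table, "MF", "P1")))
})
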