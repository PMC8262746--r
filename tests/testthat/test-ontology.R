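test_that("parse_obo transcribes stanzas, obsolete terms, alt_ids", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: a",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "alt_id: GO:0000099", "",
    "[Term]", "id: GO:0000003", "name: b",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: c",
    "namespace: biological_process", "is_a: GO:0000002",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000005", "name: gone", "is_obsolete: true", "")
  g <- parse_obo(obo)
  expect_length(g$classes, 4L)
  expect_equal(unname(g$roots), "GO:0000001")
  expect_equal(g$edges$parent[g$edges$child == "GO:0000003"], "GO:0000002")
  expect_true("GO:0000005" %in% g$obsolete)
  expect_false("GO:0000005" %in% g$classes)
  expect_equal(unname(g$alt_ids[["GO:0000099"]]), "GO:0000002")
  expect_equal(g$edges$relation[g$edges$child == "GO:0000004"],
               c("is_a", "part_of"))
})

test_that("parse_obo rejects cycles (naming them) and dangling parents", {
  cyc <- c("[Term]", "id: A", "namespace: x", "is_a: B", "",
           "[Term]", "id: B", "namespace: x", "is_a: A", "")
  expect_error(parse_obo(cyc), "cycle.*A.*B")
  dangling <- c("[Term]", "id: A", "namespace: x", "is_a: MISSING", "")
  expect_error(parse_obo(dangling), "MISSING")
})

test_that("closure walks chains, stops at roots, matches diamond oracle", {
  g <- chain_ontology()
  expect_equal(closure(g, "C", "up"), c("A", "R"))
  expect_equal(closure(g, "R", "up"), character(0))
  expect_equal(closure(g, "R", "down"), c("A", "C"))
  d <- diamond_ontology()
  expect_equal(closure(d, "D", "up"),
               oracle_reachable(d$edges, "D", "up"))
  expect_setequal(closure(d, "D", "up"), c("A", "B", "C"))
  expect_error(closure(g, "NOPE"), "NOPE")
})

test_that("closure equals brute-force path enumeration on random DAGs", {
  for (seed in 1:25) {
    g <- random_dag(sample(3:8, 1L), seed = seed)
    for (cls in g$classes) {
      expect_equal(closure(g, cls, "up"),
                   oracle_reachable(g$edges, cls, "up"))
      expect_equal(closure(g, cls, "down"),
                   oracle_reachable(g$edges, cls, "down"))
    }
  }
})

test_that("filter_experimental keeps exactly the accepted codes in order", {
  rec <- data.frame(protein = c("p1", "p1", "p2"),
                    class = c("A", "B", "C"),
                    evidence = c("IDA", "IEA", "TAS"))
  kept <- filter_experimental(rec)
  expect_equal(kept$class, c("A", "C"))
  expect_equal(nrow(filter_experimental(rec[0, ])), 0L)
  all_iea <- data.frame(protein = "p", class = "A", evidence = "IEA")
  expect_equal(nrow(filter_experimental(all_iea)), 0L)
  expect_length(go_experimental_codes, 13L)
})

test_that("read_annotations handles GAF 2.x and 3-column TSV dialects", {
  gaf <- c("!gaf-version: 2.1",
           paste(c("DB", "P001", "sym", "", "GO:0000002", "ref", "IDA",
                   "", "P", "", "", "", "", "", "", "", ""),
                 collapse = "\t"))
  rec <- read_annotations(gaf)
  expect_equal(rec$protein, "P001")
  expect_equal(rec$class, "GO:0000002")
  expect_equal(rec$evidence, "IDA")
  tsv <- c("P001\tGO:0000002\tIDA", "P002\tGO:0000003\tIEA")
  rec2 <- read_annotations(tsv)
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$evidence, c("IDA", "IEA"))
})

test_that("propagation closes chains upward and is idempotent", {
  g <- chain_ontology()
  corpus <- propagate_annotations(g, list(p1 = "C"))
  expect_equal(corpus$annotations$p1, c("A", "C", "R"))
  again <- propagate_annotations(g, corpus$annotations)
  expect_equal(again$annotations, corpus$annotations)
  d <- diamond_ontology()
  expect_setequal(propagate_annotations(d, list(p = "D"))$annotations$p,
                  c("D", oracle_reachable(d$edges, "D", "up")))
  expect_error(propagate_annotations(g, list(p1 = "NOPE")), "p1.*NOPE")
})

test_that("propagation is idempotent and monotone on random DAGs", {
  for (seed in 1:15) {
    g <- random_dag(sample(5:30, 1L), seed = 100 + seed)
    raw <- random_raw_annotations(g, 6L, seed = 200 + seed)
    corpus <- propagate_annotations(g, raw)
    twice <- propagate_annotations(g, corpus$annotations)
    expect_equal(twice$annotations, corpus$annotations)
    # propagated protein count of a parent >= that of each child
    counts <- table(unlist(corpus$annotations))
    for (r in seq_len(nrow(g$edges))) {
      child <- g$edges$child[[r]]; parent <- g$edges$parent[[r]]
      n_child <- if (child %in% names(counts)) counts[[child]] else 0L
      n_parent <- if (parent %in% names(counts)) counts[[parent]] else 0L
      expect_gte(n_parent, n_child)
    }
  }
})

test_that("alt_ids resolve silently and obsolete annotations drop with warning", {
  obo <- c("[Term]", "id: GO:0000001", "namespace: x", "",
           "[Term]", "id: GO:0000002", "namespace: x",
           "is_a: GO:0000001", "alt_id: GO:0000042", "",
           "[Term]", "id: GO:0000009", "is_obsolete: true", "")
  g <- parse_obo(obo)
  corpus <- propagate_annotations(g, list(p1 = "GO:0000042"))
  expect_setequal(corpus$annotations$p1, c("GO:0000001", "GO:0000002"))
  expect_warning(
    propagate_annotations(g, list(p1 = c("GO:0000002", "GO:0000009"))),
    "obsolete")
})

test_that("select_terms applies the minimum-count boundary", {
  sets <- c(lapply(1:49, function(i) c("A", "B")), list(c("A")))
  names(sets) <- sprintf("p%02d", 1:50)
  corpus <- corpus_from_sets(sets)
  expect_equal(select_terms(corpus, min_count = 50L), "A")   # A:50, B:49
  expect_setequal(select_terms(corpus, min_count = 1L), c("A", "B"))
})

test_that("select_terms equals direct counting on a random corpus", {
  g <- random_dag(12L, seed = 5)
  raw <- random_raw_annotations(g, 10L, seed = 6)
  corpus <- propagate_annotations(g, raw)
  counts <- table(unlist(corpus$annotations))
  expect_equal(select_terms(corpus, min_count = 3L),
               sort(names(counts)[counts >= 3]))
  expect_equal(select_terms(corpus, min_count = 3L, exclude_roots = TRUE,
                            graph = g),
               setdiff(sort(names(counts)[counts >= 3]), unname(g$roots)))
})

test_that("information content implements -log2 of the conditional probability", {
  g <- chain_ontology()
  # parent A in 4 proteins, child C in 1 of them
  sets <- list(p1 = c("R", "A", "C"), p2 = c("R", "A"), p3 = c("R", "A"),
               p4 = c("R", "A"))
  corpus <- corpus_from_sets(sets)
  ic <- information_content(g, corpus, log_base = 2)
  expect_equal(ic$ic[["R"]], 0)                  # root covers the corpus
  expect_equal(ic$ic[["C"]], 2)                  # -log2(1/4)
  expect_equal(ic$ic[["A"]], 0)                  # all R-proteins carry A
  expect_true(all(ic$ic >= 0))
  nat <- information_content(g, corpus, log_base = exp(1))
  expect_equal(nat$ic[["C"]], -log(1 / 4))
  expect_error(information_content(g, corpus_from_sets(list())), "empty")
})

test_that("unannotated classes receive the maximum-IC fallback", {
  g <- diamond_ontology()
  corpus <- corpus_from_sets(list(p1 = c("A", "B"), p2 = c("A", "B"),
                                  p3 = c("A", "B"), p4 = c("A")))
  expect_message(ic <- information_content(g, corpus), "maximum")
  # C and D are unobserved; they get the max observed IC (that of B: 2 bits)
  expect_equal(ic$ic[["C"]], ic$ic[["B"]])
  expect_equal(ic$ic[["D"]], ic$ic[["B"]])
  expect_equal(ic$ic[["B"]], -log2(3 / 4))
})

test_that("IC is non-negative on random propagated corpora, with IC(root)=0", {
  for (seed in 1:8) {
    g <- random_dag(sample(5:15, 1L), seed = 300 + seed)
    corpus <- propagate_annotations(
      g, random_raw_annotations(g, 8L, seed = 400 + seed))
    ic <- suppressMessages(information_content(g, corpus))
    expect_true(all(ic$ic >= 0))
    root <- unname(g$roots)[[1L]]
    if (all(vapply(corpus$annotations, function(a) root %in% a, logical(1))))
      expect_equal(ic$ic[[root]], 0)
  }
})
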