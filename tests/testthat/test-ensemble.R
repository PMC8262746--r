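pm <- function(values, proteins, classes) {
  matrix(values, nrow = length(proteins), byrow = TRUE,
         dimnames = list(proteins, classes))
}

test_that("combine_scores is the alpha-weighted sum with exact boundaries", {
  cnn <- pm(c(0.8, 0.1), "p1", c("a", "b"))
  sim <- pm(c(0.4, 0.9), "p1", c("a", "b"))
  expect_equal(combine_scores(cnn, sim, alpha = 1), sim)    # similarity only
  expect_equal(combine_scores(cnn, sim, alpha = 0), cnn)    # CNN only
  expect_equal(combine_scores(cnn, sim, alpha = 0.5)["p1", "a"], 0.6)
  expect_error(combine_scores(cnn, sim, alpha = 1.5), "alpha")
  expect_error(combine_scores(cnn, sim, alpha = -0.1), "alpha")
})

test_that("combine_scores unions supports with missing components at 0", {
  cnn <- pm(0.8, "p1", "a")
  sim <- pm(0.6, "p2", "b")
  out <- combine_scores(cnn, sim, alpha = 0.25)
  expect_setequal(rownames(out), c("p1", "p2"))
  expect_setequal(colnames(out), c("a", "b"))
  expect_equal(out["p1", "a"], 0.75 * 0.8)
  expect_equal(out["p2", "b"], 0.25 * 0.6)
  expect_equal(out["p1", "b"], 0)
  # monotone in alpha toward the similarity score when similarity > cnn
  both_c <- pm(0.2, "p", "f"); both_s <- pm(0.9, "p", "f")
  vals <- vapply(c(0, 0.3, 0.7, 1), function(a)
    combine_scores(both_c, both_s, a)["p", "f"], numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("enforce_consistency pushes subclass confidence to ancestors", {
  g <- chain_ontology()
  sc <- pm(c(0.2, 0.5, 0.3), "p1", c("R", "A", "C"))
  out <- enforce_consistency(g, sc)
  expect_equal(out["p1", ], c(R = 0.5, A = 0.5, C = 0.3))
  expect_equal(enforce_consistency(g, out), out)            # idempotent
  expect_true(all(out >= sc))                               # never decreases
  expect_error(enforce_consistency(g, pm(0.5, "p1", "NOPE")), "NOPE")
})

test_that("consistency matches the descendant-set oracle on random DAGs", {
  for (seed in 1:12) {
    g <- random_dag(sample(5:20, 1L), seed = 1100 + seed)
    sc <- random_scores(g, 3L, seed = 1200 + seed)
    out <- enforce_consistency(g, sc)
    for (i in 1:3) {
      expect_equal(out[i, ], oracle_consistency(g$edges, sc[i, ]),
                   tolerance = 1e-12)
    }
    # monotone along every edge, root carries the block maximum
    for (r in seq_len(nrow(g$edges)))
      expect_true(all(out[, g$edges$parent[[r]]] >= out[, g$edges$child[[r]]]))
    root <- unname(g$roots)[[1L]]
    expect_equal(out[, root], apply(out, 1L, max))
  }
})

test_that("thresholding respects the boundary and both comparisons", {
  sc <- pm(c(0.31, 0.29), "p1", c("a", "b"))
  expect_equal(threshold_predictions(sc, 0.3), list(p1 = "a"))
  expect_equal(threshold_predictions(sc, 0)$p1, c("a", "b"))
  exact1 <- pm(c(1, 0.999), "p1", c("a", "b"))
  expect_equal(threshold_predictions(exact1, 1)$p1, "a")
  expect_equal(threshold_predictions(sc, 0.31, strict = TRUE)$p1,
               character(0))
  expect_equal(threshold_predictions(sc, 0.31, strict = FALSE)$p1, "a")
  # zero scores encode "unscored" and are never predicted
  zero <- pm(c(0, 0.4), "p1", c("a", "b"))
  expect_equal(threshold_predictions(zero, 0)$p1, "b")
})

test_that("prune_to_ontology drops version-skewed classes with a warning", {
  g <- chain_ontology()
  sc <- pm(c(0.5, 0.4), "p1", c("A", "GHOST"))
  expect_warning(out <- prune_to_ontology(sc, g), "GHOST")
  expect_equal(colnames(out), "A")
})

test_that("formatted output is namespace-grouped, sorted, tie-broken by id", {
  g <- go_ontology(
    classes = c("R1", "A1", "B1", "R2", "A2"),
    edges = data.frame(child = c("A1", "B1", "A2"),
                       parent = c("R1", "R1", "R2"), relation = "is_a"),
    namespace = c(R1 = "cellular_component", A1 = "cellular_component",
                  B1 = "cellular_component", R2 = "molecular_function",
                  A2 = "molecular_function"))
  sc <- pm(c(0.782, 0.5, 0.5, 0.2, 0.1), "p1",
           c("R1", "A1", "B1", "R2", "A2"))
  fmt <- format_predictions(sc, g, t = 0.3)
  cc <- fmt[[1]]$predictions$cellular_component
  expect_equal(cc$go_id, c("R1", "A1", "B1"))   # desc score, ties by id
  expect_true(all(diff(cc$score) <= 0))
  mf <- fmt[[1]]$predictions$molecular_function
  expect_equal(nrow(mf), 0L)                    # empty block still present
  # thresholded set is exactly the union of the blocks (no loss/duplication)
  listed <- unlist(lapply(fmt[[1]]$predictions, function(b) b$go_id))
  expect_setequal(listed, threshold_predictions(sc, 0.3)$p1)
})

test_that("provenance hits are attached sorted by bitscore", {
  g <- chain_ontology()
  sc <- pm(c(0.9, 0.8, 0.4), "q1", c("R", "A", "C"))
  hits <- data.frame(query = c("q1", "q1", "other"),
                     subject = c("s_lo", "s_hi", "sx"),
                     bitscore = c(40, 150, 99), evalue = 1e-9)
  fmt <- format_predictions(sc, g, t = 0.3, hits = hits)
  expect_equal(fmt[[1]]$similar_proteins$id, c("s_hi", "s_lo"))
})

test_that("prediction writers emit valid JSON and TSV", {
  g <- chain_ontology()
  sc <- pm(c(0.9, 0.8, 0.4), "q1", c("R", "A", "C"))
  hits <- data.frame(query = "q1", subject = "s1", bitscore = 55,
                     evalue = 1e-9)
  fmt <- format_predictions(sc, g, t = 0.3, hits = hits)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_predictions_json(fmt, jpath)
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed[[1]]$protein_id, "q1")
  expect_equal(parsed[[1]]$predictions$biological_process[[1]]$go_id, "R")
  expect_equal(parsed[[1]]$similar_proteins[[1]]$bitscore, 55)

  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_predictions_tsv(fmt, tpath)
  tab <- read.delim(tpath)
  expect_equal(names(tab), c("protein", "go_id", "namespace", "score"))
  expect_equal(nrow(tab), 3L)
})
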