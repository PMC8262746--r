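truth2 <- function(sets) corpus_from_sets(sets)

test_that("a perfect predictor attains Fmax = 1 and Smin = 0", {
  truth <- truth2(list(p1 = c("a", "b"), p2 = "a"))
  sc <- matrix(c(1, 1, 1, 0), nrow = 2L, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("a", "b")))
  ic <- ic_table(c(a = 1, b = 2))
  ev <- evaluate_predictions(sc, truth, ic = ic)
  expect_equal(ev$fmax, 1)
  expect_equal(ev$smin, 0)
  expect_equal(fmax_only(sc, truth)$fmax, 1)
  expect_equal(smin_only(sc, truth, ic)$smin, 0)
})

test_that("hand sweep: one protein, half-right predictions give F = 0.5", {
  truth <- truth2(list(p1 = c("a", "b")))
  sc <- matrix(c(0.9, 0.9), nrow = 1L,
               dimnames = list("p1", c("a", "c")))
  ev <- evaluate_predictions(sc, truth)
  low <- ev$table$threshold <= 0.9
  expect_true(all(ev$table$avg_pr[low] == 0.5))
  expect_true(all(ev$table$avg_rc[low] == 0.5))
  expect_true(all(ev$table$f[low] == 0.5))
  expect_equal(ev$fmax, 0.5)
  expect_equal(fmax_only(sc, truth)$threshold, 0)   # smallest maximiser
})

test_that("AvgPr averages over covered proteins, AvgRc over all proteins", {
  truth <- truth2(list(p1 = "a", p2 = "a"))
  sc <- matrix(c(0.8, 0), nrow = 2L,
               dimnames = list(c("p1", "p2"), "a"))
  ev <- evaluate_predictions(sc, truth)
  at5 <- ev$table[ev$table$threshold == 0.5, ]
  expect_equal(at5$m, 1L)              # only p1 has a prediction
  expect_equal(at5$avg_pr, 1)          # averaged over m(t) = 1
  expect_equal(at5$avg_rc, 0.5)        # averaged over n = 2
})

test_that("the sweep grid is exactly 101 thresholds with monotone m and recall", {
  g <- random_dag(10L, seed = 31)
  truth <- propagate_annotations(g, random_raw_annotations(g, 6L, seed = 32))
  sc <- random_scores(g, 6L, seed = 33)
  ev <- evaluate_predictions(sc, truth)
  expect_equal(ev$table$threshold, seq(0, 1, by = 0.01))
  expect_equal(nrow(ev$table), 101L)
  expect_true(all(diff(ev$table$avg_rc) <= 1e-12))
  expect_true(all(diff(ev$table$m) <= 0L))
})

test_that("all-zero scores yield Fmax 0 under the documented convention", {
  truth <- truth2(list(p1 = "a"))
  sc <- matrix(0, 1L, 1L, dimnames = list("p1", "a"))
  ev <- evaluate_predictions(sc, truth)
  expect_equal(ev$fmax, 0)
  expect_true(all(ev$table$avg_rc == 0))
})

test_that("hand sweep of the semantic-distance minimum", {
  # truth {A} (IC 1), prediction {B} (IC 2) at scores below 1: for t <= 0.6
  # S = sqrt(1 + 4); once B drops out only the missed A remains: S = 1
  truth <- truth2(list(p1 = "A"))
  sc <- matrix(0.6, 1L, 1L, dimnames = list("p1", "B"))
  ic <- ic_table(c(A = 1, B = 2))
  ev <- evaluate_predictions(sc, truth, ic = ic)
  expect_equal(ev$table$s[ev$table$threshold == 0.5], sqrt(5))
  expect_equal(ev$smin, 1)
  expect_equal(ev$smin_threshold, 0.61)     # smallest minimiser on the grid

  doubled <- ic_table(c(A = 2, B = 4))
  expect_equal(smin_only(sc, truth, doubled)$smin, 2)   # homogeneity
})

test_that("evaluation errors on unlabeled proteins and empty truth", {
  truth <- truth2(list(p1 = "a"))
  sc <- matrix(0.5, 1L, 1L, dimnames = list("p_unknown", "a"))
  expect_error(evaluate_predictions(sc, truth), "p_unknown")
  expect_error(evaluate_predictions(sc, truth2(list())), "empty")
})

test_that("sweep agrees with the set-arithmetic oracle on random instances", {
  for (seed in 1:30) {
    g <- random_dag(sample(4:10, 1L), seed = 1300 + seed)
    n_prot <- sample(2:5, 1L)
    truth <- propagate_annotations(
      g, random_raw_annotations(g, n_prot, seed = 1400 + seed))
    sc <- random_scores(g, n_prot, seed = 1500 + seed)
    ic_vals <- setNames(round(runif(length(g$classes), 0.1, 3), 3),
                        g$classes)
    ev <- evaluate_predictions(sc, truth, ic = ic_table(ic_vals))
    expect_equal(ev$fmax,
                 oracle_fmax(matrix_to_rows(sc), truth$annotations),
                 tolerance = 1e-12)
    expect_equal(ev$smin,
                 oracle_smin(matrix_to_rows(sc), truth$annotations, ic_vals),
                 tolerance = 1e-12)
  }
})

test_that("multi-namespace evaluation decomposes into per-namespace runs", {
  cfg <- synth_config(seed = 41L, n_namespaces = 3L, n_proteins = 40L,
                      depth = 1L, branching = 3L)
  onto <- make_ontology(cfg)
  prot <- sample_proteins(onto$graph, onto$motifs, cfg)
  truth <- propagate_annotations(onto$graph, prot$raw)
  sc <- random_scores(onto$graph, 40L, seed = 42)
  rownames(sc) <- prot$records$id
  namespaces <- unique(unname(onto$graph$namespace))
  expect_length(namespaces, 3L)
  per_ns <- lapply(namespaces, function(ns)
    evaluate_predictions(sc, truth, graph = onto$graph, namespace = ns))
  # each per-namespace run only sees that namespace's classes
  for (k in seq_along(namespaces)) {
    ns_classes <- names(onto$graph$namespace)[
      onto$graph$namespace == namespaces[[k]]]
    keep <- intersect(colnames(sc), ns_classes)
    solo <- evaluate_predictions(sc[, keep, drop = FALSE], truth,
                                 graph = onto$graph,
                                 namespace = namespaces[[k]])
    expect_equal(per_ns[[k]]$fmax, solo$fmax)
    expect_equal(per_ns[[k]]$table$avg_rc, solo$table$avg_rc)
  }
})

test_that("evaluation reports serialise to JSON and TSV", {
  truth <- truth2(list(p1 = c("a", "b")))
  sc <- matrix(c(0.9, 0.2), 1L, dimnames = list("p1", c("a", "b")))
  ev <- evaluate_predictions(sc, truth, ic = ic_table(c(a = 1, b = 1)))
  jp <- withr::local_tempfile(fileext = ".json")
  write_eval_json(ev, jp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$fmax, ev$fmax)
  expect_length(parsed$table$threshold, 101L)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_eval_tsv(ev, tp)
  expect_equal(nrow(read.delim(tp)), 101L)
})
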