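# Fixture builders used across the suite. All ontologies are constructed in
# code; "chain" is R <- A <- C, "diamond" is A <- {B, C} <- D.

chain_ontology <- function() {
  go_ontology(
    classes = c("R", "A", "C"),
    edges = data.frame(child = c("A", "C"), parent = c("R", "A"),
                       relation = "is_a"),
    namespace = setNames(rep("biological_process", 3), c("R", "A", "C")))
}

diamond_ontology <- function() {
  go_ontology(
    classes = c("A", "B", "C", "D"),
    edges = data.frame(child = c("B", "C", "D", "D"),
                       parent = c("A", "A", "B", "C"),
                       relation = "is_a"),
    namespace = setNames(rep("biological_process", 4),
                         c("A", "B", "C", "D")))
}

# A corpus does not need to come from propagate_annotations for functions
# that only count classes; build one directly from closed sets.
corpus_from_sets <- function(sets) {
  structure(list(annotations = lapply(sets, sort), proteins = names(sets)),
            class = "go_corpus")
}

ic_table <- function(ic, log_base = 2) {
  structure(list(ic = ic, log_base = log_base,
                 counts = setNames(rep(NA_integer_, length(ic)), names(ic))),
            class = "go_ic")
}

# Random rooted DAG: class 1 is the root; every later class gets 1-2 parents
# among earlier classes, so the graph is acyclic by construction.
random_dag <- function(n_classes, seed, p_extra = 0.3) {
  set.seed(seed)
  ids <- sprintf("C%02d", seq_len(n_classes))
  edges <- list()
  for (i in seq_len(n_classes)[-1L]) {
    parents <- sample(i - 1L, 1L)
    if (i > 2L && runif(1) < p_extra)
      parents <- unique(c(parents, sample(i - 1L, 1L)))
    for (p in parents)
      edges[[length(edges) + 1L]] <- data.frame(child = ids[[i]],
                                                parent = ids[[p]],
                                                relation = "is_a")
  }
  go_ontology(ids, do.call(rbind, edges),
              setNames(rep("biological_process", n_classes), ids))
}

random_raw_annotations <- function(graph, n_proteins, seed) {
  set.seed(seed)
  raw <- lapply(seq_len(n_proteins), function(i)
    sample(graph$classes, sample(1:3, 1L)))
  names(raw) <- sprintf("p%02d", seq_len(n_proteins))
  raw
}

# Random dense score matrix over the classes of a graph.
random_scores <- function(graph, n_proteins, seed) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_proteins))
  matrix(round(runif(n_proteins * length(graph$classes)), 3),
         nrow = n_proteins,
         dimnames = list(ids, graph$classes))
}

toy_cnn_config <- function(vocab, seed = 1L, ...) {
  cnn_config(vocabulary = vocab, kernel_sizes = c(2L, 3L), n_filters = 4L,
             max_len = 20L, epochs = 2L, validation_split = 0,
             patience = Inf, seed = seed, ...)
}

toy_records <- function(n, len = 15L, seed = 1L) {
  set.seed(seed)
  data.frame(id = sprintf("q%02d", seq_len(n)),
             sequence = vapply(seq_len(n), function(i)
               paste(sample(protein_alphabet[1:20], len, replace = TRUE),
                     collapse = ""), character(1)))
}
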