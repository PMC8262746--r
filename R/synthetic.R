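#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the inputs of the prediction pipeline at desk
#' scale: a small GO-like DAG (a rooted tree per namespace, optionally
#' with extra "diamond" edges), proteins that draw leaf classes and carry
#' the leaf's sequence motif implanted into background sequence, and a
#' pseudo-similarity hit table based on shared k-mers. Functions are
#' therefore learnable from sequence, and annotation transfer from
#' motif-sharing proteins is informative.
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @param n_namespaces number of independent sub-ontologies (default 1).
#' @param depth,branching tree depth below the root and branching factor
#'   (default 2 and 3: 13 classes per namespace).
#' @param diamond_prob probability that a non-root class gains a second
#'   parent (creates diamond motifs in the DAG; default 0).
#' @param n_proteins number of proteins to sample (default 500).
#' @param seq_len_range integer range of sequence lengths (default
#'   80..120).
#' @param motif_length length of each leaf motif (default 8).
#' @param implant_prob probability that each owned leaf's motif is
#'   actually implanted (default 0.9).
#' @param leaf_extra_prob probability that a protein owns a second leaf
#'   class (default 0.4).
#' @param background_freqs residue frequencies of the background sequence
#'   (default uniform over the 20 standard residues).
#' @param hit_scale bitscore contributed per shared k-mer (default 25).
#' @param hit_noise_sd standard deviation of bitscore noise (default 2).
#' @param hit_floor minimum bitscore for a pair to be reported
#'   (default 10).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_namespaces = 1L, depth = 2L,
                         branching = 3L, diamond_prob = 0,
                         n_proteins = 500L, seq_len_range = c(80L, 120L),
                         motif_length = 8L, implant_prob = 0.9,
                         leaf_extra_prob = 0.4,
                         background_freqs = NULL,
                         hit_scale = 25, hit_noise_sd = 2,
                         hit_floor = 10) {
  stopifnot(n_namespaces >= 1L, depth >= 1L, branching >= 1L,
            n_proteins >= 1L, motif_length >= 1L,
            implant_prob >= 0, implant_prob <= 1,
            diamond_prob >= 0, diamond_prob <= 1,
            length(seq_len_range) == 2L,
            seq_len_range[[1L]] <= seq_len_range[[2L]],
            motif_length <= seq_len_range[[1L]])
  if (is.null(background_freqs)) {
    aa <- protein_alphabet[1:20]
    background_freqs <- setNames(rep(1 / 20, 20), aa)
  }
  structure(list(seed = as.integer(seed),
                 n_namespaces = as.integer(n_namespaces),
                 depth = as.integer(depth), branching = as.integer(branching),
                 diamond_prob = diamond_prob,
                 n_proteins = as.integer(n_proteins),
                 seq_len_range = as.integer(seq_len_range),
                 motif_length = as.integer(motif_length),
                 implant_prob = implant_prob,
                 leaf_extra_prob = leaf_extra_prob,
                 background_freqs = background_freqs,
                 hit_scale = hit_scale, hit_noise_sd = hit_noise_sd,
                 hit_floor = hit_floor),
            class = "synth_config")
}

.synth_namespaces <- function(config) {
  if (config$n_namespaces == 1L) "biological_process"
  else paste0("synthetic_namespace_", seq_len(config$n_namespaces))
}

#' Generate a toy GO-like ontology with leaf motifs
#'
#' Builds, per namespace, a rooted tree of the configured depth and
#' branching (13 classes at the defaults), optionally adding extra edges
#' to non-root classes so the graph is a genuine DAG. Each leaf is
#' assigned a unique random amino-acid motif; internal classes gain
#' sequence signal only through annotation propagation from their leaves.
#'
#' @param config a [synth_config()].
#' @return list with `graph` (a `go_ontology`) and `motifs` (named
#'   character vector, leaf class -> motif).
#' @export
make_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  namespaces <- .synth_namespaces(config)
  next_id <- 1L
  mk_id <- function() {
    id <- sprintf("GO:%07d", next_id)
    next_id <<- next_id + 1L
    id
  }
  classes <- character(0); ns_of <- character(0)
  edges <- list()
  leaves <- character(0)
  for (ns in namespaces) {
    levels <- list(mk_id())
    for (d in seq_len(config$depth)) {
      prev <- levels[[d]]
      cur <- character(0)
      for (p in prev) {
        for (b in seq_len(config$branching)) {
          id <- mk_id()
          cur <- c(cur, id)
          edges[[length(edges) + 1L]] <-
            data.frame(child = id, parent = p, relation = "is_a")
        }
      }
      levels[[d + 1L]] <- cur
    }
    all_ns <- unlist(levels)
    classes <- c(classes, all_ns)
    ns_of <- c(ns_of, setNames(rep(ns, length(all_ns)), all_ns))
    leaves <- c(leaves, levels[[length(levels)]])
    # optional diamond edges: a deeper class gains a second, shallower parent
    if (config$diamond_prob > 0 && config$depth >= 2L) {
      for (d in 3:length(levels)) {
        for (cls in levels[[d]]) {
          if (runif(1) < config$diamond_prob) {
            cand <- setdiff(levels[[d - 1L]],
                            vapply(edges, function(e)
                              if (e$child == cls) e$parent else "",
                              character(1)))
            cand <- cand[nzchar(cand)]
            if (length(cand) > 0L)
              edges[[length(edges) + 1L]] <-
                data.frame(child = cls, parent = sample(cand, 1L),
                           relation = "is_a")
          }
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  name <- setNames(paste("synthetic class", seq_along(classes)), classes)
  graph <- go_ontology(classes, edges, ns_of, name)
  aa <- names(config$background_freqs)
  motifs <- character(0)
  for (lf in leaves) {
    repeat {
      m <- paste(sample(aa, config$motif_length, replace = TRUE),
                 collapse = "")
      if (!m %in% motifs) break
    }
    motifs[[lf]] <- m
  }
  list(graph = graph, motifs = motifs)
}

#' Sample motif-implanted protein sequences with annotations
#'
#' Each protein draws at least one leaf class, samples a background
#' sequence from the configured residue frequencies, and implants each
#' owned leaf's motif at a uniform random non-overlapping position with
#' probability `implant_prob`. Raw annotations are the drawn leaves;
#' upward propagation is left to [propagate_annotations()].
#'
#' @param graph a `go_ontology` from [make_ontology()].
#' @param motifs leaf motif map from [make_ontology()].
#' @param config a [synth_config()].
#' @param ids optional protein identifiers (default P0001, P0002, ...).
#' @return list with `records` (data.frame id/sequence) and `raw` (named
#'   list protein -> drawn leaf classes).
#' @export
sample_proteins <- function(graph, motifs, config, ids = NULL) {
  set.seed(config$seed + 1L)
  n <- config$n_proteins
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  stopifnot(length(ids) == n)
  leaves <- names(motifs)
  aa <- names(config$background_freqs)
  records <- vector("list", n)
  raw <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 1L + rbinom(1L, 1L, config$leaf_extra_prob)
    owned <- sample(leaves, min(k, length(leaves)))
    len <- sample(seq(config$seq_len_range[[1L]], config$seq_len_range[[2L]]), 1L)
    to_implant <- owned[runif(length(owned)) < config$implant_prob]
    need <- length(to_implant) * config$motif_length
    while (len < 2L * need && need > 0L) {   # room for non-overlapping placement
      len <- len + config$motif_length
    }
    seq_chars <- sample(aa, len, replace = TRUE,
                        prob = unname(config$background_freqs))
    occupied <- logical(len)
    for (m in motifs[to_implant]) {
      ml <- nchar(m)
      placed <- FALSE
      for (try in 1:100) {
        start <- sample.int(len - ml + 1L, 1L)
        span <- start:(start + ml - 1L)
        if (!any(occupied[span])) {
          seq_chars[span] <- strsplit(m, "")[[1L]]
          occupied[span] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) message("sample_proteins: could not place a motif in ",
                           ids[[i]], " (sequence crowded)")
    }
    records[[i]] <- data.frame(id = ids[[i]],
                               sequence = paste(seq_chars, collapse = ""))
    raw[[i]] <- sort(owned)
  }
  names(raw) <- ids
  list(records = do.call(rbind, records), raw = raw)
}

.kmer_set <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  unique(substring(sequence, 1:(L - k + 1L), k:L))
}

#' Simulate a similarity hit table from shared k-mers
#'
#' Pseudo-alignment stand-in for a real sequence search: the bitscore of a
#' (query, training protein) pair is `hit_scale` times the number of
#' shared motif-length k-mers plus seeded Gaussian noise; pairs below
#' `hit_floor` are omitted, and e-values are assigned as a monotonically
#' decreasing function of bitscore (10^(-bitscore/4)) so that weak hits
#' are removed by the standard e-value cutoff. Background-only pairs share
#' no k-mers at the default lengths (k-mer collisions over a 20-letter
#' alphabet are vanishingly rare) and are therefore absent.
#'
#' @param records query sequences (data.frame id/sequence).
#' @param train training sequences (data.frame id/sequence).
#' @param config a [synth_config()].
#' @return A `hit_table` data.frame (query, subject, bitscore, evalue).
#' @export
simulate_hits <- function(records, train, config) {
  set.seed(config$seed + 2L)
  k <- config$motif_length
  train_kmers <- lapply(train$sequence, .kmer_set, k = k)
  # invert: k-mer -> training protein indices
  inv <- new.env(parent = emptyenv())
  for (j in seq_along(train_kmers)) {
    for (km in train_kmers[[j]]) {
      assign(km, c(get0(km, envir = inv, ifnotfound = integer(0)), j),
             envir = inv)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(records))) {
    qk <- .kmer_set(records$sequence[[i]], k)
    shared <- table(unlist(lapply(qk, function(km)
      get0(km, envir = inv, ifnotfound = integer(0))), use.names = FALSE))
    if (length(shared) == 0L) next
    subj_idx <- as.integer(names(shared))
    bitscore <- round(config$hit_scale * as.numeric(shared) +
                        rnorm(length(shared), sd = config$hit_noise_sd), 1)
    keep <- bitscore >= config$hit_floor
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(query = records$id[[i]],
                 subject = train$id[subj_idx[keep]],
                 bitscore = bitscore[keep],
                 evalue = 10^(-bitscore[keep] / 4))
  }
  out <- if (length(rows) == 0L)
    data.frame(query = character(0), subject = character(0),
               bitscore = numeric(0), evalue = numeric(0))
  else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' Emits one `[Term]` stanza per class (id, name, namespace, `is_a:` and
#' `relationship: part_of` lines) plus stanzas for obsolete terms; the
#' output round-trips through [parse_obo()].
#'
#' @param graph a `go_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (cls in graph$classes) {
    lines <- c("[Term]", paste0("id: ", cls),
               paste0("name: ", if (cls %in% names(graph$name))
                 graph$name[[cls]] else cls),
               paste0("namespace: ", graph$namespace[[cls]]))
    e <- graph$edges[graph$edges$child == cls, , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      lines <- c(lines, if (e$relation[[r]] == "is_a")
        paste0("is_a: ", e$parent[[r]])
        else paste0("relationship: ", e$relation[[r]], " ", e$parent[[r]]))
    }
    alt <- names(graph$alt_ids)[graph$alt_ids == cls]
    for (a in alt) lines <- c(lines, paste0("alt_id: ", a))
    writeLines(c(lines, ""), con)
  }
  for (cls in graph$obsolete)
    writeLines(c("[Term]", paste0("id: ", cls), "is_obsolete: true", ""),
               con)
  invisible(path)
}

#' Write annotation records as a 3-column TSV
#'
#' @param raw named list protein -> classes, or a data.frame with
#'   protein/class/evidence columns.
#' @param path output file path.
#' @param evidence evidence code used when `raw` is a list (default IDA).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(raw, path, evidence = "IDA") {
  df <- if (is.data.frame(raw)) raw else
    data.frame(protein = rep(names(raw), lengths(raw)),
               class = unlist(raw, use.names = FALSE),
               evidence = evidence)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: builds the ontology, samples proteins, splits them
#' into training and test sets, propagates annotations, and simulates the
#' test-versus-training hit table.
#'
#' @param config a [synth_config()].
#' @param test_fraction fraction of proteins held out as queries
#'   (default 0.2).
#' @return list with `graph`, `motifs`, `records`, `raw`, `corpus` (all
#'   proteins, propagated), `train_ids`, `test_ids`, `train_corpus`, and
#'   `hits` (test queries vs training proteins).
#' @export
synth_benchmark <- function(config, test_fraction = 0.2) {
  onto <- make_ontology(config)
  prot <- sample_proteins(onto$graph, onto$motifs, config)
  corpus <- propagate_annotations(onto$graph, prot$raw)
  n <- nrow(prot$records)
  set.seed(config$seed + 3L)
  test_ids <- sort(sample(prot$records$id, floor(test_fraction * n)))
  train_ids <- setdiff(prot$records$id, test_ids)
  train_rec <- prot$records[prot$records$id %in% train_ids, , drop = FALSE]
  test_rec <- prot$records[prot$records$id %in% test_ids, , drop = FALSE]
  train_corpus <- propagate_annotations(onto$graph, prot$raw[train_ids])
  hits <- simulate_hits(test_rec, train_rec, config)
  list(graph = onto$graph, motifs = onto$motifs, records = prot$records,
       raw = prot$raw, corpus = corpus, train_ids = train_ids,
       test_ids = test_ids, train_corpus = train_corpus, hits = hits)
}
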