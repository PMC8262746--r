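#' Combine CNN and similarity scores with a weighted sum
#'
#' Final prediction scores are `alpha * similarity + (1 - alpha) * cnn`,
#' where `alpha` in [0, 1] weights the relative importance of the
#' similarity-transfer component. The result covers the union of proteins
#' and classes of the two inputs; a component that does not score a
#' (protein, class) pair contributes 0.
#'
#' @param cnn numeric matrix of CNN scores (proteins x classes), or NULL.
#' @param similarity numeric matrix of similarity-transfer scores, or NULL.
#' @param alpha weight on the similarity component, in [0, 1]. Default 0.5.
#' @return numeric matrix over the union of rows/columns, values in [0, 1].
#' @export
combine_scores <- function(cnn, similarity, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  if (is.null(cnn) && is.null(similarity))
    stop("at least one score matrix is required")
  mats <- Filter(Negate(is.null), list(cnn = cnn, similarity = similarity))
  proteins <- unique(unlist(lapply(mats, rownames), use.names = FALSE))
  classes <- sort(unique(unlist(lapply(mats, colnames), use.names = FALSE)))
  expand <- function(m) {
    out <- matrix(0, length(proteins), length(classes),
                  dimnames = list(proteins, classes))
    if (!is.null(m) && nrow(m) > 0L && ncol(m) > 0L)
      out[rownames(m), colnames(m)] <- m
    out
  }
  alpha * expand(similarity) + (1 - alpha) * expand(cnn)
}

#' Drop scored classes that are absent from the ontology
#'
#' Handles version skew between the model vocabulary and the ontology
#' release: columns whose class cannot be resolved are removed with a
#' warning; alternative ids are mapped to their canonical class (keeping
#' the maximum score on collision).
#'
#' @param scores numeric matrix (proteins x classes).
#' @param graph a `go_ontology`.
#' @return the pruned matrix with canonical column names.
#' @export
prune_to_ontology <- function(scores, graph) {
  cls <- colnames(scores)
  mapped <- ifelse(cls %in% names(graph$alt_ids),
                   unname(graph$alt_ids[cls]), cls)
  keep <- mapped %in% graph$classes
  if (any(!keep))
    warning("dropping ", sum(!keep),
            " scored class(es) absent from the ontology: ",
            paste(head(cls[!keep], 5L), collapse = ", "))
  scores <- scores[, keep, drop = FALSE]
  mapped <- mapped[keep]
  if (anyDuplicated(mapped)) {
    out <- matrix(0, nrow(scores), length(unique(mapped)),
                  dimnames = list(rownames(scores), unique(mapped)))
    for (j in seq_along(mapped))
      out[, mapped[[j]]] <- pmax(out[, mapped[[j]]], scores[, j])
    out
  } else {
    colnames(scores) <- mapped
    scores
  }
}

#' Enforce true-path-rule consistency on prediction scores
#'
#' Post-processes scores so that each class's score is the maximum of its
#' own score and the scores of all its (scored) subclasses; afterwards
#' scores decrease monotonically from a class to its subclasses and the
#' namespace root carries the block maximum. Idempotent; never decreases a
#' score. Scored classes must be resolvable in the ontology.
#'
#' @param graph a `go_ontology`.
#' @param scores numeric matrix (proteins x classes).
#' @param relations relation labels defining the hierarchy.
#' @return matrix of the same shape with consistent scores.
#' @export
enforce_consistency <- function(graph, scores,
                                relations = go_default_relations) {
  cls <- colnames(scores)
  unknown <- setdiff(cls, graph$classes)
  if (length(unknown) > 0L)
    stop("unknown class identifier(s): ", paste(unknown, collapse = ", "))
  # children-before-parents over the scored columns; descendants that are
  # unscored contribute nothing (they carry no prediction to push up)
  order_pc <- .topo_order(graph, relations)       # parents before children
  children <- .adjacency(graph, relations, "down")
  out <- scores
  for (cl in rev(order_pc)) {
    if (!(cl %in% cls)) next
    ch <- intersect(children[[cl]], cls)
    for (d in ch) out[, cl] <- pmax(out[, cl], out[, d])
  }
  out
}

#' Threshold scores into predicted annotation sets
#'
#' A class counts as predicted when its score is at least `t` (or strictly
#' above `t` with `strict = TRUE`). The default threshold of 0.3 is the
#' operating point that maximises Fmax at production scale. A score of
#' exactly 0 never counts as a prediction: dense score matrices zero-fill
#' the (protein, class) pairs that no component scored, so 0 encodes
#' "unscored" and sparse and dense representations stay equivalent.
#'
#' @param scores numeric matrix (proteins x classes).
#' @param t threshold in [0, 1].
#' @param strict use strictly-greater comparison.
#' @return named list: protein -> sorted character vector of classes.
#' @export
threshold_predictions <- function(scores, t = 0.3, strict = FALSE) {
  stopifnot(t >= 0, t <= 1)
  cls <- colnames(scores)
  out <- lapply(seq_len(nrow(scores)), function(i) {
    keep <- if (strict) scores[i, ] > t else scores[i, ] >= t
    sort(cls[keep & scores[i, ] > 0])
  })
  names(out) <- rownames(scores)
  out
}

#' Format thresholded predictions as a structured report
#'
#' Per protein and GO namespace, the classes with score at least `t`,
#' sorted by descending score with ties broken lexicographically by class
#' id. Every namespace present in the ontology appears, possibly with an
#' empty block. When a hit table is supplied, each protein's similarity
#' provenance (subject, bitscore), sorted by bitscore, is attached.
#'
#' @param scores consistency-enforced numeric matrix (proteins x classes).
#' @param graph a `go_ontology`.
#' @param t confidence threshold (default 0.3).
#' @param hits optional `hit_table` for provenance.
#' @param strict strict threshold comparison (see
#'   [threshold_predictions()]).
#' @return A `go_predictions` object: list of per-protein records, each
#'   with `protein_id`, `predictions` (namespace -> data.frame of go_id,
#'   name, score) and `similar_proteins` (data.frame of id, bitscore).
#' @export
format_predictions <- function(scores, graph, t = 0.3, hits = NULL,
                               strict = FALSE) {
  namespaces <- sort(unique(unname(graph$namespace)))
  cls <- colnames(scores)
  ns_of <- graph$namespace[cls]
  result <- lapply(seq_len(nrow(scores)), function(i) {
    blocks <- setNames(lapply(namespaces, function(ns) {
      in_ns <- which(ns_of == ns)
      sc <- scores[i, in_ns]
      keep <- if (strict) sc > t else sc >= t
      ids <- cls[in_ns][keep]
      sc <- sc[keep]
      ord <- order(-sc, ids)
      data.frame(go_id = ids[ord],
                 name = unname(ifelse(ids[ord] %in% names(graph$name),
                                      graph$name[ids[ord]], ids[ord])),
                 score = unname(sc[ord]))
    }), namespaces)
    prov <- NULL
    if (!is.null(hits)) {
      h <- hits[hits$query == rownames(scores)[[i]], , drop = FALSE]
      h <- h[order(-h$bitscore, h$subject), , drop = FALSE]
      prov <- data.frame(id = h$subject, bitscore = h$bitscore)
    }
    list(protein_id = rownames(scores)[[i]], predictions = blocks,
         similar_proteins = prov)
  })
  structure(result, class = "go_predictions", threshold = t)
}

#' @export
print.go_predictions <- function(x, ...) {
  cat("Function predictions for ", length(x), " protein(s), threshold ",
      attr(x, "threshold"), "\n", sep = "")
  for (rec in head(x, 3L)) {
    cat("\n", rec$protein_id, "\n", sep = "")
    for (ns in names(rec$predictions)) {
      blk <- rec$predictions[[ns]]
      cat("  [", ns, "] ", nrow(blk), " prediction(s)\n", sep = "")
      if (nrow(blk) > 0L)
        for (j in seq_len(min(5L, nrow(blk))))
          cat(sprintf("    %s  %-40s %.3f\n", blk$go_id[[j]],
                      blk$name[[j]], blk$score[[j]]))
    }
  }
  if (length(x) > 3L) cat("\n... and", length(x) - 3L, "more\n")
  invisible(x)
}

#' Serialise predictions to JSON or TSV
#'
#' JSON schema: one record per protein with `protein_id`, `predictions`
#' (namespace -> array of `{go_id, name, score}`) and `similar_proteins`
#' (array of `{id, bitscore}`). The TSV layout is flat:
#' protein, go_id, namespace, score.
#'
#' @param preds a `go_predictions` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_json <- function(preds, path) {
  recs <- lapply(preds, function(rec) {
    list(protein_id = rec$protein_id,
         predictions = lapply(rec$predictions, function(blk)
           if (nrow(blk) == 0L) list() else blk),
         similar_proteins = if (is.null(rec$similar_proteins) ||
                                nrow(rec$similar_proteins) == 0L) list()
         else rec$similar_proteins)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_predictions_json
#' @param graph the ontology (for namespaces in the TSV output).
#' @export
write_predictions_tsv <- function(preds, path, graph = NULL) {
  rows <- do.call(rbind, lapply(preds, function(rec)
    do.call(rbind, lapply(names(rec$predictions), function(ns) {
      blk <- rec$predictions[[ns]]
      if (nrow(blk) == 0L) return(NULL)
      data.frame(protein = rec$protein_id, go_id = blk$go_id,
                 namespace = ns, score = blk$score)
    }))))
  if (is.null(rows))
    rows <- data.frame(protein = character(0), go_id = character(0),
                       namespace = character(0), score = numeric(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
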