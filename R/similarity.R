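#' Parse BLAST/DIAMOND tabular hits (outfmt 6)
#'
#' Reads the 12-column tab-separated format (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). Rows with e-value above `evalue_max` are dropped and
#' duplicate (query, subject) pairs — multiple HSPs — are collapsed keeping
#' the maximum bitscore.
#'
#' @param input path to a hits file, or a character vector of lines.
#' @param evalue_max e-value cutoff (default 0.001).
#' @return A `hit_table` data.frame with columns `query`, `subject`,
#'   `bitscore`, `evalue`.
#' @export
parse_hits <- function(input, evalue_max = 0.001) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else as.character(input)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), evalue = numeric(0))
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(fields, length, integer(1))
  if (any(nc != 12L))
    stop("malformed hit row (expected 12 tab-separated columns) at line ",
         which(nc != 12L)[[1L]])
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 11L)))
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 12L)))
  bad <- which(is.na(evalue) | is.na(bitscore))
  if (length(bad) > 0L)
    stop("non-numeric e-value or bitscore at line ", bad[[1L]])
  df <- data.frame(query = vapply(fields, `[[`, character(1), 1L),
                   subject = vapply(fields, `[[`, character(1), 2L),
                   bitscore = bitscore, evalue = evalue)
  df <- df[df$evalue <= evalue_max, , drop = FALSE]
  if (nrow(df) > 0L) {
    # max bitscore per (query, subject) pair
    ord <- order(df$query, df$subject, -df$bitscore)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df[c("query", "subject")]), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' Emits 12 tab-separated columns; the alignment-detail columns that the
#' scoring does not use (pident, length, mismatch, gapopen, coordinates)
#' are filled with zeros.
#'
#' @param hits a `hit_table` (or data.frame with query/subject/bitscore/
#'   evalue columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t%g\t%g",
                   hits$query, hits$subject, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Similarity-based prediction scores for one query
#'
#' Bitscore-weighted annotation transfer: for the set E of similar
#' sequences of query q, the score of class f is
#' sum over s in E of I(f in T_s) * bitscore(q, s), divided by the total
#' bitscore of E, where T_s is the (propagated) annotation set of subject
#' s. Scores therefore lie in (0, 1], and a class carried by every subject
#' scores exactly 1. Subjects absent from the corpus are skipped with a
#' message; with `exclude_self` the query itself never votes.
#'
#' @param hits a `hit_table`.
#' @param corpus a propagated `go_corpus` of subject annotations.
#' @param query query identifier.
#' @param exclude_self drop hits whose subject equals the query (prevents
#'   label leakage when the query is part of the corpus). Default TRUE.
#' @return named numeric vector class -> score (empty when the query has
#'   no usable hits).
#' @export
transfer_score <- function(hits, corpus, query, exclude_self = TRUE) {
  rows <- hits[hits$query == query, , drop = FALSE]
  if (exclude_self) rows <- rows[rows$subject != query, , drop = FALSE]
  if (nrow(rows) == 0L) return(setNames(numeric(0), character(0)))
  known <- rows$subject %in% corpus$proteins
  if (any(!known))
    message("transfer_score: skipping ", sum(!known),
            " hit(s) with subjects absent from the corpus")
  rows <- rows[known, , drop = FALSE]
  total <- sum(rows$bitscore)
  if (nrow(rows) == 0L || total <= 0) {
    if (nrow(rows) > 0L) warning("total bitscore is zero for query ", query)
    return(setNames(numeric(0), character(0)))
  }
  votes <- unlist(lapply(seq_len(nrow(rows)), function(i)
    setNames(rep(rows$bitscore[[i]],
                 length(corpus$annotations[[rows$subject[[i]]]])),
             corpus$annotations[[rows$subject[[i]]]])),
    use.names = TRUE)
  score <- vapply(split(votes, names(votes)), sum, numeric(1)) / total
  sort(score, decreasing = TRUE)
}

#' Similarity scores for a batch of queries, as a prediction matrix
#'
#' Applies [transfer_score()] to each query and assembles the results into
#' a dense protein x class matrix (zero where a class received no votes).
#'
#' @inheritParams transfer_score
#' @param queries character vector of query ids (rows of the result).
#' @return numeric matrix, rownames = queries, colnames = scored classes.
#' @export
transfer_score_matrix <- function(hits, corpus, queries,
                                  exclude_self = TRUE) {
  per_query <- lapply(queries, function(q)
    transfer_score(hits, corpus, q, exclude_self = exclude_self))
  classes <- sort(unique(unlist(lapply(per_query, names), use.names = FALSE)))
  mat <- matrix(0, nrow = length(queries), ncol = length(classes),
                dimnames = list(queries, classes))
  for (i in seq_along(queries)) {
    s <- per_query[[i]]
    if (length(s) > 0L) mat[i, names(s)] <- unname(s)
  }
  mat
}
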