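# Independent brute-force oracles, written directly from the defining
# formulas and set arithmetic. They deliberately share no code with the
# package implementation paths they check.

# Reachability by explicit path extension: grow the set of reachable nodes
# one edge-hop at a time until a fixed point.
oracle_reachable <- function(edges, seed, direction = c("up", "down")) {
  direction <- match.arg(direction)
  from <- if (direction == "up") edges$child else edges$parent
  to <- if (direction == "up") edges$parent else edges$child
  reached <- seed
  repeat {
    nxt <- unique(to[from %in% reached])
    if (all(nxt %in% reached)) break
    reached <- union(reached, nxt)
  }
  sort(setdiff(reached, seed))
}

# Transfer score by explicit enumeration of (class, subject) indicator terms.
oracle_transfer <- function(hit_rows, annot_sets, query) {
  rows <- hit_rows[hit_rows$query == query, , drop = FALSE]
  rows <- rows[rows$subject %in% names(annot_sets), , drop = FALSE]
  if (nrow(rows) == 0L) return(setNames(numeric(0), character(0)))
  classes <- sort(unique(unlist(annot_sets[rows$subject])))
  denom <- sum(rows$bitscore)
  score <- vapply(classes, function(f) {
    num <- 0
    for (r in seq_len(nrow(rows))) {
      if (f %in% annot_sets[[rows$subject[[r]]]])
        num <- num + rows$bitscore[[r]]
    }
    num / denom
  }, numeric(1))
  score
}

# Consistency by max over explicitly enumerated descendant sets.
oracle_consistency <- function(edges, score_row) {
  out <- score_row
  for (cls in names(score_row)) {
    desc <- oracle_reachable(edges, cls, "down")
    desc <- intersect(desc, names(score_row))
    out[[cls]] <- max(score_row[c(cls, desc)])
  }
  out
}

# Per-protein set-arithmetic evaluation sweep over the 0.01 grid.
# pred_sets(t) uses score >= t (and > 0); AvgPr averages over proteins with
# at least one prediction, AvgRc over all proteins.
oracle_sweep <- function(score_rows, truth_sets, ic = NULL) {
  thresholds <- round(seq(0, 1, by = 0.01), 2)
  n <- length(truth_sets)
  res <- data.frame(threshold = thresholds, m = NA_integer_,
                    avg_pr = NA_real_, avg_rc = NA_real_,
                    ru = NA_real_, mi = NA_real_)
  for (k in seq_along(thresholds)) {
    t <- thresholds[[k]]
    prs <- c(); rcs <- c(); rus <- c(); mis <- c()
    for (i in seq_len(n)) {
      s <- score_rows[[i]]
      P <- names(s)[s >= t & s > 0]
      T_i <- truth_sets[[i]]
      if (length(P) > 0L)
        prs <- c(prs, length(intersect(P, T_i)) / length(P))
      rcs <- c(rcs, length(intersect(P, T_i)) / length(T_i))
      if (!is.null(ic)) {
        rus <- c(rus, sum(ic[setdiff(T_i, P)]))
        mis <- c(mis, sum(ic[setdiff(P, T_i)]))
      }
    }
    res$m[[k]] <- length(prs)
    res$avg_pr[[k]] <- if (length(prs)) mean(prs) else NA_real_
    res$avg_rc[[k]] <- mean(rcs)
    if (!is.null(ic)) {
      res$ru[[k]] <- mean(rus)
      res$mi[[k]] <- mean(mis)
    }
  }
  res
}

oracle_fmax <- function(score_rows, truth_sets) {
  sw <- oracle_sweep(score_rows, truth_sets)
  f <- with(sw, ifelse(m > 0 & (avg_pr + avg_rc) > 0,
                       2 * avg_pr * avg_rc / (avg_pr + avg_rc), 0))
  f[sw$m == 0] <- NA
  if (all(is.na(f))) 0 else max(f, na.rm = TRUE)
}

oracle_smin <- function(score_rows, truth_sets, ic) {
  sw <- oracle_sweep(score_rows, truth_sets, ic = ic)
  min(sqrt(sw$ru^2 + sw$mi^2))
}

# Convert a dense score matrix into the per-protein named-vector form the
# oracles consume.
matrix_to_rows <- function(scores) {
  lapply(seq_len(nrow(scores)), function(i)
    setNames(scores[i, ], colnames(scores)))
}
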