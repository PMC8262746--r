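#' Protein-centric evaluation over a threshold sweep
#'
#' Sweeps prediction thresholds t = 0.00, 0.01, ..., 1.00 (101 points) and
#' computes, at each t, the protein-centric average precision AvgPr(t)
#' (averaged over the m(t) proteins with at least one prediction), average
#' recall AvgRc(t) (averaged over all n evaluation proteins), the
#' F-measure, and — when an information-content table is supplied — the
#' average remaining uncertainty ru(t) (total IC of missed annotations)
#' and average misinformation mi(t) (total IC of spurious predictions).
#' Summary statistics:
#' \itemize{
#'   \item Fmax: the maximum over thresholds of the harmonic mean of
#'     AvgPr and AvgRc (thresholds where m(t) = 0 are skipped);
#'   \item Smin: the minimum over thresholds of
#'     sqrt(ru(t)^2 + mi(t)^2), the semantic distance between predicted
#'     and true annotation sets;
#'   \item AUPR: trapezoidal area under the (AvgRc, AvgPr) curve.
#' }
#' Tied optima resolve to the smallest threshold.
#'
#' Evaluation proteins are the rows of `scores`; each must be present in
#' the truth corpus. When `graph` and `namespace` are given the evaluation
#' is restricted to classes of that namespace; namespace roots are
#' excluded by default (they are trivially true for every protein).
#' Proteins with an empty truth set after restriction are dropped from the
#' evaluation set.
#'
#' @param scores numeric matrix (proteins x classes), consistency-enforced.
#' @param truth a propagated `go_corpus` of true annotations.
#' @param ic optional `go_ic` table; required for ru/mi/Smin. Classes
#'   absent from the table fall back to its maximum IC.
#' @param graph optional `go_ontology` for namespace restriction and root
#'   exclusion.
#' @param namespace optional namespace to restrict to.
#' @param exclude_roots drop namespace roots from truth and predictions
#'   (default TRUE).
#' @param strict count a class as predicted only when its score is
#'   strictly above t (default: at least t). In either convention a score
#'   of exactly 0 is treated as "unscored" (dense matrices zero-fill
#'   unscored pairs) and never counts as a prediction.
#' @return A `go_eval` object: list with `table` (per-threshold
#'   data.frame: threshold, m, avg_pr, avg_rc, f, ru, mi, s), `n`,
#'   `fmax`, `fmax_threshold`, `smin`, `smin_threshold`, `aupr`.
#' @export
evaluate_predictions <- function(scores, truth, ic = NULL, graph = NULL,
                                 namespace = NULL, exclude_roots = TRUE,
                                 strict = FALSE) {
  if (!inherits(truth, "go_corpus")) stop("truth must be a go_corpus")
  if (length(truth$proteins) == 0L) stop("empty truth corpus")
  proteins <- rownames(scores)
  missing <- setdiff(proteins, truth$proteins)
  if (length(missing) > 0L)
    stop("protein(s) in predictions but not in truth: ",
         paste(head(missing, 5L), collapse = ", "))

  keep_class <- function(cls) {
    if (!is.null(graph)) {
      if (!is.null(namespace))
        cls <- cls[cls %in% names(graph$namespace)[graph$namespace == namespace]]
      if (exclude_roots) cls <- setdiff(cls, unname(graph$roots))
    }
    cls
  }
  cols <- keep_class(colnames(scores))
  scores <- scores[, cols, drop = FALSE]
  truth_sets <- lapply(proteins, function(p)
    keep_class(truth$annotations[[p]]))
  names(truth_sets) <- proteins
  nonempty <- lengths(truth_sets) > 0L
  proteins <- proteins[nonempty]
  truth_sets <- truth_sets[nonempty]
  scores <- scores[nonempty, , drop = FALSE]
  n <- length(proteins)
  if (n == 0L) stop("no evaluation protein has a nonempty truth set")

  ic_of <- NULL
  if (!is.null(ic)) {
    ic_max <- max(ic$ic)
    ic_of <- function(cls) {
      v <- ic$ic[cls]
      v[is.na(v)] <- ic_max
      unname(v)
    }
  }

  thresholds <- round(seq(0, 1, by = 0.01), 2)   # exact grid values
  nt <- length(thresholds)
  m <- integer(nt); sum_pr <- numeric(nt); sum_rc <- numeric(nt)
  ru <- numeric(nt); mi <- numeric(nt)
  cls <- colnames(scores)
  for (i in seq_len(n)) {
    s <- scores[i, ]
    t_set <- truth_sets[[i]]
    in_truth <- cls %in% t_set
    # IC of truth classes that are never predicted still counts toward ru
    if (!is.null(ic_of)) {
      truth_ic <- ic_of(t_set)
      total_truth_ic <- sum(truth_ic)
      names(truth_ic) <- t_set
    }
    for (k in seq_len(nt)) {
      pred <- if (strict) s > thresholds[[k]] else s >= thresholds[[k]]
      pred <- pred & s > 0              # zero means "unscored", never predicted
      np <- sum(pred)
      tp <- sum(pred & in_truth)
      if (np > 0L) {
        m[[k]] <- m[[k]] + 1L
        sum_pr[[k]] <- sum_pr[[k]] + tp / np
      }
      sum_rc[[k]] <- sum_rc[[k]] + tp / length(t_set)
      if (!is.null(ic_of)) {
        pred_cls <- cls[pred]
        fn <- setdiff(t_set, pred_cls)
        fp <- setdiff(pred_cls, t_set)
        ru[[k]] <- ru[[k]] + sum(truth_ic[fn])
        mi[[k]] <- mi[[k]] + if (length(fp)) sum(ic_of(fp)) else 0
      }
    }
  }
  avg_pr <- ifelse(m > 0L, sum_pr / m, NA_real_)
  avg_rc <- sum_rc / n
  f <- ifelse(m > 0L & (avg_pr + avg_rc) > 0,
              2 * avg_pr * avg_rc / (avg_pr + avg_rc), 0)
  f[m == 0L] <- NA_real_
  ru <- if (is.null(ic_of)) rep(NA_real_, nt) else ru / n
  mi <- if (is.null(ic_of)) rep(NA_real_, nt) else mi / n
  s_dist <- sqrt(ru^2 + mi^2)

  valid <- which(m > 0L)
  fmax <- if (length(valid)) max(f[valid]) else 0
  fmax_threshold <- if (length(valid))
    thresholds[valid[which.max(f[valid])]] else NA_real_
  if (is.null(ic_of)) {
    smin <- NA_real_; smin_threshold <- NA_real_
  } else {
    smin <- min(s_dist)
    smin_threshold <- thresholds[[which.min(s_dist)]]
  }
  # trapezoid over the protein-centric (recall, precision) curve
  pr_pts <- avg_pr[valid]; rc_pts <- avg_rc[valid]
  ord <- order(rc_pts)
  aupr <- if (length(valid) >= 2L)
    sum(diff(rc_pts[ord]) * (head(pr_pts[ord], -1L) + tail(pr_pts[ord], -1L)) / 2)
  else 0

  structure(list(table = data.frame(threshold = thresholds, m = m,
                                    avg_pr = avg_pr, avg_rc = avg_rc, f = f,
                                    ru = ru, mi = mi, s = s_dist),
                 n = n, fmax = fmax, fmax_threshold = fmax_threshold,
                 smin = smin, smin_threshold = smin_threshold, aupr = aupr),
            class = "go_eval")
}

#' @export
print.go_eval <- function(x, ...) {
  cat("Protein-centric evaluation over ", x$n, " protein(s)\n", sep = "")
  cat(sprintf("  Fmax = %.4f at threshold %.2f\n", x$fmax, x$fmax_threshold))
  if (!is.na(x$smin))
    cat(sprintf("  Smin = %.4f at threshold %.2f\n", x$smin,
                x$smin_threshold))
  cat(sprintf("  AUPR = %.4f\n", x$aupr))
  invisible(x)
}

#' Fmax and its maximising threshold
#'
#' Convenience wrapper over [evaluate_predictions()].
#'
#' @inheritParams evaluate_predictions
#' @param ... forwarded to [evaluate_predictions()].
#' @return list with `fmax` and `threshold` (smallest maximiser).
#' @export
fmax_only <- function(scores, truth, ...) {
  ev <- evaluate_predictions(scores, truth, ...)
  list(fmax = ev$fmax, threshold = ev$fmax_threshold)
}

#' Smin and its minimising threshold
#'
#' @inheritParams evaluate_predictions
#' @param ... forwarded to [evaluate_predictions()].
#' @return list with `smin` and `threshold` (smallest minimiser).
#' @export
smin_only <- function(scores, truth, ic, ...) {
  ev <- evaluate_predictions(scores, truth, ic = ic, ...)
  list(smin = ev$smin, threshold = ev$smin_threshold)
}

#' Write an evaluation report
#'
#' JSON carries the summary statistics plus the per-threshold table; the
#' TSV is the flat per-threshold table alone.
#'
#' @param eval a `go_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval, path) {
  jsonlite::write_json(list(n = eval$n, fmax = eval$fmax,
                            fmax_threshold = eval$fmax_threshold,
                            smin = eval$smin,
                            smin_threshold = eval$smin_threshold,
                            aupr = eval$aupr, table = eval$table),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_eval_json
#' @export
write_eval_tsv <- function(eval, path) {
  write.table(eval$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
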