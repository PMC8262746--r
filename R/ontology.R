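#' @useDynLib protgo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rbinom setNames predict coef
#' @importFrom utils head tail read.delim write.table
NULL

#' Experimental GO evidence codes
#'
#' The thirteen evidence codes that mark experimentally supported GO
#' annotations (EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC, HTP, HDA, HMP, HGI,
#' HEP). Annotation corpora used for training and for information-content
#' estimation are conventionally restricted to these codes so that
#' electronically inferred annotations (IEA) do not leak into the labels.
#'
#' @export
go_experimental_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                           "TAS", "IC", "HTP", "HDA", "HMP", "HGI", "HEP")

#' Default ontology relations used for propagation
#' @export
go_default_relations <- c("is_a", "part_of")

#' Construct an ontology DAG object
#'
#' Low-level constructor used by [parse_obo()] and by the synthetic
#' generator. Validates acyclicity over the given edges and detects
#' per-namespace roots (classes without parents inside their own namespace).
#'
#' @param classes character vector of non-obsolete class identifiers.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param namespace named character vector, class -> namespace.
#' @param name optional named character vector of human-readable class names.
#' @param alt_ids named character vector mapping alias -> canonical id.
#' @param obsolete character vector of obsolete class identifiers.
#' @return An object of class `go_ontology` with fields `classes`, `edges`,
#'   `namespace`, `name`, `roots`, `alt_ids`, `obsolete`.
#' @export
go_ontology <- function(classes, edges, namespace,
                        name = setNames(classes, classes),
                        alt_ids = character(0), obsolete = character(0)) {
  classes <- sort(unique(as.character(classes)))
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  dangling <- setdiff(unique(c(edges$child, edges$parent)), classes)
  if (length(dangling) > 0L)
    stop("ontology edges reference undefined class(es): ",
         paste(dangling, collapse = ", "))
  cyc <- .find_cycle_members(classes, edges)
  if (length(cyc) > 0L)
    stop("ontology contains a cycle involving: ", paste(cyc, collapse = ", "))
  if (is.null(names(namespace)) || !all(classes %in% names(namespace)))
    stop("namespace must be a named vector covering every class")
  namespace <- namespace[classes]
  if (!all(names(name) %in% c(classes, obsolete)))
    name <- name[intersect(names(name), classes)]
  bad_alt <- setdiff(unname(alt_ids), classes)
  if (length(bad_alt) > 0L)
    stop("alt_ids map to unknown class(es): ", paste(bad_alt, collapse = ", "))

  # root = class with no parent in its own namespace
  has_parent <- rep(FALSE, length(classes))
  names(has_parent) <- classes
  same_ns <- namespace[edges$child] == namespace[edges$parent]
  has_parent[unique(edges$child[same_ns])] <- TRUE
  root_ids <- classes[!has_parent]
  roots <- setNames(root_ids, namespace[root_ids])

  structure(list(classes = classes, edges = edges, namespace = namespace,
                 name = name, roots = roots, alt_ids = alt_ids,
                 obsolete = sort(unique(obsolete))),
            class = "go_ontology")
}

# Kahn peeling on child->parent edges; returns ids on a cycle (empty if DAG).
.find_cycle_members <- function(classes, edges) {
  out_deg <- table(factor(edges$child, levels = classes))
  in_edges <- split(seq_len(nrow(edges)), edges$parent)
  deg <- as.integer(out_deg)
  names(deg) <- classes
  queue <- classes[deg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (i in in_edges[[v]]) {
      ch <- edges$child[i]
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(classes)) character(0) else sort(names(deg)[deg > 0L])
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("Ontology DAG: ", length(x$classes), " classes, ",
      nrow(x$edges), " edges, ",
      length(unique(x$namespace)), " namespace(s)\n", sep = "")
  cat("Roots:", paste(sprintf("%s (%s)", x$roots, names(x$roots)),
                      collapse = ", "), "\n")
  if (length(x$obsolete) > 0L)
    cat("Obsolete terms:", length(x$obsolete), "\n")
  invisible(x)
}

#' Parse an OBO 1.2 flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas. `is_a:` lines become edges with relation
#' `"is_a"`; `relationship: part_of` lines become `"part_of"` edges.
#' Obsolete terms are recorded but excluded from the class set; `alt_id:`
#' lines populate the alias map. The parser rejects cyclic ontologies
#' (naming the classes on the cycle) and edges to undefined terms.
#'
#' @param input path to an OBO file, or a character vector of OBO lines.
#' @return A [go_ontology()] object.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process",
#'          "", "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' g <- parse_obo(obo)
#' g$roots
#' @export
parse_obo <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else as.character(input)
  lines <- sub("\\s+$", "", lines)

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() if (!is.null(cur)) terms[[length(terms) + 1L]] <<- cur
  for (ln in lines) {
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, is_a = character(0),
                  part_of = character(0), alt_id = character(0),
                  obsolete = FALSE)
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !grepl(":", ln, fixed = TRUE)) next
    key <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)          # strip trailing ! comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of")
        cur$part_of <- c(cur$part_of, parts[[2L]])
    }
  }
  flush()
  if (length(terms) == 0L) stop("no [Term] stanzas found")
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyNA(ids)) stop("a [Term] stanza lacks an id")
  obsolete <- ids[vapply(terms, `[[`, logical(1), "obsolete")]
  live <- terms[!vapply(terms, `[[`, logical(1), "obsolete")]
  classes <- vapply(live, `[[`, character(1), "id")
  if (anyDuplicated(classes))
    stop("duplicate term id(s): ",
         paste(unique(classes[duplicated(classes)]), collapse = ", "))
  ns <- vapply(live, `[[`, character(1), "namespace")
  ns[is.na(ns)] <- "default"
  nm <- vapply(live, `[[`, character(1), "name")
  nm[is.na(nm)] <- classes[is.na(nm)]
  edges <- do.call(rbind, lapply(live, function(tm) {
    rbind(
      if (length(tm$is_a)) data.frame(child = tm$id, parent = tm$is_a,
                                      relation = "is_a"),
      if (length(tm$part_of)) data.frame(child = tm$id, parent = tm$part_of,
                                         relation = "part_of"))
  }))
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  alt <- unlist(lapply(live, function(tm)
    setNames(rep(tm$id, length(tm$alt_id)), tm$alt_id)))
  if (is.null(alt)) alt <- character(0)
  go_ontology(classes, edges, setNames(ns, classes), setNames(nm, classes),
              alt_ids = alt, obsolete = obsolete)
}

#' Resolve class identifiers against an ontology
#'
#' Maps alternative identifiers to their canonical class. Unknown
#' identifiers raise an error naming the offender; obsolete identifiers can
#' optionally be dropped with a warning instead.
#'
#' @param graph a `go_ontology`.
#' @param ids character vector of class identifiers.
#' @param drop_obsolete drop (with a warning) ids in the obsolete set.
#' @return character vector of canonical identifiers.
#' @export
go_resolve <- function(graph, ids, drop_obsolete = TRUE) {
  ids <- as.character(ids)
  hit_alt <- ids %in% names(graph$alt_ids)
  ids[hit_alt] <- unname(graph$alt_ids[ids[hit_alt]])
  if (drop_obsolete && any(ids %in% graph$obsolete)) {
    warning("dropping obsolete class(es): ",
            paste(unique(ids[ids %in% graph$obsolete]), collapse = ", "))
    ids <- ids[!ids %in% graph$obsolete]
  }
  unknown <- setdiff(ids, graph$classes)
  if (length(unknown) > 0L)
    stop("unknown class identifier(s): ", paste(unknown, collapse = ", "))
  ids
}

.adjacency <- function(graph, relations, direction = c("up", "down")) {
  direction <- match.arg(direction)
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (direction == "up") split(e$parent, factor(e$child, levels = graph$classes))
  else split(e$child, factor(e$parent, levels = graph$classes))
}

#' Transitive closure over the ontology DAG
#'
#' All ancestors (`direction = "up"`) or descendants (`"down"`) of a seed
#' class reachable over the chosen relation labels; the seed itself is
#' excluded.
#'
#' @inheritParams go_resolve
#' @param seed a single class identifier.
#' @param direction `"up"` for ancestors, `"down"` for descendants.
#' @param relations relation labels to traverse (default is_a + part_of).
#' @return sorted character vector of reachable classes.
#' @export
closure <- function(graph, seed, direction = c("up", "down"),
                    relations = go_default_relations) {
  direction <- match.arg(direction)
  seed <- go_resolve(graph, seed, drop_obsolete = FALSE)
  adj <- .adjacency(graph, relations, direction)
  seen <- character(0)
  frontier <- seed
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, seed))
}

# Ancestor sets for every class, computed bottom-up in topological order.
.all_ancestors <- function(graph, relations = go_default_relations) {
  adj <- .adjacency(graph, relations, "up")
  order <- .topo_order(graph, relations)      # parents before children
  anc <- setNames(vector("list", length(graph$classes)), graph$classes)
  for (cls in order) {
    ps <- adj[[cls]]
    anc[[cls]] <- if (length(ps) == 0L) character(0) else
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

# Topological order with parents before children (Kahn on parent->child).
.topo_order <- function(graph, relations = go_default_relations) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  deg <- table(factor(e$child, levels = graph$classes))
  deg <- setNames(as.integer(deg), graph$classes)
  children <- split(e$child, factor(e$parent, levels = graph$classes))
  queue <- sort(graph$classes[deg == 0L])
  out <- character(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Filter annotation records by evidence code
#'
#' Keeps exactly the records whose evidence code is in the accepted set
#' (defaults to the 13 experimental codes), preserving input order.
#'
#' @param records data.frame with columns `protein`, `class`, `evidence`.
#' @param accepted character vector of accepted codes.
#' @return the filtered data.frame.
#' @export
filter_experimental <- function(records, accepted = go_experimental_codes) {
  stopifnot(all(c("protein", "class", "evidence") %in% names(records)))
  if (any(!nzchar(records$evidence)))
    stop("empty evidence code in annotation records")
  records[records$evidence %in% accepted, , drop = FALSE]
}

#' Read protein-to-GO annotation records (GAF 2.x or 3-column TSV)
#'
#' GAF is detected by `!` comment headers or a column count of 15 or more
#' (protein = column 2, class = column 5, evidence = column 7). Otherwise a
#' plain TSV with columns protein, class, evidence is assumed (a header row
#' is skipped when its first field is not a data-like identifier).
#'
#' @param input path to a file, or a character vector of lines.
#' @return data.frame with columns `protein`, `class`, `evidence`.
#' @export
read_annotations <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else as.character(input)
  lines <- lines[nzchar(lines)]
  is_gaf <- any(grepl("^!", lines))
  body <- lines[!grepl("^!", lines)]
  if (length(body) == 0L)
    return(data.frame(protein = character(0), class = character(0),
                      evidence = character(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  if (!is_gaf) is_gaf <- ncol1 >= 15L
  if (is_gaf) {
    bad <- which(vapply(fields, length, integer(1)) < 7L)
    if (length(bad) > 0L)
      stop("GAF row with fewer than 7 columns at line ", bad[[1L]])
    df <- data.frame(protein = vapply(fields, `[[`, character(1), 2L),
                     class = vapply(fields, `[[`, character(1), 5L),
                     evidence = vapply(fields, `[[`, character(1), 7L))
  } else {
    if (ncol1 < 3L) stop("annotation TSV needs 3 columns: protein, class, evidence")
    if (tolower(fields[[1L]][[1L]]) %in% c("protein", "protein_id", "id"))
      fields <- fields[-1L]
    df <- data.frame(protein = vapply(fields, `[[`, character(1), 1L),
                     class = vapply(fields, `[[`, character(1), 2L),
                     evidence = vapply(fields, `[[`, character(1), 3L))
  }
  df
}

#' Propagate annotations upward (true path rule)
#'
#' Closes each protein's class set under the ancestor relation: a protein
#' annotated with a class carries every ancestor of that class. The
#' operation is idempotent. Alternative ids are resolved; obsolete classes
#' are dropped with a warning.
#'
#' @param graph a `go_ontology`.
#' @param raw named list: protein id -> character vector of classes.
#' @param relations relation labels used for propagation.
#' @return A `go_corpus` object: list with `annotations` (named list of
#'   propagated, sorted class sets) and `proteins` (ordered ids).
#' @export
propagate_annotations <- function(graph, raw,
                                  relations = go_default_relations) {
  if (is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("raw annotations must be a named list keyed by protein id")
  anc <- .all_ancestors(graph, relations)
  annotations <- lapply(seq_along(raw), function(i) {
    cls <- tryCatch(go_resolve(graph, raw[[i]]),
                    error = function(e) stop("protein ", names(raw)[[i]], ": ",
                                             conditionMessage(e), call. = FALSE))
    sort(unique(c(cls, unlist(anc[cls], use.names = FALSE))))
  })
  names(annotations) <- names(raw)
  structure(list(annotations = annotations, proteins = names(raw)),
            class = "go_corpus")
}

#' @export
print.go_corpus <- function(x, ...) {
  sizes <- lengths(x$annotations)
  cat("Annotation corpus: ", length(x$proteins), " proteins, ",
      length(unique(unlist(x$annotations, use.names = FALSE))),
      " distinct classes (", round(mean(sizes), 1),
      " classes/protein on average)\n", sep = "")
  invisible(x)
}

# protein counts per class over a propagated corpus
.class_counts <- function(corpus) {
  tab <- table(unlist(corpus$annotations, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Select the prediction vocabulary
#'
#' Classes annotated (after propagation) to at least `min_count` proteins,
#' in lexicographic order. The production-scale convention is a cutoff of
#' 50 proteins; toy corpora use smaller values.
#'
#' @param corpus a propagated `go_corpus`.
#' @param min_count minimum number of annotated proteins (>= 1).
#' @param exclude_roots drop namespace roots from the vocabulary.
#' @param graph the companion ontology; required when `exclude_roots`.
#' @return character vector vocabulary.
#' @export
select_terms <- function(corpus, min_count = 50L, exclude_roots = FALSE,
                         graph = NULL) {
  stopifnot(min_count >= 1L)
  counts <- .class_counts(corpus)
  vocab <- sort(names(counts)[counts >= min_count])
  if (exclude_roots) {
    if (is.null(graph)) stop("exclude_roots requires the ontology graph")
    vocab <- setdiff(vocab, unname(graph$roots))
  }
  vocab
}

#' Information content of ontology classes
#'
#' Estimates, for each class c, the annotation probability conditional on
#' its parents, Pr(c | parents of c), as N(c) / N(parents), where N(c)
#' counts corpus proteins annotated with c and N(parents) counts proteins
#' annotated with every parent of c (the corpus size for roots). The
#' information content is -log of that probability (base 2 by default, so
#' units are bits). Classes with undefined estimates (zero numerator or
#' denominator) fall back to the maximum observed IC.
#'
#' @param graph a `go_ontology`.
#' @param corpus a propagated, non-empty `go_corpus`.
#' @param log_base 2 (bits) or `exp(1)` (nats).
#' @param relations relation labels defining parenthood.
#' @return A `go_ic` object: list with `ic` (named numeric, >= 0),
#'   `log_base`, and `counts` (named integer protein counts).
#' @export
information_content <- function(graph, corpus, log_base = 2,
                                relations = go_default_relations) {
  if (length(corpus$proteins) == 0L) stop("empty annotation corpus")
  n <- length(corpus$proteins)
  counts <- .class_counts(corpus)
  full <- setNames(integer(length(graph$classes)), graph$classes)
  full[names(counts)] <- counts
  adj <- .adjacency(graph, relations, "up")
  ic <- setNames(numeric(length(graph$classes)), graph$classes)
  undefined <- character(0)
  for (cls in graph$classes) {
    ps <- adj[[cls]]
    n_parent <- if (length(ps) == 0L) n else {
      # proteins annotated with every parent
      sum(vapply(corpus$annotations, function(a) all(ps %in% a), logical(1)))
    }
    if (full[[cls]] == 0L || n_parent == 0L) {
      undefined <- c(undefined, cls)
      ic[[cls]] <- NA_real_
    } else {
      ic[[cls]] <- -log(full[[cls]] / n_parent) / log(log_base)
    }
  }
  if (length(undefined) > 0L) {
    mx <- if (all(is.na(ic))) 0 else max(ic, na.rm = TRUE)
    ic[undefined] <- mx
    message("information_content: ", length(undefined),
            " class(es) without a defined estimate assigned the maximum ",
            "observed IC (", format(mx, digits = 4), ")")
  }
  ic[ic < 0 & ic > -1e-12] <- 0            # guard tiny negative rounding
  structure(list(ic = ic, log_base = log_base, counts = full),
            class = "go_ic")
}

#' @export
print.go_ic <- function(x, ...) {
  cat("Information content for ", length(x$ic), " classes (log base ",
      format(x$log_base), "): range [",
      format(min(x$ic), digits = 4), ", ",
      format(max(x$ic), digits = 4), "]\n", sep = "")
  invisible(x)
}
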