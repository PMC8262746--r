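#' Configuration for the multi-kernel convolutional classifier
#'
#' The architecture mirrors the multi-kernel design used for large-scale GO
#' prediction: one 1D convolutional layer per kernel size (default sizes 8,
#' 16, 24, ..., 128, i.e. 16 layers), each with `n_filters` filters, global
#' max pooling per filter (the pooled value indicates whether a filter was
#' active anywhere along the sequence), concatenation of all pooled
#' vectors, and a single fully connected sigmoid output layer of width
#' |vocabulary|.
#'
#' @param vocabulary ordered character vector of classes to predict.
#' @param kernel_sizes strictly increasing integer kernel widths, each
#'   `<= max_len` (default `seq(8, 128, by = 8)`).
#' @param n_filters filters per convolutional layer (default 512).
#' @param max_len encoded sequence length (default 2000).
#' @param alphabet residue alphabet used for encoding.
#' @param activation `"linear"` convolutions (the pooled maximum is the
#'   activity signal) or `"relu"`.
#' @param epochs,batch_size,learning_rate,validation_split,patience
#'   training hyperparameters; `patience` is early-stopping patience in
#'   epochs on the validation loss (`Inf` disables early stopping).
#' @param seed integer seed controlling initialisation and data shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(vocabulary,
                       kernel_sizes = seq(8L, 128L, by = 8L),
                       n_filters = 512L,
                       max_len = 2000L,
                       alphabet = protein_alphabet,
                       activation = c("linear", "relu"),
                       epochs = 30L, batch_size = 32L,
                       learning_rate = 1e-3,
                       validation_split = 0.1, patience = 5L,
                       seed = 1L) {
  activation <- match.arg(activation)
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) == 0L) stop("vocabulary must be nonempty")
  if (anyDuplicated(vocabulary)) stop("vocabulary contains duplicates")
  kernel_sizes <- as.integer(kernel_sizes)
  if (any(diff(kernel_sizes) <= 0L))
    stop("kernel sizes must be strictly increasing")
  if (any(kernel_sizes > max_len))
    stop("kernel size ", max(kernel_sizes), " exceeds max_len ", max_len)
  stopifnot(n_filters >= 1L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, validation_split >= 0, validation_split < 1)
  structure(list(vocabulary = vocabulary, kernel_sizes = kernel_sizes,
                 n_filters = as.integer(n_filters),
                 max_len = as.integer(max_len), alphabet = alphabet,
                 activation = activation, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_split = validation_split,
                 patience = patience, seed = as.integer(seed)),
            class = "cnn_config")
}

.feature_dim <- function(config) length(config$kernel_sizes) * config$n_filters

#' Build an untrained convolutional model
#'
#' Initialises parameters (scaled Gaussian weights, zero biases) from the
#' config's seed; two builds from the same config are identical.
#'
#' @param config a [cnn_config()].
#' @return A `go_cnn` object (untrained).
#' @export
go_cnn_build <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  A <- length(config$alphabet)
  set.seed(config$seed)
  Ws <- lapply(config$kernel_sizes, function(k) {
    array(rnorm(config$n_filters * A * k, sd = sqrt(1 / (A * k))),
          dim = c(config$n_filters, A, k))
  })
  bs <- lapply(config$kernel_sizes, function(k) numeric(config$n_filters))
  D <- .feature_dim(config)
  C <- length(config$vocabulary)
  V <- matrix(rnorm(D * C, sd = sqrt(1 / D)), nrow = D, ncol = C)
  cvec <- numeric(C)
  structure(list(params = list(Ws = Ws, bs = bs, V = V, c = cvec),
                 config = config, history = NULL, trained = FALSE),
            class = "go_cnn")
}

.as_index_list <- function(batch, config) {
  if (!inherits(batch, "encoded_batch"))
    stop("batch must be an encoded_batch (see encode_batch)")
  if (!identical(batch$alphabet, config$alphabet) ||
      batch$max_len != config$max_len)
    stop("batch encoding (alphabet/max_len) does not match the model config")
  batch$index
}

.cnn_features <- function(params, index, config) {
  fwd <- cnn_conv_forward(index, params$Ws, params$bs, config$max_len)
  H <- fwd$pooled
  if (config$activation == "relu") H <- pmax(H, 0)
  list(H = H, argmax = fwd$argmax, raw = fwd$pooled)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

.cnn_forward_scores <- function(params, index, config) {
  ft <- .cnn_features(params, index, config)
  z <- ft$H %*% params$V
  z <- sweep(z, 2L, params$c, "+")
  list(p = .sigmoid(z), ft = ft)
}

# One Adam step over a flat list of parameter arrays.
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

.flatten_params <- function(p) {
  out <- list(V = p$V, c = p$c)
  for (i in seq_along(p$Ws)) {
    out[[paste0("W", i)]] <- p$Ws[[i]]
    out[[paste0("b", i)]] <- p$bs[[i]]
  }
  out
}

.unflatten_params <- function(flat, n_kernels) {
  list(Ws = lapply(seq_len(n_kernels), function(i) flat[[paste0("W", i)]]),
       bs = lapply(seq_len(n_kernels), function(i) flat[[paste0("b", i)]]),
       V = flat$V, c = flat$c)
}

#' Fit the multi-kernel convolutional GO classifier
#'
#' Builds the model from `config` and trains it by minimising per-class
#' binary cross-entropy with the Adam optimiser on mini-batches. A seeded
#' validation split monitors generalisation; the parameters from the epoch
#' with the lowest validation loss are kept (early stopping after
#' `patience` epochs without improvement). With `validation_split = 0` the
#' training loss is monitored instead. Fully deterministic given the
#' config seed.
#'
#' @param batch an [encode_batch()] of training sequences.
#' @param labels binary matrix, rows aligned with `batch`, columns aligned
#'   with `config$vocabulary`; labels must already be propagated so that a
#'   class implies its ancestors.
#' @param config a [cnn_config()].
#' @return A trained `go_cnn` object with a `history` data.frame of
#'   per-epoch training and validation losses.
#' @seealso [predict.go_cnn()], [go_cnn_save()], [go_cnn_load()]
#' @export
go_cnn <- function(batch, labels, config) {
  model <- go_cnn_build(config)
  index <- .as_index_list(batch, config)
  labels <- as.matrix(labels)
  if (nrow(labels) != length(index))
    stop("label matrix rows (", nrow(labels),
         ") do not match batch size (", length(index), ")")
  if (ncol(labels) != length(config$vocabulary))
    stop("label matrix columns (", ncol(labels),
         ") do not match vocabulary size (", length(config$vocabulary), ")")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")

  n <- length(index)
  set.seed(config$seed)
  perm <- sample.int(n)
  n_val <- floor(config$validation_split * n)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)

  params <- .flatten_params(model$params)
  # initialise output bias at the label prior log-odds (speeds convergence
  # for sparse multi-label targets)
  prior <- pmin(pmax(colMeans(labels[tr_idx, , drop = FALSE]), 1e-3), 1 - 1e-3)
  params$c <- log(prior / (1 - prior))
  state <- list(t = 0L,
                m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  nk <- length(config$kernel_sizes)
  C <- length(config$vocabulary)

  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  eval_loss <- function(params, idx) {
    if (length(idx) == 0L) return(NA_real_)
    p <- .cnn_forward_scores(.unflatten_params(params, nk),
                             index[idx], config)$p
    .bce(p, labels[idx, , drop = FALSE])
  }

  for (epoch in seq_len(config$epochs)) {
    order_i <- sample(tr_idx)
    batches <- split(order_i, ceiling(seq_along(order_i) / config$batch_size))
    epoch_loss <- 0
    for (bi in batches) {
      pr <- .unflatten_params(params, nk)
      fwd <- .cnn_forward_scores(pr, index[bi], config)
      y <- labels[bi, , drop = FALSE]
      p <- fwd$p
      epoch_loss <- epoch_loss + .bce(p, y) * length(bi)
      dZ <- (p - y) / (length(bi) * C)
      H <- fwd$ft$H
      grads <- list(V = crossprod(H, dZ), c = colSums(dZ))
      dH <- dZ %*% t(pr$V)
      if (config$activation == "relu") dH[fwd$ft$raw <= 0] <- 0
      bwd <- cnn_conv_backward(index[bi], pr$Ws, fwd$ft$argmax, dH,
                               config$max_len)
      for (i in seq_len(nk)) {
        grads[[paste0("W", i)]] <- bwd$dW[[i]]
        grads[[paste0("b", i)]] <- bwd$dB[[i]]
      }
      st <- .adam_step(params, grads, state, config$learning_rate)
      params <- st$params
      state <- st$state
    }
    train_loss <- epoch_loss / length(tr_idx)
    val_loss <- eval_loss(params, val_idx)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    monitor <- if (is.na(val_loss)) train_loss else val_loss
    if (monitor < best_loss - 1e-9) {
      best_loss <- monitor
      best_params <- params
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (is.finite(config$patience) && stall >= config$patience) break
    }
  }

  model$params <- .unflatten_params(best_params, nk)
  model$history <- history
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Predict class scores for encoded sequences
#'
#' @param object a `go_cnn` model.
#' @param batch an [encode_batch()] produced with the model's alphabet and
#'   `max_len`.
#' @param ... unused.
#' @return numeric matrix (sequences x vocabulary) of sigmoid scores,
#'   each strictly in (0, 1); rownames are the batch ids.
#' @export
predict.go_cnn <- function(object, batch, ...) {
  index <- .as_index_list(batch, object$config)
  p <- .cnn_forward_scores(object$params, index, object$config)$p
  dimnames(p) <- list(batch$ids, object$config$vocabulary)
  p
}

#' @export
print.go_cnn <- function(x, ...) {
  cfg <- x$config
  cat("Multi-kernel 1D CNN protein function classifier\n")
  cat("  kernels: {", paste(cfg$kernel_sizes, collapse = ", "), "} x ",
      cfg$n_filters, " filters (pooled feature length ",
      .feature_dim(cfg), ")\n", sep = "")
  cat("  input: ", cfg$max_len, " positions x ", length(cfg$alphabet),
      " symbols; output: ", length(cfg$vocabulary),
      " classes (sigmoid)\n", sep = "")
  cat("  ", if (isTRUE(x$trained))
    paste0("trained, best epoch ", x$best_epoch, " of ",
           nrow(x$history), " run")
    else "untrained", "\n", sep = "")
  invisible(x)
}

#' @export
summary.go_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat("Training history (last 5 epochs):\n")
    print(tail(h, 5L), row.names = FALSE)
  }
  n_par <- sum(vapply(.flatten_params(object$params), length, numeric(1)))
  cat("Parameters:", format(n_par, big.mark = ","), "\n")
  invisible(object)
}

#' @export
coef.go_cnn <- function(object, ...) object$params

#' Save / load a trained model checkpoint
#'
#' The checkpoint directory contains `params.rds` (numeric parameters),
#' `config.yaml` (architecture and training configuration) and
#' `vocabulary.txt` (one class per line). Loading verifies that the stored
#' parameter shapes agree with the config; predictions from a reloaded
#' model are bit-identical to the original.
#'
#' @param model a `go_cnn`.
#' @param dir checkpoint directory (created if absent).
#' @return `dir` (save) or the reloaded `go_cnn` (load).
#' @export
go_cnn_save <- function(model, dir) {
  stopifnot(inherits(model, "go_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg_list <- unclass(cfg)
  cfg_list$vocabulary <- NULL
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  writeLines(cfg$vocabulary, file.path(dir, "vocabulary.txt"))
  saveRDS(list(params = model$params, history = model$history,
               best_epoch = model$best_epoch, trained = model$trained),
          file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname go_cnn_save
#' @export
go_cnn_load <- function(dir) {
  for (f in c("config.yaml", "vocabulary.txt", "params.rds"))
    if (!file.exists(file.path(dir, f)))
      stop("checkpoint is missing file: ", f)
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  config <- cnn_config(vocabulary = vocab,
                       kernel_sizes = cfg_list$kernel_sizes,
                       n_filters = cfg_list$n_filters,
                       max_len = cfg_list$max_len,
                       alphabet = cfg_list$alphabet,
                       activation = cfg_list$activation,
                       epochs = cfg_list$epochs,
                       batch_size = cfg_list$batch_size,
                       learning_rate = cfg_list$learning_rate,
                       validation_split = cfg_list$validation_split,
                       patience = cfg_list$patience,
                       seed = cfg_list$seed)
  stored <- readRDS(file.path(dir, "params.rds"))
  p <- stored$params
  A <- length(config$alphabet)
  ok <- length(p$Ws) == length(config$kernel_sizes) &&
    all(vapply(seq_along(p$Ws), function(i)
      identical(dim(p$Ws[[i]]),
                c(config$n_filters, A, config$kernel_sizes[[i]])),
      logical(1))) &&
    identical(dim(p$V), c(.feature_dim(config), length(config$vocabulary)))
  if (!ok)
    stop("checkpoint integrity error: parameter shapes disagree with config.yaml")
  structure(list(params = p, config = config, history = stored$history,
                 best_epoch = stored$best_epoch, trained = stored$trained),
            class = "go_cnn")
}

#' Binary label matrix for a protein set over a vocabulary
#'
#' @param corpus a propagated `go_corpus`.
#' @param proteins protein ids (rows, in order).
#' @param vocabulary class ids (columns, in order).
#' @return binary matrix with dimnames (proteins, vocabulary).
#' @export
label_matrix <- function(corpus, proteins, vocabulary) {
  bad <- setdiff(proteins, corpus$proteins)
  if (length(bad) > 0L)
    stop("proteins absent from corpus: ", paste(head(bad, 5L), collapse = ", "))
  mat <- matrix(0, nrow = length(proteins), ncol = length(vocabulary),
                dimnames = list(proteins, vocabulary))
  for (i in seq_along(proteins)) {
    hit <- intersect(corpus$annotations[[proteins[[i]]]], vocabulary)
    if (length(hit) > 0L) mat[i, hit] <- 1
  }
  mat
}
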