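# Training loop: Adam over hand-derived gradients, shuffled mini-batches,
# per-epoch dev evaluation with best-F checkpointing and early stopping.

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(upd, p, g, m, v)
      list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
           v = lapply(r, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(r, `[[`, "p"),
       state = list(m = lapply(r, `[[`, "m"),
                    v = lapply(r, `[[`, "v"), t = t))
}

batch_slice <- function(batch, idx) {
  structure(
    list(ids_a = batch$ids_a[idx, , drop = FALSE],
         ids_b = batch$ids_b[idx, , drop = FALSE],
         mask_a = batch$mask_a[idx, , drop = FALSE],
         mask_b = batch$mask_b[idx, , drop = FALSE],
         lengths_a = batch$lengths_a[idx], lengths_b = batch$lengths_b[idx],
         labels = batch$labels[idx], n = batch$n),
    class = "tokenized_batch"
  )
}

# Probabilities for an encoded batch in inference mode, chunked to bound
# memory.
predict_probs <- function(params, batch, config, chunk = 128L) {
  B <- nrow(batch$ids_a)
  out <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    out[idx] <- capstm_forward(params, batch_slice(batch, idx), config)$prob
  }
  out
}

#' Train the capsule-network matcher
#'
#' Runs Adam (learning rate and batch size from the configuration) over
#' shuffled mini-batches of the training pairs. After every epoch the dev
#' set is scored at threshold 0.5; the parameters with the highest dev
#' F-score are retained (ties resolved to the earliest epoch). Training
#' stops at `max_epochs` or once `patience` consecutive epochs bring no
#' dev-F improvement (`patience = 0` trains for exactly one epoch). The run
#' is fully reproducible from `config$seed`.
#'
#' @param train,dev Tibbles of labeled pairs (`text_a`, `text_b`, `label`).
#' @param config A [capstm_config()].
#' @param vectors Optional path to pretrained vectors in word2vec text
#'   format (see [read_word_vectors()]); absent tokens get seeded random
#'   rows.
#' @param verbose Print one line of loss / dev metrics per epoch.
#' @return A fitted `capstm_model`: best parameters, config, vocabulary and
#'   a `history` tibble (`epoch`, `train_loss`, `dev_precision`,
#'   `dev_recall`, `dev_f`). Supports [predict()][predict.capstm_model],
#'   [tidy()][tidy.capstm_model], [glance()][glance.capstm_model] and
#'   [autoplot()][autoplot.capstm_model].
#' @export
capstm_fit <- function(train, dev, config = capstm_config(), vectors = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "capstm_config"))
  if (nrow(train) == 0L || nrow(dev) == 0L) {
    stop("empty train or dev split", call. = FALSE)
  }
  if (anyNA(train$label) || anyNA(dev$label)) {
    stop("train and dev pairs must be labeled", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  vocab <- build_vocab(train, mode = config$tokenizer)
  embeddings <- if (!is.null(vectors)) {
    read_word_vectors(vectors, vocab, config$embedding_size,
                      seed = config$seed)
  }
  params <- capstm_init_params(config, length(vocab), embeddings)
  enc_train <- encode_batch(train, vocab, config$max_len)
  enc_dev <- encode_batch(dev, vocab, config$max_len)
  state <- adam_init(params)
  n_train <- nrow(train)
  best <- list(f = -Inf, epoch = 0L, params = params)
  since_best <- 0L
  history <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    losses <- c()
    for (start in seq(1L, n_train, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
      mb <- batch_slice(enc_train, idx)
      fwd <- capstm_forward(params, mb, config, training = TRUE,
                            keep_cache = TRUE)
      losses <- c(losses, bce_loss(fwd$prob, mb$labels))
      grads <- capstm_backward(params, mb, config, fwd,
                               bce_dlogit(fwd$prob, mb$labels))
      au <- adam_update(params, grads, state, config$learning_rate)
      params <- au$params
      params$emb[1L, ] <- 0 # keep the padding row inert
      state <- au$state
    }
    dev_prob <- predict_probs(params, enc_dev, config)
    m <- match_metrics(enc_dev$labels, as.integer(dev_prob >= 0.5))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses),
      dev_precision = m$precision, dev_recall = m$recall, dev_f = m$f_score
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  dev P %.3f R %.3f F %.3f",
                      epoch, mean(losses), m$precision, m$recall, m$f_score))
    }
    if (m$f_score > best$f) {
      best <- list(f = m$f_score, epoch = epoch, params = params)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= config$patience) break
  }
  history <- dplyr::bind_rows(history)
  structure(
    list(params = best$params, config = config, vocab = vocab,
         history = history, best_epoch = best$epoch,
         dev_f = best$f, seed = config$seed),
    class = "capstm_model"
  )
}

#' @export
print.capstm_model <- function(x, ...) {
  cat(sprintf(
    "<capstm_model> preset %s | %d epochs trained, best epoch %d (dev F %.3f)\n",
    x$config$preset, nrow(x$history), x$best_epoch, x$dev_f
  ))
  invisible(x)
}

#' Predict match probabilities for new question pairs
#'
#' @param object A fitted `capstm_model`.
#' @param newdata Tibble with `text_a`, `text_b` (labels, if present, are
#'   carried through untouched).
#' @param ... Unused.
#' @return `newdata` with columns `probability` (match probability in
#'   (0, 1)) and `label_pred` (1 iff probability >= 0.5) appended.
#' @export
predict.capstm_model <- function(object, newdata, ...) {
  enc <- encode_batch(newdata, object$vocab, object$config$max_len)
  prob <- predict_probs(object$params, enc, object$config)
  dplyr::mutate(tibble::as_tibble(newdata),
                probability = prob,
                label_pred = as.integer(prob >= 0.5))
}

#' Evaluate a fitted model on labeled pairs
#'
#' Scores predictions at threshold 0.5 and returns precision, recall and
#' F-score over the positive class together with the confusion counts.
#'
#' @param model A fitted `capstm_model`.
#' @param data Tibble of labeled pairs.
#' @return One-row tibble, see [match_metrics()].
#' @export
capstm_evaluate <- function(model, data) {
  if (!"label" %in% names(data) || anyNA(data$label)) {
    stop("capstm_evaluate requires labeled data", call. = FALSE)
  }
  pred <- predict(model, data)
  match_metrics(data$label, pred$label_pred)
}

# ---- checkpointing ------------------------------------------------------

# Rolling polynomial hash (mod 2^31 - 1, exact in double arithmetic) of a
# character vector; binds checkpoints to the vocabulary they were trained
# with.
content_hash <- function(x) {
  cps <- utf8ToInt(paste(x, collapse = "\u0001"))
  h <- 17
  for (b in cps) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save / load a fitted model
#'
#' Writes the parameters (`params.json`), and a sidecar `meta.json` holding
#' the configuration, vocabulary, training history and a vocabulary hash.
#' `capstm_load()` verifies the hash and errors on mismatch. Everything is
#' plain JSON text.
#'
#' @param model A fitted `capstm_model`.
#' @param dir Checkpoint directory (created if needed).
#' @export
capstm_save <- function(model, dir) {
  stopifnot(inherits(model, "capstm_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- function(x) {
    if (is.list(x)) lapply(x, ser)
    else if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = length(x), data = as.vector(x))
  }
  jsonlite::write_json(ser(model$params), file.path(dir, "params.json"),
                       digits = NA, auto_unbox = FALSE)
  tokens <- attr(model$vocab, "tokens")
  meta <- list(
    config = unclass(model$config),
    vocab_tokens = tokens,
    vocab_mode = attr(model$vocab, "mode"),
    vocab_hash = content_hash(tokens),
    history = model$history,
    best_epoch = model$best_epoch,
    dev_f = model$dev_f,
    seed = model$seed
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname capstm_save
#' @param dir Checkpoint directory written by `capstm_save()`.
#' @export
capstm_load <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (content_hash(meta$vocab_tokens) != meta$vocab_hash) {
    stop("checkpoint vocabulary hash mismatch", call. = FALSE)
  }
  raw <- jsonlite::read_json(file.path(dir, "params.json"),
                             simplifyVector = TRUE)
  deser <- function(x) {
    if (is.list(x) && !is.null(x$dim)) {
      if (length(x$dim) == 2L) matrix(x$data, x$dim[1L], x$dim[2L])
      else as.numeric(x$data)
    } else {
      lapply(x, deser)
    }
  }
  cfg_raw <- meta$config
  preset <- cfg_raw$preset
  cfg_raw$preset <- NULL
  config <- do.call(capstm_config, c(list(preset = preset), cfg_raw))
  idx <- seq_along(meta$vocab_tokens) - 1L
  names(idx) <- meta$vocab_tokens
  vocab <- structure(idx, tokens = meta$vocab_tokens,
                     mode = meta$vocab_mode, class = "capstm_vocab")
  structure(
    list(params = deser(raw), config = config, vocab = vocab,
         history = tibble::as_tibble(meta$history),
         best_epoch = meta$best_epoch, dev_f = meta$dev_f, seed = meta$seed),
    class = "capstm_model"
  )
}
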