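#' Model configuration
#'
#' Builds a validated configuration for the capsule-network matcher. Three
#' named presets are provided:
#'
#' * `"word2vec"` — the full-size configuration for 300-dimensional static
#'   word vectors: embedding size 300, BiLSTM hidden size 100 per direction,
#'   6 capsules of dimension 50, 3 routing iterations, learning rate 0.001,
#'   dropout 0.5, ReLU activation, batch size 32.
#' * `"contextual"` — the same architecture sized for 768-dimensional
#'   contextual token vectors: embedding size 768, hidden size 384,
#'   dropout 0.9, everything else as above.
#' * `"small"` — a reduced configuration for desk-scale experiments on
#'   synthetic corpora; trains in minutes on one CPU.
#'
#' Any field can be overridden through `...`. The convolutional front of the
#' capsule layer (kernel count `conv_channels`, width `conv_width`, per-channel
#' feature dimension `conv_dim`) has no canonical published size; the defaults
#' here are package choices.
#'
#' `dropout_rate` is the probability of *dropping* a unit (applied to
#' embeddings and to both BiLSTM outputs during training only).
#'
#' @param preset Character; one of `"small"`, `"word2vec"`, `"contextual"`.
#' @param ... Named overrides for any configuration field, e.g.
#'   `hidden_size = 16`, `use_attention = FALSE`, `capsule_mode = "max"`.
#' @return An object of class `capstm_config` (a validated named list).
#' @examples
#' capstm_config("small", routing_iters = 2)
#' @export
capstm_config <- function(preset = c("small", "word2vec", "contextual"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    word2vec = list(
      embedding_size = 300L, hidden_size = 100L, n_capsules = 6L,
      capsule_dim = 50L, routing_iters = 3L, learning_rate = 0.001,
      dropout_rate = 0.5, activation = "relu", batch_size = 32L,
      max_len = 50L, conv_channels = 16L, conv_width = 3L, conv_dim = 100L,
      head_hidden = 100L
    ),
    contextual = list(
      embedding_size = 768L, hidden_size = 384L, n_capsules = 6L,
      capsule_dim = 50L, routing_iters = 3L, learning_rate = 0.001,
      dropout_rate = 0.9, activation = "relu", batch_size = 32L,
      max_len = 50L, conv_channels = 16L, conv_width = 3L, conv_dim = 384L,
      head_hidden = 100L
    ),
    small = list(
      embedding_size = 32L, hidden_size = 32L, n_capsules = 4L,
      capsule_dim = 16L, routing_iters = 3L, learning_rate = 0.002,
      dropout_rate = 0.1, activation = "relu", batch_size = 32L,
      max_len = 16L, conv_channels = 8L, conv_width = 3L, conv_dim = 16L,
      head_hidden = 32L
    )
  )
  common <- list(
    preset = preset,
    norm_mode = "softmax",          # attention weight normalisation
    similarity_source = "embedding", # "embedding" (highway output) or "hidden"
    squash_variant = "printed",      # "printed" s/(1+|s|) or "standard"
    capsule_mode = "routing",        # "routing", "max", "mean"
    use_attention = TRUE,
    tokenizer = "char",
    train_embeddings = TRUE,
    max_epochs = 50L,
    patience = 5L,
    seed = 1L
  )
  cfg <- utils::modifyList(c(base, common), list(...))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_fields <- c(
    "embedding_size", "hidden_size", "n_capsules", "capsule_dim",
    "routing_iters", "batch_size", "max_len", "conv_channels",
    "conv_width", "conv_dim", "head_hidden", "max_epochs"
  )
  for (f in int_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("config field `", f, "` must be a positive integer", call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(cfg$patience) || cfg$patience < 0) {
    stop("config field `patience` must be a non-negative integer", call. = FALSE)
  }
  cfg$patience <- as.integer(cfg$patience)
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$conv_width %% 2L != 1L) {
    stop("conv_width must be odd (same-padding convolution)", call. = FALSE)
  }
  match_field <- function(f, choices) {
    if (!cfg[[f]] %in% choices) {
      stop("config field `", f, "` must be one of: ",
           paste(choices, collapse = ", "), call. = FALSE)
    }
  }
  match_field("norm_mode", c("softmax", "literal"))
  match_field("similarity_source", c("embedding", "hidden"))
  match_field("squash_variant", c("printed", "standard"))
  match_field("capsule_mode", c("routing", "max", "mean"))
  match_field("activation", c("relu", "tanh", "sigmoid"))
  match_field("tokenizer", c("char", "whitespace"))
  if (!is.logical(cfg$use_attention) || length(cfg$use_attention) != 1L) {
    stop("use_attention must be TRUE or FALSE", call. = FALSE)
  }
  structure(cfg, class = "capstm_config")
}

#' @export
print.capstm_config <- function(x, ...) {
  cat("<capstm_config> preset:", x$preset, "\n")
  cat(sprintf(
    "  E=%d H=%d J=%d d=%d T=%d | conv: I=%d w=%d dim=%d | attention=%s mode=%s\n",
    x$embedding_size, x$hidden_size, x$n_capsules, x$capsule_dim,
    x$routing_iters, x$conv_channels, x$conv_width, x$conv_dim,
    x$use_attention, x$capsule_mode
  ))
  cat(sprintf(
    "  lr=%g dropout=%g act=%s batch=%d max_len=%d squash=%s\n",
    x$learning_rate, x$dropout_rate, x$activation, x$batch_size,
    x$max_len, x$squash_variant
  ))
  invisible(x)
}

#' Ablation variants of a configuration
#'
#' Given a base configuration, returns the base plus the three ablations
#' studied with this architecture: dynamic routing replaced by max pooling,
#' by mean pooling, and the cross-question attention removed. Each derived
#' configuration differs from the base in exactly one field.
#'
#' @param config A `capstm_config`.
#' @return Named list of four `capstm_config` objects:
#'   `full`, `wo_routing_max`, `wo_routing_mean`, `wo_attention`.
#' @export
ablation_variants <- function(config) {
  stopifnot(inherits(config, "capstm_config"))
  tweak <- function(field, value) {
    cfg <- unclass(config)
    cfg[[field]] <- value
    validate_config(cfg)
  }
  list(
    full            = config,
    wo_routing_max  = tweak("capsule_mode", "max"),
    wo_routing_mean = tweak("capsule_mode", "mean"),
    wo_attention    = tweak("use_attention", FALSE)
  )
}

#' Read / write a configuration as YAML
#'
#' The YAML keys are exactly the `capstm_config` field names; two preset
#' files (`word2vec.yaml`, `contextual.yaml`) ship in
#' `system.file("extdata", package = "capstm")`.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `capstm_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "small"
  raw$preset <- NULL
  do.call(capstm_config, c(list(preset = preset), raw))
}

#' @rdname read_config
#' @param config A `capstm_config` to serialise.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "capstm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
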