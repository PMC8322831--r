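# Shared fixtures for model-level tests: a tiny smooth (tanh, no dropout)
# configuration so finite-difference checks are well behaved, and a
# finite-difference utility.

tiny_config <- function(...) {
  capstm_config("small",
    embedding_size = 5, hidden_size = 3, n_capsules = 2, capsule_dim = 3,
    routing_iters = 3, conv_channels = 2, conv_dim = 3, conv_width = 3,
    head_hidden = 4, max_len = 6, dropout_rate = 0, activation = "tanh",
    ...
  )
}

tiny_model <- function(config = tiny_config(), seed = 42) {
  wb <- make_worked_batch()
  set.seed(seed)
  params <- capstm:::capstm_init_params(config, length(wb$vocab))
  list(config = config, params = params, batch = wb$batch, vocab = wb$vocab)
}

# Central finite difference of scalar_fn at x (vector/matrix/array).
num_grad <- function(scalar_fn, x, eps = 1e-6, idx = seq_along(x)) {
  g <- x * 0
  for (i in idx) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (scalar_fn(x1) - scalar_fn(x2)) / (2 * eps)
  }
  g
}

# Small labeled corpus tibbles for training tests.
tiny_corpus <- function(n_pairs = 40, seed = 9, ...) {
  generate_corpus(synth_config(
    n_pairs = n_pairs,
    split = c(train = n_pairs - 8, dev = 4, test = 4),
    seed = seed, ...
  ))
}
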