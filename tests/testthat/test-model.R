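test_that("forward probabilities are strictly inside (0,1) and deterministic", {
  tm <- tiny_model()
  f1 <- capstm_forward(tm$params, tm$batch, tm$config)
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  f2 <- capstm_forward(tm$params, tm$batch, tm$config)
  expect_identical(f1$prob, f2$prob)
})

test_that("forward accepts any batch size and any length >= the kernel width", {
  tm <- tiny_model()
  one <- capstm:::batch_slice(tm$batch, 1L)
  expect_length(capstm_forward(tm$params, one, tm$config)$prob, 1L)
  pairs <- tibble::tibble(
    text_a = c("ab", "abcd", "abc"), text_b = c("ba", "dcba", "cab"),
    label = c(1L, 0L, 1L)
  )
  for (n in c(3L, 5L, 9L)) {
    enc <- encode_batch(pairs, tm$vocab, n)
    expect_length(capstm_forward(tm$params, enc, tm$config)$prob, 3L)
  }
})

test_that("appending padding to both questions never moves the probability", {
  tm <- tiny_model()
  base <- capstm_forward(tm$params, tm$batch, tm$config)$prob
  wb <- make_worked_batch()
  for (extra in c(2L, 7L)) {
    enc <- encode_batch(wb$pairs, tm$vocab, n = 6L + extra)
    prob <- capstm_forward(tm$params, enc, tm$config)$prob
    expect_lt(max(abs(prob - base)), 1e-6)
  }
})

test_that("every per-capsule block of the fusion input has norm below 1", {
  tm <- tiny_model()
  fwd <- capstm_forward(tm$params, tm$batch, tm$config, keep_cache = TRUE)
  J <- tm$config$n_capsules; d <- tm$config$capsule_dim
  for (cblock in list(fwd$cache$fs$cache$c1, fwd$cache$fs$cache$c2)) {
    caps <- array(cblock, c(nrow(cblock), J, d))
    norms <- sqrt(rowSums(caps^2, dims = 2L))
    expect_true(all(norms < 1))
  }
})

test_that("ablation variants differ from the base in exactly one field", {
  base <- capstm_config("word2vec")
  vars <- ablation_variants(base)
  expect_named(vars, c("full", "wo_routing_max", "wo_routing_mean",
                       "wo_attention"))
  expect_identical(vars$full, base)
  diff_fields <- function(a, b) {
    names(which(!mapply(identical, unclass(a), unclass(b))))
  }
  expect_equal(diff_fields(base, vars$wo_routing_max), "capsule_mode")
  expect_equal(diff_fields(base, vars$wo_routing_mean), "capsule_mode")
  expect_equal(diff_fields(base, vars$wo_attention), "use_attention")
  # the attention ablation still routes with the configured iterations
  expect_equal(vars$wo_attention$capsule_mode, "routing")
  expect_equal(vars$wo_attention$routing_iters, 3L)
})

test_that("the Table-3-style presets expose the published hyperparameters", {
  w2v <- capstm_config("word2vec")
  expect_equal(
    c(w2v$embedding_size, w2v$hidden_size, w2v$n_capsules, w2v$capsule_dim,
      w2v$routing_iters, w2v$batch_size),
    c(300L, 100L, 6L, 50L, 3L, 32L)
  )
  expect_equal(w2v$learning_rate, 0.001)
  expect_equal(w2v$dropout_rate, 0.5)
  expect_equal(w2v$activation, "relu")
  ctx <- capstm_config("contextual")
  expect_equal(c(ctx$embedding_size, ctx$hidden_size), c(768L, 384L))
  expect_equal(ctx$dropout_rate, 0.9)
})

test_that("whole-model analytic gradients match finite differences", {
  tm <- tiny_model()
  cfg <- tm$config
  batch <- tm$batch
  fwd <- capstm_forward(tm$params, batch, cfg, keep_cache = TRUE)
  grads <- capstm_backward(tm$params, batch, cfg, fwd,
                           capstm:::bce_dlogit(fwd$prob, batch$labels))
  loss_at <- function(p) {
    bce_loss(capstm_forward(p, batch, cfg)$prob, batch$labels)
  }
  set.seed(99)
  check_block <- function(path) {
    p <- tm$params[[path[1]]]
    g <- grads[[path[1]]]
    if (length(path) > 1) { p <- p[[path[2]]]; g <- g[[path[2]]] }
    for (i in sample(length(p), min(4L, length(p)))) {
      pp <- tm$params
      if (length(path) > 1) pp[[path[1]]][[path[2]]][i] <- p[i] + 1e-6
      else pp[[path[1]]][i] <- p[i] + 1e-6
      up <- loss_at(pp)
      if (length(path) > 1) pp[[path[1]]][[path[2]]][i] <- p[i] - 1e-6
      else pp[[path[1]]][i] <- p[i] - 1e-6
      dn <- loss_at(pp)
      num <- (up - dn) / 2e-6
      expect_lt(abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])), 1e-3)
    }
  }
  check_block("emb")
  for (nm in c("w_f", "b_g")) check_block(c("highway", nm))
  for (nm in c("w_x_f", "w_h_b")) check_block(c("enc", nm))
  for (nm in c("w_x_b", "b_f")) check_block(c("agg", nm))
  for (nm in c("w_conv", "k_caps", "b_caps")) check_block(c("caps", nm))
  for (nm in c("w_h1", "w_h2")) check_block(c("head", nm))
})

test_that("all four variants reduce the worked-batch loss within 200 steps", {
  wb <- make_worked_batch()
  for (variant in names(ablation_variants(tiny_config()))) {
    cfg <- ablation_variants(tiny_config(activation = "relu"))[[variant]]
    set.seed(17)
    params <- capstm:::capstm_init_params(cfg, length(wb$vocab))
    state <- capstm:::adam_init(params)
    first <- NA
    for (step in 1:200) {
      fwd <- capstm_forward(params, wb$batch, cfg, training = TRUE,
                            keep_cache = TRUE)
      if (step == 1) first <- bce_loss(fwd$prob, wb$batch$labels)
      g <- capstm_backward(params, wb$batch, cfg, fwd,
                           capstm:::bce_dlogit(fwd$prob, wb$batch$labels))
      au <- capstm:::adam_update(params, g, state, cfg$learning_rate)
      params <- au$params; state <- au$state
    }
    final <- bce_loss(capstm_forward(params, wb$batch, cfg)$prob,
                      wb$batch$labels)
    expect_lt(final, first)
    expect_lt(final, 0.1)
  }
})
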