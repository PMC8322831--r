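fast_cfg <- function(...) {
  capstm_config("small",
    embedding_size = 8, hidden_size = 6, n_capsules = 2, capsule_dim = 4,
    conv_channels = 2, conv_dim = 4, head_hidden = 8, max_len = 12,
    batch_size = 16, dropout_rate = 0, ...
  )
}

test_that("zero patience trains for exactly one epoch", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev, fast_cfg(patience = 0, seed = 1))
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training is reproducible from the seed", {
  corp <- tiny_corpus()
  cfg <- fast_cfg(max_epochs = 3, patience = 3, seed = 21)
  f1 <- capstm_fit(corp$train, corp$dev, cfg)
  f2 <- capstm_fit(corp$train, corp$dev, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("the retained checkpoint maximizes dev F with earliest-epoch ties", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev,
                    fast_cfg(max_epochs = 5, patience = 5, seed = 2))
  expect_equal(fit$dev_f, max(fit$history$dev_f))
  expect_equal(fit$best_epoch,
               which(fit$history$dev_f == max(fit$history$dev_f))[1L])
  # the stored parameters really are the best epoch's: re-scoring dev with
  # them reproduces the recorded best dev F
  m <- capstm_evaluate(fit, corp$dev)
  expect_equal(m$f_score, fit$dev_f, tolerance = 1e-12)
})

test_that("empty or unlabeled splits are rejected", {
  corp <- tiny_corpus()
  empty <- corp$train[0, ]
  expect_error(capstm_fit(empty, corp$dev, fast_cfg()), "empty")
  unlab <- dplyr::mutate(corp$dev, label = NA_integer_)
  expect_error(capstm_fit(corp$train, unlab, fast_cfg()), "labeled")
  fit <- capstm_fit(corp$train, corp$dev, fast_cfg(patience = 0, seed = 3))
  expect_error(capstm_evaluate(fit, dplyr::select(corp$test, -label)),
               "labeled")
})

test_that("predictions carry probabilities and the 0.5 decision rule", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev, fast_cfg(patience = 0, seed = 4))
  pred <- predict(fit, corp$test)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  expect_equal(pred$label_pred, as.integer(pred$probability >= 0.5))
  expect_equal(pred$pair_id, corp$test$pair_id)
})

test_that("checkpoints round-trip through JSON with a verified vocab hash", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev, fast_cfg(patience = 0, seed = 5))
  dir <- withr::local_tempdir()
  capstm_save(fit, dir)
  back <- capstm_load(dir)
  p1 <- predict(fit, corp$test)$probability
  p2 <- predict(back, corp$test)$probability
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_identical(attr(back$vocab, "tokens"), attr(fit$vocab, "tokens"))
  # corrupt the stored vocabulary: loading must refuse
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$vocab_tokens[3] <- "corrupted"
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  expect_error(capstm_load(dir), "hash mismatch")
})

test_that("attention export is normalized, token-labeled and oracle-consistent", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev, fast_cfg(patience = 0, seed = 6))
  ta <- substr(corp$test$text_a[1], 1, 4)
  tb <- substr(corp$test$text_b[1], 1, 5)
  att <- capstm_attention(fit, ta, tb)
  expect_equal(dim(att$weights), c(4L, 5L))
  expect_equal(unname(rowSums(att$weights)), rep(1, 4), tolerance = 1e-6)
  expect_equal(rownames(att$weights), tokenize_text(ta, "char")[[1]])

  # dual route: recompute the weights from the checkpoint's own embeddings
  # through the standalone attention operation
  enc <- encode_batch(tibble::tibble(text_a = ta, text_b = tb),
                      fit$vocab, fit$config$max_len)
  embed <- function(ids) {
    x <- fit$params$emb[as.vector(ids) + 1L, , drop = FALSE]
    highway(x, fit$params$highway)
  }
  want <- interaction_attention(embed(enc$ids_a), embed(enc$ids_b),
                                enc$mask_a[1, ], enc$mask_b[1, ], "softmax")
  expect_equal(att$weights, want$a_fwd[1:4, 1:5],
               ignore_attr = TRUE, tolerance = 1e-10)

  # TSV export parses back to the same matrix
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_attention(att, tf)
  lines <- readLines(tf, encoding = "UTF-8")
  expect_length(lines, 5L)
  header <- strsplit(lines[1], "\t")[[1]]
  expect_equal(header[-1], att$tokens_b)
  row1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.numeric(row1[-1]), unname(att$weights[1, ]),
               tolerance = 1e-7)
})

test_that("attention export refuses models trained without attention", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev,
                    fast_cfg(patience = 0, seed = 7, use_attention = FALSE))
  expect_error(capstm_attention(fit, "ab", "cd"), "without attention")
})

test_that("tidiers and autoplot summarize a fitted model", {
  corp <- tiny_corpus()
  fit <- capstm_fit(corp$train, corp$dev,
                    fast_cfg(max_epochs = 2, patience = 2, seed = 8))
  td <- tidy(fit)
  expect_named(td, c("epoch", "train_loss", "dev_precision", "dev_recall",
                     "dev_f"))
  expect_equal(nrow(td), 2L)
  gl <- glance(fit)
  expect_equal(gl$epochs_trained, 2L)
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(autoplot(fit), "ggplot")
  att <- capstm_attention(fit, "ab", "ab")
  expect_s3_class(autoplot(att), "ggplot")
  expect_equal(sum(tidy(att)$weight), nrow(att$weights), tolerance = 1e-6)
})
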