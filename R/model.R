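# End-to-end model assembly: embed -> highway -> BiLSTM -> cross-attention
# -> concat -> aggregation BiLSTM -> conv capsule features -> routing (or
# pooling ablation) -> fuse -> sigmoid head. Both sentences share every
# parameter (siamese contract).

attention_dim <- function(config) {
  if (!config$use_attention) return(0L)
  if (config$similarity_source == "embedding") config$embedding_size
  else 2L * config$hidden_size
}

capstm_init_params <- function(config, vocab_size, embeddings = NULL) {
  E <- config$embedding_size; H <- config$hidden_size
  J <- config$n_capsules; d <- config$capsule_dim
  I <- config$conv_channels; cd <- config$conv_dim; w <- config$conv_width
  emb <- if (is.null(embeddings)) {
    matrix(stats::runif(vocab_size * E, -0.05, 0.05), vocab_size, E)
  } else {
    stopifnot(nrow(embeddings) == vocab_size, ncol(embeddings) == E)
    embeddings
  }
  emb[1L, ] <- 0 # padding row
  din_agg <- 2L * H + attention_dim(config)
  list(
    emb = emb,
    highway = list(
      w_f = glorot(E, E), b_f = numeric(E),
      w_g = glorot(E, E), b_g = rep(-1, E) # gate starts near the carry path
    ),
    enc = init_bilstm(E, H),
    agg = init_bilstm(din_agg, H),
    caps = list(
      w_conv = glorot(w * 2L * H, I * cd), b_conv = numeric(I * cd),
      k_caps = glorot(cd, J * d), b_caps = numeric(d)
    ),
    head = list(
      w_h1 = glorot(3L * J * d + 1L, config$head_hidden),
      b_h1 = numeric(config$head_hidden),
      w_h2 = glorot(config$head_hidden, 1L), b_h2 = 0
    )
  )
}

caps_call_params <- function(params, config) {
  c(params$caps, list(
    conv_width = config$conv_width, conv_channels = config$conv_channels,
    n_capsules = config$n_capsules, capsule_dim = config$capsule_dim
  ))
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  m <- array(stats::rbinom(length(x), 1L, keep) / keep, dim(x))
  list(y = x * m, mask = m)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

embed_fwd <- function(ids, emb) {
  B <- nrow(ids); n <- ncol(ids); E <- ncol(emb)
  array(emb[as.vector(ids) + 1L, ], c(B, n, E))
}

embed_bwd <- function(dx, ids, vocab_size) {
  B <- dim(dx)[1L]; n <- dim(dx)[2L]; E <- dim(dx)[3L]
  m <- matrix(dx, B * n, E)
  agg <- rowsum(m, group = as.vector(ids) + 1L)
  demb <- matrix(0, vocab_size, E)
  demb[as.integer(rownames(agg)), ] <- agg
  demb[1L, ] <- 0 # padding row never trains
  demb
}

# Forward pass. Returns probabilities plus (optionally) the full cache
# needed by the backward pass, and the per-example attention weights.
capstm_forward <- function(params, batch, config, training = FALSE,
                           keep_cache = FALSE, return_attention = FALSE) {
  side <- function(ids, mask) {
    x0 <- embed_fwd(ids, params$emb)
    dr_e <- dropout_fwd(x0, config$dropout_rate, training)
    B <- nrow(ids); n <- ncol(ids); E <- config$embedding_size
    hw <- highway_fwd(matrix(dr_e$y, B * n, E), params$highway$w_f,
                      params$highway$b_f, params$highway$w_g,
                      params$highway$b_g)
    eprime <- array(hw$y, c(B, n, E))
    enc <- bilstm_fwd(eprime, mask, params$enc)
    dr_h <- dropout_fwd(enc$out, config$dropout_rate, training)
    list(ids = ids, mask = mask, dr_e = dr_e, hw = hw, eprime = eprime,
         enc = enc, dr_h = dr_h, h = dr_h$y)
  }
  a <- side(batch$ids_a, batch$mask_a)
  b <- side(batch$ids_b, batch$mask_b)
  B <- nrow(batch$ids_a)
  att <- NULL
  if (config$use_attention) {
    xa <- if (config$similarity_source == "embedding") a$eprime else a$h
    xb <- if (config$similarity_source == "embedding") b$eprime else b$h
    att <- attention_batch_fwd(xa, xb, batch$mask_a, batch$mask_b,
                               config$norm_mode)
    ca <- concat_representation(a$h, att$att_a)
    cb <- concat_representation(b$h, att$att_b)
  } else {
    ca <- a$h
    cb <- b$h
  }
  agg_a <- bilstm_fwd(ca, batch$mask_a, params$agg)
  agg_b <- bilstm_fwd(cb, batch$mask_b, params$agg)
  dr_sa <- dropout_fwd(agg_a$out, config$dropout_rate, training)
  dr_sb <- dropout_fwd(agg_b$out, config$dropout_rate, training)
  cp <- caps_call_params(params, config)
  cf_a <- capsule_features_fwd(dr_sa$y, batch$mask_a, cp, config$activation)
  cf_b <- capsule_features_fwd(dr_sb$y, batch$mask_b, cp, config$activation)
  route <- function(uh) {
    if (config$capsule_mode == "routing") {
      routing_fwd(uh, config$routing_iters, config$squash_variant)
    } else {
      pool_fwd(uh, config$capsule_mode, config$squash_variant)
    }
  }
  rt_a <- route(cf_a$u_hat)
  rt_b <- route(cf_b$u_hat)
  J <- config$n_capsules; d <- config$capsule_dim
  c1 <- matrix(rt_a$d_out, B, J * d)
  c2 <- matrix(rt_b$d_out, B, J * d)
  fs <- fuse_fwd(c1, c2)
  hd <- head_fwd(fs$f, params$head, config$activation)
  out <- list(prob = hd$prob, logit = hd$logit)
  if (return_attention && config$use_attention) {
    out$attention <- lapply(att$caches, `[[`, "a_fwd")
  }
  if (keep_cache) {
    out$cache <- list(a = a, b = b, att = att, agg_a = agg_a, agg_b = agg_b,
                      dr_sa = dr_sa, dr_sb = dr_sb, cf_a = cf_a, cf_b = cf_b,
                      rt_a = rt_a, rt_b = rt_b, fs = fs, hd = hd, B = B)
  }
  out
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

add_grads <- function(a, b) {
  if (is.list(a)) Map(add_grads, a, b) else a + b
}

# Backward pass from d(loss)/d(logit); returns gradients with the same
# nesting as the parameter list.
capstm_backward <- function(params, batch, config, fwd, dlogit) {
  ch <- fwd$cache
  B <- ch$B
  J <- config$n_capsules; d <- config$capsule_dim
  g <- zero_like(params)
  hb <- head_bwd(dlogit, ch$hd$cache, params$head)
  g$head <- list(w_h1 = hb$grads$dw_h1, b_h1 = hb$grads$db_h1,
                 w_h2 = hb$grads$dw_h2, b_h2 = hb$grads$db_h2)
  fb <- fuse_bwd(hb$df, ch$fs$cache)
  ddcap_a <- array(fb$dc1, c(B, J, d))
  ddcap_b <- array(fb$dc2, c(B, J, d))
  route_bwd <- function(ddcap, rt) {
    if (config$capsule_mode == "routing") routing_bwd(ddcap, rt$cache)
    else pool_bwd(ddcap, rt$cache)
  }
  duh_a <- route_bwd(ddcap_a, ch$rt_a)
  duh_b <- route_bwd(ddcap_b, ch$rt_b)
  cb_a <- capsule_features_bwd(duh_a, ch$cf_a$cache)
  cb_b <- capsule_features_bwd(duh_b, ch$cf_b$cache)
  g$caps <- list(
    w_conv = cb_a$grads$dw_conv + cb_b$grads$dw_conv,
    b_conv = cb_a$grads$db_conv + cb_b$grads$db_conv,
    k_caps = cb_a$grads$dk_caps + cb_b$grads$dk_caps,
    b_caps = cb_a$grads$db_caps + cb_b$grads$db_caps
  )
  dS_a <- dropout_bwd(cb_a$ds_seq, ch$dr_sa$mask)
  dS_b <- dropout_bwd(cb_b$ds_seq, ch$dr_sb$mask)
  ab_a <- bilstm_bwd(dS_a, ch$agg_a$cache)
  ab_b <- bilstm_bwd(dS_b, ch$agg_b$cache)
  g$agg <- list(
    w_x_f = ab_a$grads$dw_x_f + ab_b$grads$dw_x_f,
    w_h_f = ab_a$grads$dw_h_f + ab_b$grads$dw_h_f,
    b_f = ab_a$grads$db_f + ab_b$grads$db_f,
    w_x_b = ab_a$grads$dw_x_b + ab_b$grads$dw_x_b,
    w_h_b = ab_a$grads$dw_h_b + ab_b$grads$dw_h_b,
    b_b = ab_a$grads$db_b + ab_b$grads$db_b
  )
  H2 <- 2L * config$hidden_size
  if (config$use_attention) {
    Datt <- attention_dim(config)
    dh_a <- ab_a$dx[, , seq_len(H2), drop = FALSE]
    dh_b <- ab_b$dx[, , seq_len(H2), drop = FALSE]
    datt_a <- ab_a$dx[, , H2 + seq_len(Datt), drop = FALSE]
    datt_b <- ab_b$dx[, , H2 + seq_len(Datt), drop = FALSE]
    attb <- attention_batch_bwd(datt_a, datt_b, ch$att)
    dxatt_a <- attb$dxa
    dxatt_b <- attb$dxb
  } else {
    dh_a <- ab_a$dx
    dh_b <- ab_b$dx
    dxatt_a <- dxatt_b <- NULL
  }
  side_bwd <- function(sd, dh, dxatt) {
    if (!is.null(dxatt) && config$similarity_source == "hidden") {
      dh <- dh + dxatt
    }
    denc <- dropout_bwd(dh, sd$dr_h$mask)
    eb <- bilstm_bwd(denc, sd$enc$cache)
    deprime <- eb$dx
    if (!is.null(dxatt) && config$similarity_source == "embedding") {
      deprime <- deprime + dxatt
    }
    n <- ncol(sd$ids); E <- config$embedding_size
    hwb <- highway_bwd(matrix(deprime, B * n, E), sd$hw$cache)
    dx0 <- dropout_bwd(array(hwb$dx, c(B, n, E)), sd$dr_e$mask)
    list(enc = eb$grads, hw = hwb,
         demb = if (config$train_embeddings) {
           embed_bwd(dx0, sd$ids, nrow(params$emb))
         } else {
           params$emb * 0
         })
  }
  sa <- side_bwd(ch$a, dh_a, dxatt_a)
  sb <- side_bwd(ch$b, dh_b, dxatt_b)
  g$enc <- list(
    w_x_f = sa$enc$dw_x_f + sb$enc$dw_x_f,
    w_h_f = sa$enc$dw_h_f + sb$enc$dw_h_f,
    b_f = sa$enc$db_f + sb$enc$db_f,
    w_x_b = sa$enc$dw_x_b + sb$enc$dw_x_b,
    w_h_b = sa$enc$dw_h_b + sb$enc$dw_h_b,
    b_b = sa$enc$db_b + sb$enc$db_b
  )
  g$highway <- list(
    w_f = sa$hw$dw_f + sb$hw$dw_f, b_f = sa$hw$db_f + sb$hw$db_f,
    w_g = sa$hw$dw_g + sb$hw$dw_g, b_g = sa$hw$db_g + sb$hw$db_g
  )
  g$emb <- sa$demb + sb$demb
  g
}

# Loss gradient w.r.t. the logit for mean BCE with probability clipping.
bce_dlogit <- function(prob, labels) {
  inside <- prob > 1e-7 & prob < 1 - 1e-7
  ifelse(inside, (prob - labels) / length(labels), 0)
}
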