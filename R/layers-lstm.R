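# LSTM over padded batches. States carry through masked positions unchanged
# and outputs are zeroed there, so appending padding never perturbs the
# states seen at valid positions — this is what makes the whole model
# padding-invariant. Gate layout in the fused weight matrices: input i,
# forget f, output o, candidate g (columns 1:H, H+1:2H, 2H+1:3H, 3H+1:4H).

lstm_dir_fwd <- function(x, mask, w_x, w_h, b, reverse = FALSE) {
  B <- dim(x)[1L]; n <- dim(x)[2L]; H <- ncol(w_h) / 4L
  steps <- if (reverse) rev(seq_len(n)) else seq_len(n)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, c(B, n, H))
  cache <- vector("list", n)
  for (k in seq_along(steps)) {
    t <- steps[[k]]
    xt <- step_mat(x, t)
    m <- mask[, t]
    z <- sweep(xt %*% w_x + h %*% w_h, 2L, b, `+`)
    iH <- seq_len(H)
    gi <- sigmoid(z[, iH, drop = FALSE])
    gf <- sigmoid(z[, H + iH, drop = FALSE])
    go <- sigmoid(z[, 2L * H + iH, drop = FALSE])
    gg <- tanh(z[, 3L * H + iH, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    cache[[k]] <- list(xt = xt, h_prev = h, c_prev = cc, gi = gi, gf = gf,
                       go = go, gg = gg, tc = tc, m = m, t = t)
    cc <- m * c_new + (1 - m) * cc
    h <- m * h_new + (1 - m) * h
    out[, t, ] <- m * h_new
  }
  list(out = out, cache = cache,
       dims = list(B = B, n = n, H = H, reverse = reverse))
}

lstm_dir_bwd <- function(dout, fwd, w_x, w_h) {
  B <- fwd$dims$B; n <- fwd$dims$n; H <- fwd$dims$H
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dx <- array(0, c(B, n, nrow(w_x)))
  dw_x <- matrix(0, nrow(w_x), ncol(w_x))
  dw_h <- matrix(0, nrow(w_h), ncol(w_h))
  db <- numeric(ncol(w_x))
  for (k in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[k]]
    m <- cc$m; t <- cc$t
    # binary mask: gradient into h_new is m*(dh_next + dout_t), the carry
    # (1-m)*dh_next flows straight to the previous state
    dh_new <- m * (step_mat(dout, t) + dh_next)
    dh_carry <- (1 - m) * dh_next
    dc_new <- m * dc_next
    dc_carry <- (1 - m) * dc_next
    do_ <- dh_new * cc$tc
    dtc <- dh_new * cc$go
    dc_new <- dc_new + dtc * (1 - cc$tc^2)
    df <- dc_new * cc$c_prev
    di <- dc_new * cc$gg
    dg <- dc_new * cc$gi
    dc_prev <- dc_new * cc$gf + dc_carry
    dz <- cbind(
      di * cc$gi * (1 - cc$gi),
      df * cc$gf * (1 - cc$gf),
      do_ * cc$go * (1 - cc$go),
      dg * (1 - cc$gg^2)
    )
    dx[, t, ] <- dz %*% t(w_x)
    dw_x <- dw_x + t(cc$xt) %*% dz
    dw_h <- dw_h + t(cc$h_prev) %*% dz
    db <- db + colSums(dz)
    dh_next <- dz %*% t(w_h) + dh_carry
    dc_next <- dc_prev
  }
  list(dx = dx, dw_x = dw_x, dw_h = dw_h, db = db)
}

bilstm_fwd <- function(x, mask, params) {
  fwd <- lstm_dir_fwd(x, mask, params$w_x_f, params$w_h_f, params$b_f,
                      reverse = FALSE)
  bwd <- lstm_dir_fwd(x, mask, params$w_x_b, params$w_h_b, params$b_b,
                      reverse = TRUE)
  B <- dim(x)[1L]; n <- dim(x)[2L]; H <- fwd$dims$H
  out <- array(0, c(B, n, 2L * H))
  out[, , seq_len(H)] <- fwd$out
  out[, , H + seq_len(H)] <- bwd$out
  list(out = out, cache = list(fwd = fwd, bwd = bwd, H = H, params = params))
}

bilstm_bwd <- function(dout, cache) {
  H <- cache$H
  p <- cache$params
  d_f <- lstm_dir_bwd(dout[, , seq_len(H), drop = FALSE], cache$fwd,
                      p$w_x_f, p$w_h_f)
  d_b <- lstm_dir_bwd(dout[, , H + seq_len(H), drop = FALSE], cache$bwd,
                      p$w_x_b, p$w_h_b)
  list(
    dx = d_f$dx + d_b$dx,
    grads = list(dw_x_f = d_f$dw_x, dw_h_f = d_f$dw_h, db_f = d_f$db,
                 dw_x_b = d_b$dw_x, dw_h_b = d_b$dw_h, db_b = d_b$db)
  )
}

init_bilstm <- function(din, H) {
  b0 <- rep(c(0, 1, 0, 0), each = H) # forget-gate bias 1
  list(
    w_x_f = glorot(din, 4L * H), w_h_f = glorot(H, 4L * H), b_f = b0,
    w_x_b = glorot(din, 4L * H), w_h_b = glorot(H, 4L * H), b_b = b0
  )
}

#' Bidirectional LSTM encoding of a padded sequence batch
#'
#' Runs a forward and a backward LSTM over the token axis and concatenates
#' their per-token hidden states, giving a `2H`-dimensional vector per
#' position. Masked (padding) positions produce zero output and do not
#' perturb the recurrent state, so results are invariant to extra padding.
#'
#' @param x Numeric array (batch x n x D) of input vectors.
#' @param mask 0/1 matrix (batch x n).
#' @param params Parameter list as produced by the model initialiser:
#'   fused gate matrices `w_x_f`, `w_h_f`, `b_f` (forward direction) and
#'   `w_x_b`, `w_h_b`, `b_b` (backward direction).
#' @return Numeric array (batch x n x 2H).
#' @export
bilstm_encode <- function(x, mask, params) {
  bilstm_fwd(x, mask, params)$out
}

#' Aggregate concatenated representations with a BiLSTM
#'
#' The aggregation layer is a second BiLSTM applied to the per-position
#' concatenation of encoder states and attended vectors; identical contract
#' to [bilstm_encode()] with its own parameters.
#'
#' @inheritParams bilstm_encode
#' @return Numeric array (batch x n x 2H).
#' @export
aggregate_sequence <- function(x, mask, params) {
  bilstm_fwd(x, mask, params)$out
}

#' Concatenate encoder states with attended vectors
#'
#' Builds the per-position representation `c_i = [h_i : a_i]` fed to the
#' aggregation layer. The order is fixed: encoder block first.
#'
#' @param h Array (batch x n x D1).
#' @param attended Array (batch x n x D2).
#' @return Array (batch x n x (D1 + D2)).
#' @export
concat_representation <- function(h, attended) {
  dh <- dim(h); da <- dim(attended)
  if (!all(dh[1:2] == da[1:2])) {
    stop("concat_representation: length mismatch", call. = FALSE)
  }
  out <- array(0, c(dh[1L], dh[2L], dh[3L] + da[3L]))
  out[, , seq_len(dh[3L])] <- h
  out[, , dh[3L] + seq_len(da[3L])] <- attended
  out
}
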