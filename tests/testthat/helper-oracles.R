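# Independent scalar-loop reference implementations. These deliberately use
# element-by-element arithmetic (no shared code with the package's
# vectorized layers) so layer tests compare two independent routes.

oracle_highway <- function(e, w_f, b_f, w_g, b_g) {
  out <- matrix(0, nrow(e), ncol(e))
  for (r in seq_len(nrow(e))) {
    E <- ncol(e)
    ehat <- numeric(E)
    for (j in seq_len(E)) {
      acc <- b_f[j]
      for (k in seq_len(E)) acc <- acc + e[r, k] * w_f[k, j]
      ehat[j] <- tanh(acc)
    }
    g <- numeric(E)
    for (j in seq_len(E)) {
      acc <- b_g[j]
      for (k in seq_len(E)) acc <- acc + ehat[k] * w_g[k, j]
      g[j] <- 1 / (1 + exp(-acc))
    }
    for (j in seq_len(E)) {
      out[r, j] <- g[j] * ehat[j] + (1 - g[j]) * e[r, j]
    }
  }
  out
}

# One LSTM cell step from zero state, scalar arithmetic.
oracle_lstm_step <- function(x, w_x, w_h, b, H) {
  z <- numeric(4 * H)
  for (j in seq_len(4 * H)) {
    acc <- b[j]
    for (k in seq_along(x)) acc <- acc + x[k] * w_x[k, j]
    z[j] <- acc # h_prev = 0
  }
  sig <- function(v) 1 / (1 + exp(-v))
  h <- numeric(H)
  for (j in seq_len(H)) {
    i_g <- sig(z[j]); f_g <- sig(z[H + j])
    o_g <- sig(z[2 * H + j]); c_g <- tanh(z[3 * H + j])
    c_t <- f_g * 0 + i_g * c_g
    h[j] <- o_g * tanh(c_t)
  }
  h
}

oracle_attention <- function(ea, eb, mask_a, mask_b, mode) {
  na <- nrow(ea); nb <- nrow(eb); D <- ncol(ea)
  sim <- matrix(0, na, nb)
  for (k in seq_len(na)) {
    for (s in seq_len(nb)) {
      for (j in seq_len(D)) sim[k, s] <- sim[k, s] + ea[k, j] * eb[s, j]
    }
  }
  norm1 <- function(scores, valid) {
    w <- numeric(length(scores))
    if (mode == "softmax") {
      mx <- max(scores[valid])
      den <- 0
      for (s in which(valid)) den <- den + exp(scores[s] - mx)
      for (s in which(valid)) w[s] <- exp(scores[s] - mx) / den
    } else {
      den <- sum(scores[valid])
      for (s in which(valid)) w[s] <- scores[s] / den
    }
    w
  }
  a_fwd <- matrix(0, na, nb); a_bwd <- matrix(0, na, nb)
  for (k in which(mask_a > 0)) a_fwd[k, ] <- norm1(sim[k, ], mask_b > 0)
  for (s in which(mask_b > 0)) a_bwd[, s] <- norm1(sim[, s], mask_a > 0)
  att_a <- matrix(0, na, D); att_b <- matrix(0, nb, D)
  for (k in which(mask_a > 0)) {
    for (s in seq_len(nb)) att_a[k, ] <- att_a[k, ] + a_fwd[k, s] * eb[s, ]
  }
  for (k in which(mask_b > 0)) {
    for (s in seq_len(na)) att_b[k, ] <- att_b[k, ] + a_bwd[s, k] * ea[s, ]
  }
  list(sim = sim, a_fwd = a_fwd, a_bwd = a_bwd,
       attended_a = att_a, attended_b = att_b)
}

oracle_squash <- function(s, variant = "printed") {
  r <- sqrt(sum(s^2))
  if (r == 0) return(s * 0)
  if (variant == "printed") (r^2 / (1 + r)) * (s / r^2) else s * r / (1 + r^2)
}

# Literal execution of the routing algorithm, triple loops throughout.
oracle_routing <- function(u_hat, iters, variant = "printed") {
  I <- dim(u_hat)[1]; J <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, I, J)
  cpl <- matrix(0, I, J)
  d_out <- matrix(0, J, d)
  hist <- list()
  for (r in seq_len(iters)) {
    for (i in seq_len(I)) {
      mx <- max(b[i, ])
      den <- sum(exp(b[i, ] - mx))
      for (j in seq_len(J)) cpl[i, j] <- exp(b[i, j] - mx) / den
    }
    hist[[r]] <- cpl + 0
    for (j in seq_len(J)) {
      s_j <- numeric(d)
      for (i in seq_len(I)) s_j <- s_j + cpl[i, j] * u_hat[i, j, ]
      d_out[j, ] <- oracle_squash(s_j, variant)
    }
    if (r < iters) {
      for (i in seq_len(I)) {
        for (j in seq_len(J)) {
          b[i, j] <- b[i, j] + sum(d_out[j, ] * u_hat[i, j, ])
        }
      }
    }
  }
  list(d_out = d_out, couplings = cpl, coupling_history = hist)
}

oracle_capsule_features <- function(s_seq, mask, params, activation) {
  act <- switch(activation,
                relu = function(x) pmax(x, 0),
                tanh = tanh, sigmoid = function(x) 1 / (1 + exp(-x)))
  B <- dim(s_seq)[1]; n <- dim(s_seq)[2]; D <- dim(s_seq)[3]
  w <- params$conv_width; I <- params$conv_channels
  cd <- ncol(params$w_conv) / I
  J <- params$n_capsules; d <- params$capsule_dim
  half <- (w - 1) / 2
  u_hat <- array(0, c(B, I, J, d))
  for (b in seq_len(B)) {
    conv <- matrix(0, n, I * cd)
    for (t in seq_len(n)) {
      win <- numeric(w * D)
      for (c_i in seq_len(w)) {
        src <- t + c_i - 1 - half
        if (src >= 1 && src <= n) {
          win[(c_i - 1) * D + seq_len(D)] <- s_seq[b, src, ]
        }
      }
      for (u in seq_len(I * cd)) {
        conv[t, u] <- act(sum(win * params$w_conv[, u]) + params$b_conv[u])
      }
    }
    feat <- numeric(I * cd)
    for (u in seq_len(I * cd)) feat[u] <- max(conv[mask[b, ] > 0, u])
    for (i in seq_len(I)) {
      u_i <- feat[(i - 1) * cd + seq_len(cd)]
      for (j in seq_len(J)) {
        pre <- numeric(d)
        for (dd in seq_len(d)) {
          pre[dd] <- sum(u_i * params$k_caps[, (j - 1) * d + dd]) +
            params$b_caps[dd]
        }
        u_hat[b, i, j, ] <- act(pre)
      }
    }
  }
  u_hat
}

oracle_metrics <- function(truth, estimate) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && estimate[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && estimate[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && estimate[i] == 0) fn <- fn + 1
    if (truth[i] == 0 && estimate[i] == 0) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
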