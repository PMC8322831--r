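# Cross-question attention. For one pair with side vectors Ea (n x D) and
# Eb (n x D):
#   sim[k, s] = <Ea_k, Eb_s>
#   row weights a_ks   : normalised over s (side-b positions)
#   col weights a'_sk  : the same sim matrix normalised over s' on the side-a
#                        axis (column direction)
#   attended_a[k] = sum_s a_ks  Eb_s    (what side a sees of side b)
#   attended_b[k] = sum_s a'_sk Ea_s    (what side b sees of side a)
# "softmax" masks padding with -Inf before normalising; "literal" divides by
# the raw row/column sum and refuses non-positive sums.

attn_norm <- function(scores, valid, mode, axis_name) {
  # scores: vector of raw similarities along the attended axis
  w <- numeric(length(scores))
  if (!any(valid)) return(w)
  if (mode == "softmax") {
    z <- scores[valid]
    e <- exp(z - max(z))
    w[valid] <- e / sum(e)
  } else {
    s <- sum(scores[valid])
    if (s <= 0) {
      # the ratio normalization only defines positive-sum slices; an
      # all-zero slice (e.g. a token orthogonal to every counterpart)
      # vacuously receives no attention mass
      if (all(scores[valid] == 0)) return(w)
      stop("literal normalization hit a non-positive ", axis_name,
           " sum; use norm_mode = \"softmax\"", call. = FALSE)
    }
    w[valid] <- scores[valid] / s
  }
  w
}

attention_pair_fwd <- function(ea, eb, mask_a, mask_b, mode) {
  n_a <- nrow(ea); n_b <- nrow(eb)
  sim <- ea %*% t(eb)
  va <- mask_a > 0; vb <- mask_b > 0
  a_fwd <- matrix(0, n_a, n_b) # rows: side-a positions, weights over side b
  a_bwd <- matrix(0, n_a, n_b) # columns: side-b positions, weights over side a
  for (k in which(va)) a_fwd[k, ] <- attn_norm(sim[k, ], vb, mode, "row")
  for (s in which(vb)) a_bwd[, s] <- attn_norm(sim[, s], va, mode, "column")
  attended_a <- a_fwd %*% eb            # n_a x D, zero rows where !va
  attended_b <- t(a_bwd) %*% ea          # n_b x D, zero rows where !vb
  list(sim = sim, a_fwd = a_fwd, a_bwd = a_bwd,
       attended_a = attended_a, attended_b = attended_b,
       va = va, vb = vb, mode = mode, ea = ea, eb = eb)
}

attention_pair_bwd <- function(datt_a, datt_b, cache) {
  ea <- cache$ea; eb <- cache$eb
  a_fwd <- cache$a_fwd; a_bwd <- cache$a_bwd
  dea <- a_bwd %*% datt_b            # attended_b = t(a_bwd) %*% ea
  deb <- t(a_fwd) %*% datt_a         # attended_a = a_fwd %*% eb
  da_fwd <- datt_a %*% t(eb)
  da_bwd <- ea %*% t(datt_b)
  dsim <- matrix(0, nrow(a_fwd), ncol(a_fwd))
  for (k in which(cache$va)) {
    dsim[k, ] <- dsim[k, ] + norm_bwd(da_fwd[k, ], a_fwd[k, ],
                                      cache$sim[k, ], cache$vb, cache$mode)
  }
  for (s in which(cache$vb)) {
    dsim[, s] <- dsim[, s] + norm_bwd(da_bwd[, s], a_bwd[, s],
                                      cache$sim[, s], cache$va, cache$mode)
  }
  dea <- dea + dsim %*% eb
  deb <- deb + t(dsim) %*% ea
  list(dea = dea, deb = deb)
}

norm_bwd <- function(dw, w, scores, valid, mode) {
  ds <- numeric(length(dw))
  if (!any(valid)) return(ds)
  if (mode == "softmax") {
    wv <- w[valid]
    ds[valid] <- wv * (dw[valid] - sum(dw[valid] * wv))
  } else {
    s <- sum(scores[valid])
    if (s <= 0) return(ds) # vacuous all-zero slice carried zero weights
    ds[valid] <- dw[valid] / s - sum(dw[valid] * scores[valid]) / s^2
  }
  ds
}

attention_batch_fwd <- function(xa, xb, mask_a, mask_b, mode) {
  B <- dim(xa)[1L]; n <- dim(xa)[2L]; D <- dim(xa)[3L]
  att_a <- array(0, c(B, n, D)); att_b <- array(0, c(B, n, D))
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    ea <- matrix(xa[b, , ], n, D); eb <- matrix(xb[b, , ], n, D)
    cc <- attention_pair_fwd(ea, eb, mask_a[b, ], mask_b[b, ], mode)
    att_a[b, , ] <- cc$attended_a
    att_b[b, , ] <- cc$attended_b
    caches[[b]] <- cc
  }
  list(att_a = att_a, att_b = att_b, caches = caches)
}

attention_batch_bwd <- function(datt_a, datt_b, fwd) {
  B <- dim(datt_a)[1L]; n <- dim(datt_a)[2L]; D <- dim(datt_a)[3L]
  dxa <- array(0, c(B, n, D)); dxb <- array(0, c(B, n, D))
  for (b in seq_len(B)) {
    d <- attention_pair_bwd(matrix(datt_a[b, , ], n, D),
                            matrix(datt_b[b, , ], n, D), fwd$caches[[b]])
    dxa[b, , ] <- d$dea
    dxb[b, , ] <- d$deb
  }
  list(dxa = dxa, dxb = dxb)
}

#' Attention interaction between two token-vector sequences
#'
#' Computes the pairwise similarity matrix `sim[k, s] = <ea_k, eb_s>`,
#' normalises it into attention weights, and builds the attended vectors:
#' position `k` of side a receives the weight-averaged side-b vectors and
#' vice versa (column-direction normalisation of the same matrix). In
#' `"softmax"` mode weights are a masked softmax over the attended axis; in
#' `"literal"` mode they are `sim / sum(sim)`, which errors on a zero or
#' negative sum (an all-zero slice is treated as vacuous and receives zero
#' weight).
#'
#' @param ea,eb Numeric matrices (n x D), one row per token position.
#' @param mask_a,mask_b 0/1 vectors of length n (1 = real token).
#' @param norm_mode `"softmax"` or `"literal"`.
#' @return List with `sim` (n x n), `a_fwd` (row-normalised weights),
#'   `a_bwd` (column-direction weights), `attended_a`, `attended_b`.
#' @examples
#' u <- c(1, 0); v <- c(0, 1)
#' r <- interaction_attention(rbind(u), rbind(u, v), 1, c(1, 1), "literal")
#' r$a_fwd # weights (1, 0): all attention on the matching token
#' @export
interaction_attention <- function(ea, eb, mask_a = NULL, mask_b = NULL,
                                  norm_mode = c("softmax", "literal")) {
  norm_mode <- match.arg(norm_mode)
  if (ncol(ea) != ncol(eb)) {
    stop("interaction_attention: vector dimension mismatch", call. = FALSE)
  }
  if (is.null(mask_a)) mask_a <- rep(1, nrow(ea))
  if (is.null(mask_b)) mask_b <- rep(1, nrow(eb))
  r <- attention_pair_fwd(ea, eb, mask_a, mask_b, norm_mode)
  r[c("sim", "a_fwd", "a_bwd", "attended_a", "attended_b")]
}
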