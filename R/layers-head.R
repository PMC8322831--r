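# Fusion of the two sentence capsule blocks and the sigmoid prediction head.

cosine_rows <- function(a, b, eps = 1e-12) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  ok <- na > eps & nb > eps
  cs <- numeric(nrow(a))
  cs[ok] <- rowSums(a * b)[ok] / (na[ok] * nb[ok])
  list(cos = cs, na = na, nb = nb, ok = ok)
}

fuse_fwd <- function(c1, c2) {
  cz <- cosine_rows(c1, c2)
  f <- cbind(c1, c2, c1 - c2, cz$cos)
  list(f = f, cache = list(c1 = c1, c2 = c2, cz = cz))
}

fuse_bwd <- function(df, cache) {
  c1 <- cache$c1; c2 <- cache$c2; cz <- cache$cz
  p <- ncol(c1)
  dc1 <- df[, seq_len(p), drop = FALSE] +
    df[, 2L * p + seq_len(p), drop = FALSE]
  dc2 <- df[, p + seq_len(p), drop = FALSE] -
    df[, 2L * p + seq_len(p), drop = FALSE]
  dcos <- df[, 3L * p + 1L]
  ok <- cz$ok
  if (any(ok)) {
    na <- cz$na[ok]; nb <- cz$nb[ok]; cs <- cz$cos[ok]; g <- dcos[ok]
    dc1[ok, ] <- dc1[ok, , drop = FALSE] +
      g * (c2[ok, , drop = FALSE] / (na * nb) -
             cs * c1[ok, , drop = FALSE] / na^2)
    dc2[ok, ] <- dc2[ok, , drop = FALSE] +
      g * (c1[ok, , drop = FALSE] / (na * nb) -
             cs * c2[ok, , drop = FALSE] / nb^2)
  }
  list(dc1 = dc1, dc2 = dc2)
}

#' Fuse the two sentence capsule representations
#'
#' Builds the prediction-layer input
#' `[C1, C2, C1 - C2, cos(C1, C2)]`: both flattened capsule blocks, their
#' elementwise difference, and one cosine-similarity scalar. The cosine of
#' a zero vector is defined as 0.
#'
#' @param c1,c2 Numeric vectors of equal length (flattened J x d capsule
#'   outputs), or matrices with one row per example.
#' @return Vector (or matrix) of length `3 * length(c1) + 1`.
#' @examples
#' fuse(c(1, 0), c(0, 1)) # orthogonal: cosine component 0
#' @export
fuse <- function(c1, c2) {
  vec <- is.null(dim(c1))
  m1 <- if (vec) matrix(c1, 1L) else c1
  m2 <- if (vec) matrix(c2, 1L) else c2
  if (ncol(m1) != ncol(m2) || nrow(m1) != nrow(m2)) {
    stop("fuse: length mismatch", call. = FALSE)
  }
  out <- fuse_fwd(m1, m2)$f
  if (vec) drop(out) else out
}

head_fwd <- function(f, params, activation) {
  act <- act_fun(activation)
  hpre <- sweep(f %*% params$w_h1, 2L, params$b_h1, `+`)
  h <- act$f(hpre)
  logit <- drop(h %*% params$w_h2) + params$b_h2
  list(logit = logit, prob = sigmoid(logit),
       cache = list(f = f, hpre = hpre, h = h, activation = activation))
}

head_bwd <- function(dlogit, cache, params) {
  act <- act_fun(cache$activation)
  dh <- outer(dlogit, drop(params$w_h2))
  dhpre <- dh * act$df(cache$hpre, cache$h)
  list(
    df = dhpre %*% t(params$w_h1),
    grads = list(
      dw_h1 = t(cache$f) %*% dhpre, db_h1 = colSums(dhpre),
      dw_h2 = matrix(colSums(cache$h * dlogit), ncol = 1L),
      db_h2 = sum(dlogit)
    )
  )
}

#' Prediction head probability
#'
#' One hidden layer with the configured activation followed by a
#' single-unit sigmoid: the match probability.
#'
#' @param f Fusion vector (or matrix of row vectors), see [fuse()].
#' @param params List with `w_h1`, `b_h1`, `w_h2` (column matrix), `b_h2`.
#' @param activation Hidden activation name.
#' @return Probability in (0, 1), one per row.
#' @export
predict_head <- function(f, params, activation = "relu") {
  m <- if (is.null(dim(f))) matrix(f, 1L) else f
  p <- head_fwd(m, params, activation)$prob
  if (is.null(dim(f))) drop(p) else p
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy of predicted match probabilities against 0/1
#' labels, with probabilities clipped to `[1e-7, 1 - 1e-7]` for stability.
#'
#' @param prob Numeric vector of probabilities.
#' @param labels 0/1 vector of the same length.
#' @return Scalar loss.
#' @examples
#' bce_loss(0.5, 1) # log(2)
#' @export
bce_loss <- function(prob, labels) {
  if (length(prob) != length(labels)) {
    stop("bce_loss: length mismatch", call. = FALSE)
  }
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
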