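# Highway-gated embedding transform. Per position:
#   ehat = tanh(e W_f + b_f)
#   g    = sigmoid(ehat W_g + b_g)
#   e'   = g * ehat + (1 - g) * e
# The gate interpolates between the nonlinear branch and the raw embedding.

highway_fwd <- function(x, w_f, b_f, w_g, b_g) {
  if (ncol(x) != nrow(w_f)) stop("highway: dimension mismatch", call. = FALSE)
  a <- sweep(x %*% w_f, 2L, b_f, `+`)
  ehat <- tanh(a)
  gpre <- sweep(ehat %*% w_g, 2L, b_g, `+`)
  g <- sigmoid(gpre)
  y <- g * ehat + (1 - g) * x
  list(y = y, cache = list(x = x, ehat = ehat, g = g, w_f = w_f, w_g = w_g))
}

highway_bwd <- function(dy, cache) {
  x <- cache$x; ehat <- cache$ehat; g <- cache$g
  dg <- dy * (ehat - x)
  dehat <- dy * g
  dgpre <- dg * g * (1 - g)
  dehat <- dehat + dgpre %*% t(cache$w_g)
  da <- dehat * (1 - ehat^2)
  dx <- dy * (1 - g) + da %*% t(cache$w_f)
  list(
    dx = dx,
    dw_f = t(x) %*% da, db_f = colSums(da),
    dw_g = t(ehat) %*% dgpre, db_g = colSums(dgpre)
  )
}

#' Highway transform of an embedding sequence
#'
#' Applies the gated highway transform position-wise:
#' `ehat = tanh(e %*% w_f + b_f)`, `g = sigmoid(ehat %*% w_g + b_g)`,
#' `e' = g * ehat + (1 - g) * e`. A gate near 0 passes the raw embedding
#' through; a gate near 1 selects the tanh branch.
#'
#' @param e Numeric matrix of row vectors (positions x E).
#' @param params List with square matrices `w_f`, `w_g` (E x E) and bias
#'   vectors `b_f`, `b_g` (length E).
#' @return Matrix of the same shape as `e`.
#' @examples
#' p <- list(w_f = diag(2), b_f = c(0, 0), w_g = diag(2), b_g = c(-30, -30))
#' highway(matrix(c(1, 2), 1), p) # gate ~0: identity
#' @export
highway <- function(e, params) {
  highway_fwd(e, params$w_f, params$b_f, params$w_g, params$b_g)$y
}
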