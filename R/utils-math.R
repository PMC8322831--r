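# Shared numeric helpers: activations with derivatives, masked softmax,
# parameter initialisation. Everything operates on plain matrices/arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
act_fun <- function(name) {
  switch(name,
    relu = list(
      f  = function(x) pmax(x, 0),
      df = function(x, y) (x > 0) * 1
    ),
    tanh = list(
      f  = function(x) tanh(x),
      df = function(x, y) 1 - y^2
    ),
    sigmoid = list(
      f  = function(x) sigmoid(x),
      df = function(x, y) y * (1 - y)
    ),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# Row-wise softmax of a matrix; rows are independent distributions.
softmax_rows <- function(x) {
  m <- x - apply(x, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Backward through row-wise softmax: given dL/dy and y = softmax_rows(x),
# returns dL/dx. Standard Jacobian: dx = y * (dy - rowSums(dy * y)).
softmax_rows_bwd <- function(dy, y) {
  y * (dy - rowSums(dy * y))
}

# Glorot-uniform weight matrix, plain runif under the caller's RNG state.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Slice time step t out of a (B, n, D) array as a B x D matrix.
step_mat <- function(x, t) {
  d <- dim(x)
  matrix(x[, t, ], nrow = d[1L], ncol = d[3L])
}

`step_mat<-` <- function(x, t, value) {
  x[, t, ] <- value
  x
}

# Sum over the trailing dims of an array keeping the first two (e.g. a
# (B, J, d) array -> (B, J) norms-squared ingredient).
sum_last <- function(x) rowSums(x, dims = 2L)
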