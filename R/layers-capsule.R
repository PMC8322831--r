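# Convolutional capsule front end and dynamic routing.
#
# capsule_features: width-w same-padded convolution over the aggregated
# token sequence (I kernels, each producing a conv_dim feature per
# position), max-over-time restricted to valid positions, then J capsule
# kernels map each channel vector to a d-dimensional prediction vector
# u_hat[i, j, ] = g(K_j u_i + b).
#
# dynamic_routing: the iterative agreement procedure. Logits b start at 0;
# each iteration softmaxes them over the output-capsule axis into couplings
# c, forms s_j = sum_i c_ij u_hat_ij, squashes into d_j, and reinforces
# logits by <d_j, u_hat_ij>.

# ---- unfold / fold for the token-axis convolution ----------------------

conv_unfold <- function(x, w) {
  B <- dim(x)[1L]; n <- dim(x)[2L]; D <- dim(x)[3L]
  half <- (w - 1L) %/% 2L
  xu <- array(0, c(B, n, w * D))
  for (c_i in seq_len(w)) {
    off <- c_i - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    xu[, which(ok), (c_i - 1L) * D + seq_len(D)] <- x[, src[ok], ]
  }
  xu
}

conv_fold <- function(dxu, w, D) {
  B <- dim(dxu)[1L]; n <- dim(dxu)[2L]
  half <- (w - 1L) %/% 2L
  dx <- array(0, c(B, n, D))
  for (c_i in seq_len(w)) {
    off <- c_i - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    dx[, src[ok], ] <- dx[, src[ok], , drop = FALSE] +
      dxu[, which(ok), (c_i - 1L) * D + seq_len(D), drop = FALSE]
  }
  dx
}

# ---- capsule feature extraction ----------------------------------------

capsule_features_fwd <- function(s_seq, mask, params, activation) {
  act <- act_fun(activation)
  B <- dim(s_seq)[1L]; n <- dim(s_seq)[2L]; D <- dim(s_seq)[3L]
  w <- params$conv_width; I <- params$conv_channels
  cd <- ncol(params$w_conv) / I
  J <- params$n_capsules; d <- params$capsule_dim
  if (n < w) stop("sequence length ", n, " shorter than kernel width ", w,
                  call. = FALSE)
  xu <- conv_unfold(s_seq, w)
  m2 <- matrix(xu, B * n, w * D)
  zpre <- sweep(m2 %*% params$w_conv, 2L, params$b_conv, `+`)
  zact <- act$f(zpre)
  icd <- I * cd
  # max over valid time positions (invalid positions excluded outright)
  mvec <- as.vector(mask) # (b, t) rows, b fastest — matches m2 row order
  fmax <- matrix(-Inf, B, icd)
  tstar <- matrix(1L, B, icd)
  for (t in seq_len(n)) {
    rows <- (t - 1L) * B + seq_len(B)
    zt <- zact[rows, , drop = FALSE]
    zt[mask[, t] == 0, ] <- -Inf
    upd <- zt > fmax
    tstar[upd] <- t
    fmax[upd] <- zt[upd]
  }
  fmax[!is.finite(fmax)] <- 0 # examples with no valid position (cannot occur)
  # channel vectors: (B, cd, I) -> rows (b, i)
  um <- matrix(aperm(array(fmax, c(B, cd, I)), c(1L, 3L, 2L)), B * I, cd)
  ppre <- sweep(um %*% params$k_caps, 2L, rep(params$b_caps, params$n_capsules), `+`)
  p <- act$f(ppre)
  u_hat <- aperm(array(p, c(B, I, d, J)), c(1L, 2L, 4L, 3L))
  list(u_hat = u_hat,
       cache = list(m2 = m2, zpre = zpre, zact = zact, tstar = tstar,
                    um = um, ppre = ppre, p = p, B = B, n = n, D = D,
                    w = w, I = I, cd = cd, J = J, d = d,
                    activation = activation, params = params))
}

capsule_features_bwd <- function(du_hat, cache) {
  act <- act_fun(cache$activation)
  B <- cache$B; n <- cache$n; D <- cache$D
  I <- cache$I; cd <- cache$cd; J <- cache$J; d <- cache$d
  params <- cache$params
  dp <- matrix(aperm(du_hat, c(1L, 2L, 4L, 3L)), B * I, J * d)
  dppre <- dp * act$df(cache$ppre, cache$p)
  dum <- dppre %*% t(params$k_caps)
  dk_caps <- t(cache$um) %*% dppre
  db_caps <- rowSums(matrix(colSums(dppre), d, J))
  # back through channel reshape to the pooled feature matrix (B x I*cd)
  dfmax <- matrix(aperm(array(dum, c(B, I, cd)), c(1L, 3L, 2L)), B, I * cd)
  # route max gradient to the argmax time step
  icd <- I * cd
  rows <- (cache$tstar - 1L) * B + seq_len(B)          # (B x icd) row index
  lin <- as.vector(rows) + (B * n) * rep(seq_len(icd) - 1L, each = B)
  dzact <- matrix(0, B * n, icd)
  dzact[lin] <- as.vector(dfmax)
  dzpre <- dzact * act$df(cache$zpre, cache$zact)
  dxu_m <- dzpre %*% t(params$w_conv)
  dw_conv <- t(cache$m2) %*% dzpre
  db_conv <- colSums(dzpre)
  ds_seq <- conv_fold(array(dxu_m, c(B, n, cache$w * D)), cache$w, D)
  list(ds_seq = ds_seq,
       grads = list(dw_conv = dw_conv, db_conv = db_conv,
                    dk_caps = dk_caps, db_caps = db_caps))
}

#' Capsule prediction vectors from an aggregated sequence
#'
#' Applies `conv_channels` width-`conv_width` convolution kernels over the
#' token axis (same-padding; padding positions never contribute), takes the
#' per-kernel max over time to get one channel feature vector each, and maps
#' every channel through each of the `n_capsules` capsule kernels to a
#' `capsule_dim`-dimensional prediction vector with the configured
#' activation.
#'
#' @param s_seq Numeric array (batch x n x D), the aggregation-layer output.
#' @param mask 0/1 matrix (batch x n).
#' @param params List with `w_conv` ((conv_width * D) x
#'   (conv_channels * conv_dim)), `b_conv`, `k_caps` (conv_dim x
#'   (n_capsules * capsule_dim)), `b_caps` (length capsule_dim, shared
#'   across capsules), and the integer fields `conv_width`, `conv_channels`,
#'   `n_capsules`, `capsule_dim`.
#' @param activation Activation name (`"relu"`, `"tanh"`, `"sigmoid"`).
#' @return Array (batch x I x J x d) of prediction vectors.
#' @export
capsule_features <- function(s_seq, mask, params, activation = "relu") {
  capsule_features_fwd(s_seq, mask, params, activation)$u_hat
}

# ---- squash -------------------------------------------------------------

squash_arr_fwd <- function(s, variant) {
  r <- sqrt(pmax(sum_last(s^2), 0))
  f <- if (variant == "printed") 1 / (1 + r) else r / (1 + r^2)
  y <- s * array(f, dim(s))
  list(y = y, r = r, f = f)
}

squash_arr_bwd <- function(dy, s, fwd, variant) {
  r <- fwd$r
  eps <- 1e-12
  dots <- sum_last(dy * s)
  if (variant == "printed") {
    coef <- ifelse(r > eps, dots / (r * (1 + r)^2), 0)
    dy * array(fwd$f, dim(s)) - s * array(coef, dim(s))
  } else {
    fprime <- (1 - r^2) / (1 + r^2)^2
    coef <- ifelse(r > eps, dots * fprime / r, 0)
    dy * array(fwd$f, dim(s)) + s * array(coef, dim(s))
  }
}

#' Squash nonlinearity
#'
#' Maps a capsule vector to the same direction with norm in \[0, 1).
#' The `"printed"` variant is `s / (1 + ||s||)` (algebraically equal to
#' `||s||^2/(1+||s||) * s/||s||^2`), with output norm `||s||/(1+||s||)`.
#' The `"standard"` variant is the canonical capsule squash
#' `s * ||s|| / (1 + ||s||^2)`. Both fix 0 to 0.
#'
#' @param s Numeric vector, or matrix whose rows are squashed independently.
#' @param variant `"printed"` or `"standard"`.
#' @return Same shape as `s`.
#' @examples
#' squash(c(3, 4)) # (0.5, 2/3), norm 5/6
#' @export
squash <- function(s, variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  vec <- is.null(dim(s))
  m <- if (vec) matrix(s, 1L) else s
  arr <- array(m, c(nrow(m), 1L, ncol(m)))
  y <- squash_arr_fwd(arr, variant)$y
  out <- matrix(y, nrow(m), ncol(m))
  if (vec) drop(out) else out
}

# ---- dynamic routing ----------------------------------------------------

routing_fwd <- function(u_hat, iters, variant) {
  dm <- dim(u_hat)
  B <- dm[1L]; I <- dm[2L]; J <- dm[3L]; d <- dm[4L]
  u2 <- matrix(u_hat, B * I, J * d)          # rows (b,i), cols (j,dd) j-fastest
  jd_j <- rep(seq_len(J), times = d)          # column -> j map
  grp <- rep(seq_len(B), times = I)           # row -> b map (b fastest)
  b_log <- matrix(0, B * I, J)
  iter_cache <- vector("list", iters)
  s_arr <- NULL; d_arr <- NULL; cpl <- NULL
  for (r in seq_len(iters)) {
    cpl <- softmax_rows(b_log)
    s2 <- rowsum(cpl[, jd_j, drop = FALSE] * u2, grp, reorder = FALSE)
    s_arr <- array(s2, c(B, J, d))
    sq <- squash_arr_fwd(s_arr, variant)
    d_arr <- sq$y
    iter_cache[[r]] <- list(cpl = cpl, s_arr = s_arr, sq = sq, d_arr = d_arr)
    if (r < iters) {
      dflat <- matrix(d_arr, B, J * d)
      inner <- u2 * dflat[grp, , drop = FALSE]
      b_log <- b_log + rowSums(array(inner, c(B * I, J, d)), dims = 2L)
    }
  }
  list(d_out = d_arr, couplings = array(cpl, c(B, I, J)),
       cache = list(u2 = u2, iter_cache = iter_cache, dims = dm,
                    jd_j = jd_j, grp = grp, variant = variant, iters = iters))
}

routing_bwd <- function(dd_out, cache) {
  dm <- cache$dims
  B <- dm[1L]; I <- dm[2L]; J <- dm[3L]; d <- dm[4L]
  u2 <- cache$u2; jd_j <- cache$jd_j; grp <- cache$grp
  iters <- cache$iters; variant <- cache$variant
  du2 <- matrix(0, B * I, J * d)
  db_log <- matrix(0, B * I, J)   # gradient w.r.t. b^{r} entering iteration r+1
  dd_r <- dd_out                   # gradient on d^T
  for (r in rev(seq_len(iters))) {
    ic <- cache$iter_cache[[r]]
    if (r < iters) {
      # b^r = b^{r-1} + <d^r, u>: db_log flows into both summands;
      # inner-product part: dd[b,j,dd] += sum_i db_log[(b,i),j] * u
      contrib <- db_log[, jd_j, drop = FALSE] * u2
      dd_add <- rowsum(contrib, grp, reorder = FALSE)       # B x (J*d)
      dd_r <- dd_r + array(dd_add, c(B, J, d))
      dflat <- matrix(ic$d_arr, B, J * d)
      du2 <- du2 + db_log[, jd_j, drop = FALSE] * dflat[grp, , drop = FALSE]
    }
    ds_arr <- squash_arr_bwd(dd_r, ic$s_arr, ic$sq, variant)
    # s_j = sum_i c_ij u_ij
    ds2 <- matrix(ds_arr, B, J * d)
    ds_rep <- ds2[grp, , drop = FALSE]
    dcpl <- rowSums(array(ds_rep * u2, c(B * I, J, d)), dims = 2L)
    du2 <- du2 + ic$cpl[, jd_j, drop = FALSE] * ds_rep
    db_prev <- softmax_rows_bwd(dcpl, ic$cpl)
    if (r < iters) db_prev <- db_prev + db_log # additive carry of b^{r-1}
    db_log <- db_prev
    dd_r <- array(0, c(B, J, d))
  }
  array(du2, dm)
}

#' Dynamic routing between capsule layers
#'
#' Runs the iterative routing-by-agreement procedure: logits start at zero
#' (so the first iteration couples uniformly, `c = 1/J`), and each iteration
#' computes couplings `c = softmax_j(b)`, weighted sums
#' `s_j = sum_i c_ij u_hat_ij`, squashed outputs `d_j`, and the logit update
#' `b_ij <- b_ij + <d_j, u_hat_ij>`.
#'
#' @param u_hat Numeric array (I x J x d) of prediction vectors from the
#'   I input channels to the J output capsules.
#' @param iters Number of routing iterations T (>= 1).
#' @param squash_variant See [squash()].
#' @return List with `d_out` (J x d output capsules), `couplings` (I x J,
#'   from the final iteration; each row sums to 1) and
#'   `coupling_history` (list of I x J matrices, one per iteration).
#' @export
dynamic_routing <- function(u_hat, iters = 3L,
                            squash_variant = c("printed", "standard")) {
  squash_variant <- match.arg(squash_variant)
  if (!is.numeric(iters) || iters < 1) stop("iters must be >= 1", call. = FALSE)
  stopifnot(length(dim(u_hat)) == 3L)
  dm <- dim(u_hat)
  u4 <- array(u_hat, c(1L, dm))
  u4[1L, , , ] <- u_hat
  r <- routing_fwd(u4, as.integer(iters), squash_variant)
  hist <- lapply(r$cache$iter_cache, function(ic) {
    matrix(ic$cpl, dm[1L], dm[2L])
  })
  list(
    d_out = matrix(r$d_out[1L, , ], dm[2L], dm[3L]),
    couplings = matrix(r$couplings[1L, , ], dm[1L], dm[2L]),
    coupling_history = hist
  )
}

# ---- pooling ablation ---------------------------------------------------

pool_fwd <- function(u_hat, mode, variant) {
  dm <- dim(u_hat)
  B <- dm[1L]; I <- dm[2L]; J <- dm[3L]; d <- dm[4L]
  if (mode == "mean") {
    s_arr <- array(colMeans(aperm(u_hat, c(2L, 1L, 3L, 4L))), c(B, J, d))
    istar <- NULL
  } else {
    s_arr <- array(-Inf, c(B, J, d))
    istar <- array(1L, c(B, J, d))
    for (i in seq_len(I)) {
      ui <- array(u_hat[, i, , ], c(B, J, d))
      upd <- ui > s_arr
      istar[upd] <- i
      s_arr[upd] <- ui[upd]
    }
  }
  sq <- squash_arr_fwd(s_arr, variant)
  list(d_out = sq$y,
       cache = list(s_arr = s_arr, sq = sq, istar = istar, mode = mode,
                    dims = dm, variant = variant))
}

pool_bwd <- function(dd_out, cache) {
  dm <- cache$dims
  B <- dm[1L]; I <- dm[2L]; J <- dm[3L]; d <- dm[4L]
  ds_arr <- squash_arr_bwd(dd_out, cache$s_arr, cache$sq, cache$variant)
  du <- array(0, dm)
  if (cache$mode == "mean") {
    for (i in seq_len(I)) du[, i, , ] <- ds_arr / I
  } else {
    lin_bjd <- seq_len(B * J * d)
    bi <- ((lin_bjd - 1L) %% B) + 1L
    jj <- (((lin_bjd - 1L) %/% B) %% J) + 1L
    dd_i <- ((lin_bjd - 1L) %/% (B * J)) + 1L
    lin4 <- bi + B * (as.vector(cache$istar) - 1L) + B * I * (jj - 1L) +
      B * I * J * (dd_i - 1L)
    du[lin4] <- as.vector(ds_arr)
  }
  du
}

#' Pool capsule predictions without routing
#'
#' Ablation of dynamic routing: collapses the input-channel axis by
#' elementwise max or mean, then squashes so outputs live on the same norm
#' scale as routed capsules.
#'
#' @param u_hat Numeric array (I x J x d).
#' @param mode `"max"` or `"mean"`.
#' @param squash_variant See [squash()].
#' @return J x d matrix of output capsules.
#' @export
pool_capsules <- function(u_hat, mode = c("max", "mean"),
                          squash_variant = c("printed", "standard")) {
  mode <- match.arg(mode)
  squash_variant <- match.arg(squash_variant)
  stopifnot(length(dim(u_hat)) == 3L)
  dm <- dim(u_hat)
  u4 <- array(0, c(1L, dm))
  u4[1L, , , ] <- u_hat
  r <- pool_fwd(u4, mode, squash_variant)
  matrix(r$d_out[1L, , ], dm[2L], dm[3L])
}
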