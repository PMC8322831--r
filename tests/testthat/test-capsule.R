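test_that("printed squash has the exact closed form and norm", {
  y <- squash(c(3, 4), "printed")
  expect_equal(y, c(0.5, 2 / 3), tolerance = 1e-13)
  expect_equal(sqrt(sum(y^2)), 5 / 6, tolerance = 1e-13)
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
})

test_that("squash output norm is bounded by 1 and increasing in the input norm", {
  set.seed(1)
  for (variant in c("printed", "standard")) {
    dirs <- matrix(rnorm(40), 10, 4)
    radii <- sort(10^runif(10, -3, 3))
    norms <- vapply(radii, function(r) {
      sqrt(sum(squash(r * dirs[1, ] / sqrt(sum(dirs[1, ]^2)), variant)^2))
    }, 0)
    expect_true(all(norms < 1))
    expect_true(all(diff(norms) > 0))
    # printed: norm is exactly r/(1+r); standard: r^2/(1+r^2)
    want <- if (variant == "printed") radii / (1 + radii)
            else radii^2 / (1 + radii^2)
    expect_equal(norms, want, tolerance = 1e-10)
  }
})

test_that("one routing iteration reduces to squashed uniform coupling", {
  set.seed(2)
  I <- 5L; J <- 3L; d <- 4L
  u <- array(rnorm(I * J * d), c(I, J, d))
  r <- dynamic_routing(u, iters = 1)
  for (j in seq_len(J)) {
    s_j <- colSums(u[, j, ]) / J # uniform couplings softmax(0) = 1/J
    expect_equal(r$d_out[j, ], oracle_squash(s_j), tolerance = 1e-12)
  }
  expect_true(all(abs(r$couplings - 1 / J) < 1e-12))
})

test_that("a single input and output capsule routes through squash with coupling 1", {
  u <- array(rnorm(6), c(1, 1, 6))
  for (iters in c(1, 3, 5)) {
    r <- dynamic_routing(u, iters)
    expect_equal(r$d_out[1, ], oracle_squash(u[1, 1, ]), tolerance = 1e-12)
    expect_equal(r$couplings[1, 1], 1)
  }
})

test_that("vectorized routing equals the scalar triple-loop reference (20 cases)", {
  for (case in 1:20) {
    set.seed(300 + case)
    I <- 4L; J <- 3L; d <- 5L
    u <- array(rnorm(I * J * d), c(I, J, d))
    got <- dynamic_routing(u, iters = 3)
    want <- oracle_routing(u, iters = 3)
    expect_lt(max(abs(got$d_out - want$d_out)), 1e-8)
    expect_lt(max(abs(got$couplings - want$couplings)), 1e-8)
  }
})

test_that("couplings stay normalized and strictly inside (0,1) at every iteration", {
  set.seed(4)
  u <- array(rnorm(6 * 4 * 5, sd = 2), c(6, 4, 5))
  r <- dynamic_routing(u, iters = 4)
  for (cpl in r$coupling_history) {
    expect_equal(rowSums(cpl), rep(1, 6), tolerance = 1e-6)
    expect_true(all(cpl > 0 & cpl < 1))
  }
  # outputs deterministic: repeated calls agree bit-for-bit
  expect_identical(r, dynamic_routing(u, iters = 4))
  expect_true(all(sqrt(rowSums(r$d_out^2)) < 1))
  expect_error(dynamic_routing(u, iters = 0), "iters")
})

test_that("capsule features have I x J x d shape with the published capsule sizes", {
  set.seed(5)
  B <- 1L; n <- 8L; D <- 4L; I <- 4L; cd <- 5L; J <- 6L; d <- 50L
  params <- list(
    w_conv = matrix(rnorm(3 * D * I * cd, sd = 0.2), 3 * D, I * cd),
    b_conv = rnorm(I * cd, sd = 0.1),
    k_caps = matrix(rnorm(cd * J * d, sd = 0.2), cd, J * d),
    b_caps = rnorm(d, sd = 0.1),
    conv_width = 3L, conv_channels = I, n_capsules = J, capsule_dim = d
  )
  s_seq <- array(rnorm(B * n * D), c(B, n, D))
  u <- capsule_features(s_seq, matrix(1, B, n), params, "relu")
  expect_equal(dim(u), c(B, I, J, d))
  expect_error(
    capsule_features(s_seq[, 1:2, , drop = FALSE], matrix(1, B, 2), params),
    "shorter than kernel width"
  )
})

test_that("zero inputs and biases give all-zero predictions for odd activations", {
  params <- list(
    w_conv = matrix(rnorm(6 * 4), 6, 4), b_conv = numeric(4),
    k_caps = matrix(rnorm(2 * 6), 2, 6), b_caps = numeric(3),
    conv_width = 3L, conv_channels = 2L, n_capsules = 2L, capsule_dim = 3L
  )
  u <- capsule_features(array(0, c(1, 5, 2)), matrix(1, 1, 5), params, "tanh")
  expect_true(all(u == 0))
})

test_that("capsule features match the scalar loop reference under masking", {
  for (case in 1:5) {
    set.seed(400 + case)
    B <- 2L; n <- 6L; D <- 3L; I <- 2L; cd <- 3L; J <- 2L; d <- 3L
    params <- list(
      w_conv = matrix(rnorm(3 * D * I * cd), 3 * D, I * cd),
      b_conv = rnorm(I * cd),
      k_caps = matrix(rnorm(cd * J * d), cd, J * d),
      b_caps = rnorm(d),
      conv_width = 3L, conv_channels = I, n_capsules = J, capsule_dim = d
    )
    mask <- rbind(c(1, 1, 1, 1, 0, 0), rep(1, 6))
    s_seq <- array(rnorm(B * n * D), c(B, n, D))
    for (b in 1:B) s_seq[b, mask[b, ] == 0, ] <- 0 # padded positions are zero
    got <- capsule_features(s_seq, mask, params, "relu")
    want <- oracle_capsule_features(s_seq, mask, params, "relu")
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("pooling ablations reduce correctly in degenerate and random cases", {
  set.seed(6)
  u1 <- array(rnorm(8), c(1, 2, 4))
  expect_equal(pool_capsules(u1, "max"),
               rbind(oracle_squash(u1[1, 1, ]), oracle_squash(u1[1, 2, ])),
               tolerance = 1e-12)
  expect_equal(pool_capsules(u1, "mean"), pool_capsules(u1, "max"))

  # mean of u and -u cancels to the zero capsule
  u <- array(rnorm(12), c(1, 2, 6))
  u2 <- array(0, c(2, 2, 6))
  u2[1, , ] <- u[1, , ]; u2[2, , ] <- -u[1, , ]
  expect_equal(pool_capsules(u2, "mean"), matrix(0, 2, 6))

  # max mode equals the brute-force elementwise maximum
  u3 <- array(rnorm(24), c(3, 2, 4))
  got <- pool_capsules(u3, "max")
  for (j in 1:2) {
    mx <- apply(u3[, j, ], 2, max)
    expect_equal(got[j, ], oracle_squash(mx), tolerance = 1e-12)
  }
  expect_error(pool_capsules(u3, "median"), "arg")
})

test_that("routing gradients agree with finite differences", {
  set.seed(7)
  I <- 3L; J <- 2L; d <- 4L
  u <- array(rnorm(I * J * d), c(1, I, J, d))
  w <- array(rnorm(J * d), c(1, J, d)) # fixed projection making a scalar loss
  loss <- function(u) {
    r <- capstm:::routing_fwd(u, 3L, "printed")
    sum(r$d_out * w) + sum(tanh(r$d_out))
  }
  fwd <- capstm:::routing_fwd(u, 3L, "printed")
  dd <- w + (1 - tanh(fwd$d_out)^2)
  ana <- capstm:::routing_bwd(dd, fwd$cache)
  num <- num_grad(loss, u)
  rel <- abs(num - ana) / pmax(1e-6, abs(num) + abs(ana))
  expect_lt(max(rel), 1e-4)
})

test_that("pooling gradients agree with finite differences in both modes", {
  set.seed(8)
  u <- array(rnorm(1 * 3 * 2 * 4), c(1, 3, 2, 4))
  for (mode in c("max", "mean")) {
    fwd <- capstm:::pool_fwd(u, mode, "printed")
    dd <- array(rnorm(8), c(1, 2, 4))
    ana <- capstm:::pool_bwd(dd, fwd$cache)
    num <- num_grad(function(x) {
      sum(capstm:::pool_fwd(x, mode, "printed")$d_out * dd)
    }, u)
    rel <- abs(num - ana) / pmax(1e-6, abs(num) + abs(ana))
    expect_lt(max(rel), 1e-4)
  }
})
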