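# Brute-force loop oracles for every network block, on tensors small
# enough to enumerate.

# reference convolution: out[n, c, t] = sum_{b,l} W[n, b, l] * xpad[b, c, t+l-1]
oracle_conv <- function(xfb, W, bias, padding = "same") {
  d <- dim(xfb); Nb <- d[1]; C <- d[2]; T_len <- d[3]
  N <- dim(W)[1]; L <- dim(W)[3]
  if (padding == "same") {
    pad_l <- (L - 1) %/% 2
    xp <- array(0, c(Nb, C, T_len + L - 1))
    xp[, , pad_l + seq_len(T_len)] <- xfb
    T1 <- T_len
  } else {
    xp <- xfb; T1 <- T_len - L + 1
  }
  out <- array(0, c(N, C, T1))
  for (n in 1:N) for (c in 1:C) for (t in 1:T1) {
    acc <- 0
    for (b in 1:Nb) for (l in 1:L) acc <- acc + W[n, b, l] * xp[b, c, t + l - 1]
    out[n, c, t] <- acc + bias[n]
  }
  out
}

test_that("dynamic convolution matches the sliding-dot-product oracle", {
  # 1-band 1-channel toy with hand-set kernel, normalization bypassed
  x <- array(c(1, 2, 3, 4), c(1, 1, 4))
  bank <- list(weights = array(c(2, -1), c(1, 1, 1, 2)),
               biases = matrix(0.5, 1, 1))
  fw <- dynamic_conv_forward(x, bank, activation = "identity")
  W <- array(c(2, -1), c(1, 1, 2))
  expect_equal(fw$xtf, oracle_conv(x, W, 0.5), tolerance = 1e-12)
  expect_equal(fw$pi, 1)

  # random small tensor, K = 2 with SE branch
  set.seed(21)
  x2 <- array(rnorm(2 * 3 * 8), c(2, 3, 8))
  bank2 <- list(weights = array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)),
                biases = matrix(rnorm(4), 2, 2))
  se <- list(w1 = matrix(rnorm(4), 2, 2), w2 = matrix(rnorm(4), 2, 2))
  fw2 <- dynamic_conv_forward(x2, bank2, se, tau_d = 0.8,
                              activation = "identity")
  pi_o <- se_attention_weights(x2, se$w1, se$w2, 0.8)
  Weff <- pi_o[1] * array(bank2$weights[1, , , ], c(2, 2, 3)) +
    pi_o[2] * array(bank2$weights[2, , , ], c(2, 2, 3))
  beff <- as.numeric(crossprod(bank2$biases, pi_o))
  expect_equal(fw2$xtf, oracle_conv(x2, Weff, beff), tolerance = 1e-10)
  expect_equal(sum(fw2$pi), 1, tolerance = 1e-6)

  # ELU of zero kernels and biases is zero
  z <- dynamic_conv_forward(x2, list(weights = array(0, c(1, 2, 2, 3)),
                                     biases = matrix(0, 1, 2)))
  expect_true(all(z$xtf == 0))

  # 'valid' padding shortens the time axis
  fv <- dynamic_conv_forward(x2, bank2, se, padding = "valid",
                             activation = "identity")
  expect_equal(dim(fv$xtf), c(2, 3, 8 - 3 + 1))
})

test_that("spatial convolution matches the explicit contraction oracle", {
  set.seed(22)
  xtf <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  filters <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  out <- spatial_conv_forward(xtf, filters, activation = "identity")
  oracle <- matrix(0, 4, 5)
  for (m in 1:4) for (t in 1:5) {
    acc <- 0
    for (n in 1:2) for (c in 1:3) acc <- acc + filters[m, n, c] * xtf[n, c, t]
    oracle[m, t] <- acc
  }
  expect_equal(out, oracle, tolerance = 1e-10)

  # indicator filter selects a single (map, electrode) series
  ind <- array(0, c(1, 2, 3))
  ind[1, 2, 3] <- 1
  sel <- spatial_conv_forward(xtf, ind)
  expect_equal(as.numeric(sel), ifelse(xtf[2, 3, ] > 0, xtf[2, 3, ],
                                       exp(xtf[2, 3, ]) - 1),
               tolerance = 1e-12)
  # zero filters -> ELU(0) = 0
  expect_true(all(spatial_conv_forward(xtf, array(0, c(2, 2, 3))) == 0))
})

test_that("windowed variances use the population divisor and floor window count", {
  v <- window_variances(matrix(c(1, 2, 3, 4), 1, 4), w = 2)
  expect_equal(v$n, 2)
  expect_equal(as.numeric(v$v), c(0.25, 0.25))
  expect_equal(as.numeric(v$means), c(1.5, 3.5))
  # constant series -> zero variance
  expect_true(all(window_variances(matrix(7, 2, 10), 5)$v == 0))
  # remainder samples are discarded
  v2 <- window_variances(matrix(c(0, 2, 0, 2, 99), 1, 5), w = 2)
  expect_equal(v2$n, 2)
  expect_equal(as.numeric(v2$v), c(1, 1))
  expect_equal(window_variances(matrix(0, 1, 800), 25)$n, 32)
  expect_error(window_variances(matrix(0, 1, 10), 11), "exceeds")
  expect_true(all(window_variances(matrix(rnorm(40), 2, 20), 5)$v >= 0))
})

test_that("temporal attention matches the scalar oracle and is convex", {
  set.seed(23)
  # U constant per row -> uniform attention -> per-channel mean variance
  v <- matrix(rnorm(4 * 3)^2, 4, 3)
  out_u <- temporal_attention(v, matrix(2, 2, 3), h = 2)
  expect_equal(out_u, rowMeans(v), tolerance = 1e-12)
  # constant variances are preserved under any attention matrix
  vc <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  expect_equal(temporal_attention(vc, matrix(rnorm(6), 2, 3), h = 2),
               c(1, 2, 3, 4), tolerance = 1e-12)
  # hand oracle, m = 4, h = 2, n = 3
  U <- matrix(c(0.1, -0.4, 1.2, 0.3, -0.2, 0.8), 2, 3)
  A <- t(apply(U, 1, function(r) exp(r) / sum(exp(r))))
  oracle <- vapply(1:4, function(c) sum(A[(c - 1) %% 2 + 1, ] * v[c, ]),
                   numeric(1))
  expect_equal(temporal_attention(v, U, h = 2), oracle, tolerance = 1e-12)
  # raw mode applies unnormalized entries
  oracle_raw <- vapply(1:4, function(c) sum(U[(c - 1) %% 2 + 1, ] * v[c, ]),
                       numeric(1))
  expect_equal(temporal_attention(v, U, h = 2, softmax = FALSE), oracle_raw,
               tolerance = 1e-12)
})
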