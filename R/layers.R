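# Block-level operations on a single sample. These are the reference
# implementations of the network blocks; the batched training path in
# forward.R reuses the same primitives.

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad_from_out <- function(out) ifelse(out > 0, 1, out + 1)

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# column-wise softmax of a matrix
softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), "-")
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

# row-wise softmax
softmax_rows <- function(Z) t(softmax_cols(t(Z)))

# im2col gather index for time-axis convolution over a padded (Nb, C, Tp)
# array: row (b-1)*L + l, column (c-1)*T + t  ->  xpad[b, c, t + l - 1]
make_im2col_index <- function(Nb, C, T_len, L) {
  Tp <- T_len + L - 1L
  b <- rep(seq_len(Nb), each = L)          # per row
  l <- rep(seq_len(L), times = Nb)
  cc <- rep(seq_len(C), each = T_len)      # per column
  tt <- rep(seq_len(T_len), times = C)
  row_b <- matrix(b, Nb * L, C * T_len)
  row_l <- matrix(l, Nb * L, C * T_len)
  col_c <- matrix(cc, Nb * L, C * T_len, byrow = TRUE)
  col_t <- matrix(tt, Nb * L, C * T_len, byrow = TRUE)
  idx <- (row_b - 1L) + (col_c - 1L) * Nb + (col_t + row_l - 2L) * Nb * C + 1L
  storage.mode(idx) <- "integer"
  idx
}

# pad (Nb, C, T) along time for 'same'/'valid' and return im2col matrix
# (Nb*L) x (C*T1)
im2col_sample <- function(x, L, padding, idx = NULL) {
  d <- dim(x)
  if (padding == "same") {
    pad_l <- (L - 1L) %/% 2L
    Tp <- d[3] + L - 1L
    xp <- array(0, c(d[1], d[2], Tp))
    xp[, , pad_l + seq_len(d[3])] <- x
    T1 <- d[3]
  } else {
    xp <- x
    T1 <- d[3] - L + 1L
  }
  if (is.null(idx)) idx <- make_im2col_index(d[1], d[2], T1, L)
  matrix(xp[idx], d[1] * L, d[2] * T1)
}

# flatten a (K, N, P) kernel array into a list of K (N x P) matrices
kernel_mats <- function(Wk) {
  K <- dim(Wk)[1]
  lapply(seq_len(K), function(k) matrix(Wk[k, , ], dim(Wk)[2], dim(Wk)[3]))
}

#' SE kernel-attention weights
#'
#' The squeeze-and-excitation branch of the dynamic convolution: global
#' average pooling compresses the multi-band tensor across channels and
#' time into a band descriptor `g` (length Nb); two fully connected layers
#' map it to K logits, `z = W2 ReLU(W1 g)`; a temperature-scaled softmax
#' yields the kernel attention weights `pi = softmax(z / tau_d)`, which lie
#' in `[0, 1]` and sum to 1.
#'
#' @param xfb Multi-band tensor `(Nb, C, T)`, or a precomputed descriptor
#'   vector `g` of length Nb.
#' @param w1 Bottleneck x Nb weight matrix.
#' @param w2 K x bottleneck weight matrix.
#' @param tau_d Softmax temperature (> 0).
#' @return Numeric vector `pi` of length K on the probability simplex.
#' @export
se_attention_weights <- function(xfb, w1, w2, tau_d = 1.0) {
  stopifnot(tau_d > 0)
  g <- if (is.null(dim(xfb))) as.numeric(xfb) else pooled_band_means(xfb)
  if (ncol(w1) != length(g)) {
    stop("W1 has ", ncol(w1), " columns but the band descriptor has length ",
         length(g))
  }
  if (ncol(w2) != nrow(w1)) {
    stop("W2 bottleneck dimension ", ncol(w2),
         " does not match W1 output dimension ", nrow(w1))
  }
  z <- as.numeric(w2 %*% pmax(w1 %*% g, 0))
  softmax_vec(z / tau_d)
}

pooled_band_means <- function(xfb) {
  stopifnot(length(dim(xfb)) == 3L)
  apply(xfb, 1L, mean)
}

#' Aggregate parallel kernels with attention weights
#'
#' The per-sample effective kernel and bias of the dynamic convolution:
#' convex combinations of the K basis kernels and biases with weights `pi`.
#'
#' @param bank List with `weights` (array `(K, N, Nb, L)` or flattened
#'   `(K, N, Nb*L)`) and `biases` (K x N matrix).
#' @param pi Attention weights on the simplex (length K).
#' @return List with `weights` (same trailing shape as one basis kernel)
#'   and `bias` (length N).
#' @export
aggregate_kernels <- function(bank, pi) {
  W <- bank$weights
  dW <- dim(W)
  K <- dW[1]
  stopifnot(length(pi) == K)
  if (any(pi < -1e-8) || abs(sum(pi) - 1) > 1e-6) {
    stop("attention weights must lie on the probability simplex")
  }
  flat <- matrix(W, K, prod(dW[-1]))
  eff <- array(as.numeric(crossprod(flat, pi)), dim = dW[-1])
  list(weights = eff, bias = as.numeric(crossprod(bank$biases, pi)))
}

apply_bn_eval <- function(x_mat, gamma, beta, mean, var, eps = 1e-5) {
  # x_mat: features x anything
  (x_mat - mean) / sqrt(var + eps) * gamma + beta
}

#' Dynamic convolution forward pass (single sample)
#'
#' Computes the SE attention weights, aggregates the kernel bank into one
#' effective kernel, and convolves along the time axis only: each of the N
#' output maps sums over the Nb band axis while the channel axis is left
#' untouched, then the bias is added. Batch normalization (evaluation mode,
#' using the supplied running statistics) and ELU activation follow unless
#' disabled.
#'
#' @param xfb Multi-band tensor `(Nb, C, T)`.
#' @param bank Kernel bank, as in [aggregate_kernels()].
#' @param se Optional list with `w1`, `w2`; when `NULL` and `K = 1` the
#'   single kernel is used as-is (static convolution), otherwise `se` is
#'   required.
#' @param tau_d Softmax temperature.
#' @param padding `"same"` (default) or `"valid"`.
#' @param bn Optional list `(gamma, beta, mean, var)` for evaluation-mode
#'   batch normalization; `NULL` skips normalization.
#' @param activation `"elu"` (default) or `"identity"`.
#' @return List with `xtf` (array `(N, C, T1)`) and `pi`.
#' @export
dynamic_conv_forward <- function(xfb, bank, se = NULL, tau_d = 1.0,
                                 padding = c("same", "valid"), bn = NULL,
                                 activation = c("elu", "identity")) {
  padding <- match.arg(padding)
  activation <- match.arg(activation)
  d <- dim(bank$weights)           # (K, N, Nb, L) or (K, N, Nb*L)
  K <- d[1]; N <- d[2]
  if (length(d) == 4L) { Nb <- d[3]; L <- d[4] } else {
    Nb <- dim(xfb)[1]; L <- d[3] %/% Nb
    if (Nb * L != d[3]) stop("kernel bank shape inconsistent with input bands")
  }
  if (dim(xfb)[1] != Nb) {
    stop("input has ", dim(xfb)[1], " bands but kernels expect ", Nb)
  }
  pi <- if (!is.null(se)) {
    se_attention_weights(xfb, se$w1, se$w2, tau_d)
  } else if (K == 1L) 1 else {
    stop("an SE branch is required when K > 1")
  }
  eff <- aggregate_kernels(bank, pi)
  # im2col rows run kernel-tap fastest within each band ((b-1)*L + l), so
  # a (N, Nb, L) kernel must be flattened with L ahead of Nb
  Wmat <- if (length(dim(eff$weights)) == 3L) {
    matrix(aperm(eff$weights, c(1L, 3L, 2L)), N, Nb * L)
  } else {
    matrix(eff$weights, N, Nb * L)
  }
  Xtil <- im2col_sample(xfb, L, padding)
  out <- Wmat %*% Xtil + eff$bias  # bias recycled down rows (one per map)
  if (!is.null(bn)) {
    out <- apply_bn_eval(out, bn$gamma, bn$beta, bn$mean, bn$var)
  }
  if (activation == "elu") out <- elu(out)
  if (!all(is.finite(out))) stop("non-finite activations in dynamic conv")
  C <- dim(xfb)[2]
  T1 <- ncol(out) %/% C
  list(xtf = array(t_to_nct(out, N, C, T1), c(N, C, T1)), pi = pi)
}

# reorder an N x (C*T) matrix (t fastest within channel) to (N, C, T)
t_to_nct <- function(mat, N, C, T1) {
  aperm(array(mat, c(N, T1, C)), c(1L, 3L, 2L))
}

#' Spatial convolution forward pass (single sample)
#'
#' Applies m filters of size C x 1 along the channel dimension: each filter
#' contracts the (N, C) axes at every time point, producing m single-channel
#' time series. Evaluation-mode batch normalization and ELU follow unless
#' disabled.
#'
#' @param xtf Array `(N, C, T1)` from the dynamic convolution block.
#' @param filters Array `(m, N, C)` or matrix `m x (N*C)` (row-major in
#'   `n` fastest, then `c`); no bias.
#' @param bn,activation As in [dynamic_conv_forward()].
#' @return Matrix `m x T1` (the `m x 1 x T1` maps with the unit axis
#'   dropped).
#' @export
spatial_conv_forward <- function(xtf, filters, bn = NULL,
                                 activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  d <- dim(xtf)
  S <- if (length(dim(filters)) == 3L) {
    matrix(filters, dim(filters)[1], prod(dim(filters)[-1]))
  } else filters
  if (ncol(S) != d[1] * d[2]) {
    stop("filters expect ", ncol(S), " inputs but xtf provides ",
         d[1] * d[2], " (N*C)")
  }
  X2 <- matrix(xtf, d[1] * d[2], d[3])   # rows ordered n fastest, then c
  out <- S %*% X2
  if (!is.null(bn)) out <- apply_bn_eval(out, bn$gamma, bn$beta, bn$mean, bn$var)
  if (activation == "elu") out <- elu(out)
  out
}

#' Windowed variance descriptors
#'
#' Splits each of the m time series into `n = floor(T1 / w)` non-overlapping
#' windows of length w (trailing remainder discarded) and computes the
#' population variance (divisor w) of every channel in every window — a
#' local energy descriptor of the signal.
#'
#' @param xsc Matrix `m x T1` (or array `(m, 1, T1)`).
#' @param w Window length in samples; must not exceed T1.
#' @return List with `v` (m x n variance matrix), `means` (m x n) and `n`.
#' @export
window_variances <- function(xsc, w) {
  if (length(dim(xsc)) == 3L) xsc <- matrix(xsc, dim(xsc)[1], dim(xsc)[3])
  m <- nrow(xsc); T1 <- ncol(xsc)
  if (w > T1) stop("window length w = ", w, " exceeds T1 = ", T1)
  n <- T1 %/% w
  xs <- array(xsc[, seq_len(n * w), drop = FALSE], c(m, w, n))
  mu <- apply(xs, c(1L, 3L), mean)
  msq <- apply(xs^2, c(1L, 3L), mean)
  list(v = pmax(msq - mu^2, 0), means = mu, n = n)
}

#' Group-wise temporal attention
#'
#' The m channels are split into m/h groups of h channels; one shared
#' `h x n` attention matrix scores the n windows of each group-local
#' channel. By default each row of the matrix is normalized with a softmax
#' over the window axis, so every output is a convex combination of that
#' channel's window variances:
#' `xout(c) = sum_q A((c-1) mod h + 1, q) * v(c, q)`.
#'
#' @param v Variance matrix m x n (or the list from [window_variances()]).
#' @param U Attention matrix h x n, shared across groups.
#' @param h Group size; must divide m.
#' @param softmax Row-wise softmax normalization of `U` (default TRUE);
#'   `FALSE` applies the raw entries.
#' @return Numeric vector `xout` of length m.
#' @export
temporal_attention <- function(v, U, h, softmax = TRUE) {
  if (is.list(v)) v <- v$v
  m <- nrow(v); n <- ncol(v)
  stopifnot(nrow(U) == h, ncol(U) == n)
  if (m %% h != 0L) stop("h = ", h, " must divide m = ", m)
  A <- if (isTRUE(softmax)) softmax_rows(U) else U
  gidx <- ((seq_len(m) - 1L) %% h) + 1L
  rowSums(A[gidx, , drop = FALSE] * v)
}
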