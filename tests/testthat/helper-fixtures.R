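# Shared fixture builders. Everything is generated in code at test time.

# a small configuration exercising every block with non-trivial shapes
toy_config <- function(...) {
  dcamnet_config(C = 3, T_len = 20, Nb = 2, K = 2, N = 4, L = 5, r = 1,
                 m = 4, w = 5, h = 2, dropout = 0, ...)
}

# random multi-band tensors matching a config
toy_tensors <- function(cfg, B, seed = 99) {
  set.seed(seed)
  lapply(seq_len(B), function(i) {
    array(rnorm(cfg$Nb * cfg$C * cfg$T_len), c(cfg$Nb, cfg$C, cfg$T_len))
  })
}

# build the (Xtil, G) batch representation used by the internal forward
toy_batch <- function(cfg, B, seed = 99) {
  xs <- toy_tensors(cfg, B, seed)
  idx <- dcamnet:::make_im2col_index(cfg$Nb, cfg$C, cfg$T1, cfg$L)
  list(Xtil = lapply(xs, dcamnet:::im2col_sample, L = cfg$L,
                     padding = cfg$padding, idx = idx),
       G = vapply(xs, dcamnet:::pooled_band_means, numeric(cfg$Nb)),
       tensors = xs)
}

# pure sinusoid epoch, one frequency on all channels
sine_epoch <- function(freq, fs, seconds, C = 1, amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  matrix(rep(amp * sin(2 * pi * freq * t), each = C), nrow = C)
}

# steady-state amplitude of a sinusoid: least-squares fit of sin/cos over
# the central half, where filter edge transients have decayed
stable_amplitude <- function(x, freq, fs) {
  n <- length(x)
  idx <- seq(ceiling(n / 4), floor(3 * n / 4))
  t <- (idx - 1) / fs
  fit <- stats::lm(x[idx] ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# band power via periodogram (independent oracle for generator tests)
fft_band_power <- function(x, fs, low, high) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= low & f <= high & f <= fs / 2
  2 * sum(sp[sel])
}

# per-subject LOSO accuracies printed for the 21-fold cross-validation
# of the reference study (used as inputs to worked-example checks)
published_loso_accuracies <- function() {
  c(91.53, 87.24, 82.16, 89.71, 84.38, 78.45, 86.92,
    90.18, 83.67, 88.54, 91.06, 79.33, 85.71, 82.89,
    73.26, 86.41, 88.07, 80.52, 87.63, 84.19, 81.94)
}
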