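#' DCAMNet configuration
#'
#' Collects the architecture hyperparameters. Defaults follow the reference
#' configuration: `K = 4` parallel kernels of length `L = 64` producing
#' `N = 16` feature maps, SE reduction ratio `r = 4` (bottleneck
#' `max(1, floor(Nb / r))`), softmax temperature `tau_d = 1`, `m = 16`
#' spatial filters, temporal windows of `w = 25` samples with `h = 4` group
#' channels, two output classes and dropout 0.5 before the classifier.
#'
#' @param C Number of EEG channels.
#' @param T_len Number of time samples per epoch.
#' @param Nb Number of filter-bank bands (default 9).
#' @param K Number of parallel convolution kernels.
#' @param N Number of output feature maps of the dynamic convolution.
#' @param L Kernel length along the time axis.
#' @param r SE reduction ratio; the bottleneck is `max(1, floor(Nb / r))`.
#' @param tau_d Softmax temperature for the kernel attention (> 0); smaller
#'   values concentrate mass on fewer kernels.
#' @param m Number of spatial filters.
#' @param w Temporal window length in samples.
#' @param h Group size of the temporal attention (must divide the number of
#'   channels entering the temporal block).
#' @param Nc Number of classes.
#' @param dropout Dropout rate before the fully connected head.
#' @param padding `"same"` (zero padding, output length `T1 = T`; default)
#'   or `"valid"` (`T1 = T - L + 1`).
#' @param attention_softmax Apply row-wise softmax over the window axis of
#'   the temporal attention matrix before the weighted sum (default TRUE);
#'   `FALSE` uses the raw matrix entries.
#' @return A `dcamnet_config` object (also records `T1`, `n_windows` and
#'   `bottleneck`).
#' @export
dcamnet_config <- function(C, T_len, Nb = 9L, K = 4L, N = 16L, L = 64L,
                           r = 4L, tau_d = 1.0, m = 16L, w = 25L, h = 4L,
                           Nc = 2L, dropout = 0.5,
                           padding = c("same", "valid"),
                           attention_softmax = TRUE) {
  padding <- match.arg(padding)
  stopifnot(C >= 1, T_len >= 1, Nb >= 1, K >= 1, N >= 1, L >= 1,
            r >= 1, tau_d > 0, m >= 1, w >= 1, h >= 1, Nc >= 2,
            dropout >= 0, dropout < 1)
  T1 <- if (padding == "same") T_len else T_len - L + 1L
  if (T1 < 1L) stop("kernel length L = ", L, " exceeds T = ", T_len,
                    " under 'valid' padding")
  if (w > T1) stop("window length w = ", w, " exceeds T1 = ", T1)
  if (m %% h != 0L) stop("h = ", h, " must divide m = ", m)
  cfg <- list(C = as.integer(C), T_len = as.integer(T_len),
              Nb = as.integer(Nb), K = as.integer(K), N = as.integer(N),
              L = as.integer(L), r = as.integer(r), tau_d = tau_d,
              m = as.integer(m), w = as.integer(w), h = as.integer(h),
              Nc = as.integer(Nc), dropout = dropout, padding = padding,
              attention_softmax = isTRUE(attention_softmax),
              T1 = as.integer(T1),
              n_windows = as.integer(T1 %/% w),
              bottleneck = max(1L, as.integer(Nb) %/% as.integer(r)))
  structure(cfg, class = "dcamnet_config")
}

#' @export
print.dcamnet_config <- function(x, ...) {
  cat(sprintf(paste0("DCAMNet config: C=%d T=%d Nb=%d | K=%d N=%d L=%d r=%d ",
                     "(bottleneck %d) tau_d=%g | m=%d w=%d h=%d -> %d windows",
                     " | Nc=%d dropout=%g padding=%s\n"),
              x$C, x$T_len, x$Nb, x$K, x$N, x$L, x$r, x$bottleneck, x$tau_d,
              x$m, x$w, x$h, x$n_windows, x$Nc, x$dropout, x$padding))
  invisible(x)
}

dcamnet_variants <- c("full", "static_K1", "no_spatial", "no_temporal",
                      "minimal")

# channels entering the temporal block / features entering the FC head
variant_dims <- function(cfg, variant) {
  switch(variant,
    full        = list(temporal_ch = cfg$m, head = cfg$m),
    static_K1   = list(temporal_ch = cfg$m, head = cfg$m),
    no_spatial  = list(temporal_ch = cfg$N, head = cfg$N),
    no_temporal = list(temporal_ch = NA_integer_, head = cfg$m),
    minimal     = list(temporal_ch = NA_integer_, head = cfg$N),
    stop("unknown variant '", variant, "'; choose one of: ",
         paste(dcamnet_variants, collapse = ", "))
  )
}

variant_has <- function(variant) {
  list(dynamic  = variant %in% c("full"),
       spatial  = variant %in% c("full", "static_K1", "no_temporal"),
       temporal = variant %in% c("full", "static_K1", "no_spatial"))
}

runif_fan_in <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Initialize a DCAMNet model
#'
#' Creates the weight tensors for the requested architecture variant, using
#' fan-in-scaled uniform initialization (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`)
#' for convolutional and linear weights, zeros for biases and batch-norm
#' shifts, ones for batch-norm scales. Fully seeded.
#'
#' @param cfg A [dcamnet_config()].
#' @param seed Integer seed for the weight draw.
#' @param variant One of `"full"`, `"static_K1"` (single static kernel, no
#'   SE branch), `"no_spatial"` (spatial block removed, channel-mean pooling
#'   before the temporal block), `"no_temporal"` (temporal attention
#'   replaced by global average pooling over time) or `"minimal"` (static
#'   convolution + classifier only).
#' @return A `dcamnet_model` object.
#' @export
dcamnet_init <- function(cfg, seed = 0L, variant = "full") {
  stopifnot(inherits(cfg, "dcamnet_config"))
  if (!variant %in% dcamnet_variants) {
    stop("unknown variant '", variant, "'; choose one of: ",
         paste(dcamnet_variants, collapse = ", "))
  }
  has <- variant_has(variant)
  K <- if (has$dynamic) cfg$K else 1L
  vd <- variant_dims(cfg, variant)
  if (has$temporal && vd$temporal_ch %% cfg$h != 0L) {
    stop("h = ", cfg$h, " must divide the ", vd$temporal_ch,
         " channels entering the temporal block for variant '", variant, "'")
  }
  set.seed(seed)
  p <- list()
  p$Wk <- runif_fan_in(c(K, cfg$N, cfg$Nb * cfg$L), cfg$Nb * cfg$L)
  p$bk <- matrix(0, K, cfg$N)
  if (has$dynamic) {
    p$se_w1 <- runif_fan_in(c(cfg$bottleneck, cfg$Nb), cfg$Nb)
    p$se_w2 <- runif_fan_in(c(K, cfg$bottleneck), cfg$bottleneck)
  }
  p$bn1_gamma <- rep(1, cfg$N)
  p$bn1_beta <- rep(0, cfg$N)
  if (has$spatial) {
    p$S <- runif_fan_in(c(cfg$m, cfg$N * cfg$C), cfg$N * cfg$C)
    p$bn2_gamma <- rep(1, cfg$m)
    p$bn2_beta <- rep(0, cfg$m)
  }
  if (has$temporal) {
    p$U <- runif_fan_in(c(cfg$h, cfg$n_windows), cfg$n_windows)
  }
  p$FC <- runif_fan_in(c(cfg$Nc, vd$head), vd$head)
  model <- list(cfg = cfg, variant = variant, params = p,
                bn1_mean = rep(0, cfg$N), bn1_var = rep(1, cfg$N),
                trained = FALSE, seed = as.integer(seed))
  if (has$spatial) {
    model$bn2_mean <- rep(0, cfg$m)
    model$bn2_var <- rep(1, cfg$m)
  }
  structure(model, class = "dcamnet_model")
}

#' @export
print.dcamnet_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("DCAMNet model (variant %s): %d trainable values, %strained\n",
              x$variant, n_par, if (x$trained) "" else "un"))
  print(x$cfg)
  invisible(x)
}

#' Build an ablation variant from an existing configuration
#'
#' Returns a freshly initialized model of the requested variant sharing the
#' configuration (a model may be passed; its config and seed are reused
#' unless overridden).
#'
#' @param x A `dcamnet_config` or `dcamnet_model`.
#' @param variant See [dcamnet_init()].
#' @param seed Seed for the new weight draw; defaults to the model's seed
#'   (or 0 for a bare config).
#' @return A `dcamnet_model`.
#' @export
make_ablation_variant <- function(x, variant, seed = NULL) {
  if (inherits(x, "dcamnet_model")) {
    if (is.null(seed)) seed <- x$seed
    return(dcamnet_init(x$cfg, seed, variant))
  }
  stopifnot(inherits(x, "dcamnet_config"))
  dcamnet_init(x, if (is.null(seed)) 0L else seed, variant)
}

#' Per-layer parameter counts
#'
#' Reports the closed-form layer parameter counts for a configuration
#' under two conventions: the layer-table convention — dynamic convolution
#' `K*N*(Nb*L + 1)` (weights plus one bias per kernel-map), spatial
#' `m*N*C` (no bias), temporal attention `h*floor(T1/w)`, fully connected
#' `Nc*m` (no bias) — and a full-framework count that additionally includes
#' the SE branch (`bottleneck*Nb + K*bottleneck`) and the batch-norm affine
#' parameters (`2N + 2m`).
#'
#' @param cfg A [dcamnet_config()].
#' @return A list with `table` (data frame of layer counts), `table_total`
#'   (layer-table convention) and `full_total`.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "dcamnet_config"))
  n <- cfg$n_windows
  rows <- data.frame(
    layer = c("dynamic_conv", "spatial_conv", "temporal_attention",
              "fully_connected", "se_branch", "batch_norm"),
    count = c(cfg$K * cfg$N * (cfg$Nb * cfg$L + 1L),
              cfg$m * cfg$N * cfg$C,
              cfg$h * n,
              cfg$Nc * cfg$m,
              cfg$bottleneck * cfg$Nb + cfg$K * cfg$bottleneck,
              2L * cfg$N + 2L * cfg$m),
    stringsAsFactors = FALSE
  )
  tab_total <- sum(rows$count[1:4])
  list(table = rows, table_total = tab_total,
       full_total = tab_total + sum(rows$count[5:6]))
}

#' Parameter count of a dense (fully connected) layer
#'
#' Utility for closed-form parameter accounting of dense baselines, e.g.
#' a first layer mapping a flattened `17 x 800` epoch (13,600 inputs) to
#' 256 units carries about 3.48 M weights.
#'
#' @param n_in,n_out Input and output dimensions.
#' @param bias Include one bias per output unit (default TRUE).
#' @return Integer parameter count.
#' @export
dense_layer_params <- function(n_in, n_out, bias = TRUE) {
  n_in * n_out + if (isTRUE(bias)) n_out else 0L
}
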