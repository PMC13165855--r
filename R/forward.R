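# Batched network forward/backward. The batch representation is a list of
# precomputed im2col matrices (one per sample) plus the Nb x B matrix of
# pooled band descriptors; prepare_model_inputs() builds both from an
# eeg_dataset so the expensive gather work is done once per dataset.

#' Prepare network inputs from a dataset
#'
#' Runs the filter-bank decomposition on every epoch and precomputes the
#' im2col expansion of each multi-band tensor together with the pooled band
#' descriptor the SE branch consumes. Optionally keeps the raw multi-band
#' tensors (needed for band-masking analyses) and can zero all but a subset
#' of bands before expansion.
#'
#' @param dataset An [eeg_dataset()].
#' @param cfg A [dcamnet_config()] whose `C`, `T_len` match the dataset.
#' @param spec Filter bank, default the nine-band bank.
#' @param keep_bands Optional band subset (indices or names) to retain,
#'   zeroing the rest (see [mask_bands()]).
#' @param keep_multiband Keep the decomposed tensors in the result.
#' @param multiband Optional precomputed list of multi-band tensors (skips
#'   the filter-bank step, e.g. when re-masking cached tensors).
#' @return A `dcamnet_inputs` list with elements `Xtil` (list of im2col
#'   matrices), `G` (Nb x B descriptor matrix), `labels`, `subjects`, `n`.
#' @export
prepare_model_inputs <- function(dataset, cfg, spec = default_filter_bank(),
                                 keep_bands = NULL, keep_multiband = FALSE,
                                 multiband = NULL) {
  stopifnot(inherits(cfg, "dcamnet_config"))
  if (is.null(multiband)) {
    stopifnot(inherits(dataset, "eeg_dataset"))
    d <- dim(dataset$epochs[[1]])
    if (d[1] != cfg$C || d[2] != cfg$T_len) {
      stop("dataset epochs are ", d[1], " x ", d[2],
           " but the config expects ", cfg$C, " x ", cfg$T_len)
    }
    if (length(spec$bands) != cfg$Nb) {
      stop("filter bank has ", length(spec$bands),
           " bands but the config expects Nb = ", cfg$Nb)
    }
    multiband <- lapply(dataset$epochs, filter_bank_decompose, spec = spec,
                        fs = dataset$fs)
    labels <- dataset$labels
    subjects <- dataset$subjects
  } else {
    labels <- if (!is.null(dataset)) dataset$labels else NULL
    subjects <- if (!is.null(dataset)) dataset$subjects else NULL
  }
  if (!is.null(keep_bands)) {
    multiband <- lapply(multiband, mask_bands, keep = keep_bands)
  }
  idx <- make_im2col_index(cfg$Nb, cfg$C, cfg$T1, cfg$L)
  Xtil <- lapply(multiband, im2col_sample, L = cfg$L,
                 padding = cfg$padding, idx = idx)
  G <- vapply(multiband, pooled_band_means, numeric(cfg$Nb))
  if (cfg$Nb == 1L) G <- matrix(G, 1L)
  structure(list(Xtil = Xtil, G = G, labels = labels, subjects = subjects,
                 n = length(Xtil), cfg = cfg,
                 multiband = if (keep_multiband) multiband else NULL),
            class = "dcamnet_inputs")
}

subset_inputs <- function(inputs, idx) {
  structure(list(Xtil = inputs$Xtil[idx],
                 G = inputs$G[, idx, drop = FALSE],
                 labels = inputs$labels[idx],
                 subjects = inputs$subjects[idx],
                 n = length(idx), cfg = inputs$cfg,
                 multiband = if (!is.null(inputs$multiband))
                   inputs$multiband[idx] else NULL),
            class = "dcamnet_inputs")
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Full batched forward pass. mode "train" uses batch statistics and
# dropout and returns a cache for the backward pass; "eval" uses running
# statistics and no dropout. Returns running-stat updates separately so the
# caller decides when to commit them.
net_forward <- function(model, Xtil, G, mode = c("eval", "train", "stats")) {
  # "stats" normalizes with batch statistics like training (and reports
  # them raw in the cache) but applies no dropout; used for test-time
  # normalization adaptation
  mode <- match.arg(mode)
  train <- mode %in% c("train", "stats")
  cfg <- model$cfg
  p <- model$params
  has <- variant_has(model$variant)
  vd <- variant_dims(cfg, model$variant)
  B <- length(Xtil)
  N <- cfg$N; CT1 <- cfg$C * cfg$T1; T1 <- cfg$T1; Cn <- cfg$C
  K <- dim(p$Wk)[1]
  cache <- list()

  # --- SE branch -> kernel attention ---------------------------------
  if (has$dynamic) {
    Apre <- p$se_w1 %*% G
    Arelu <- pmax(Apre, 0)
    Z <- p$se_w2 %*% Arelu
    PI <- softmax_cols(Z / cfg$tau_d)
    cache$Apre <- Apre; cache$Arelu <- Arelu
  } else {
    PI <- matrix(1, 1L, B)
  }
  cache$PI <- PI

  # --- dynamic (or static) convolution -------------------------------
  Wmats <- kernel_mats(p$Wk)
  beff <- crossprod(p$bk, PI)              # N x B
  OUT1 <- array(0, c(N, CT1, B))
  for (i in seq_len(B)) {
    Weff <- Wmats[[1L]] * PI[1L, i]
    if (K > 1L) for (k in 2:K) Weff <- Weff + Wmats[[k]] * PI[k, i]
    OUT1[, , i] <- Weff %*% Xtil[[i]] + beff[, i]
  }
  if (!all(is.finite(OUT1))) stop("non-finite activations after convolution")

  # --- batch norm 1 + ELU --------------------------------------------
  M1 <- matrix(OUT1, N, CT1 * B)
  if (train) {
    mu1 <- rowMeans(M1)
    var1 <- rowMeans(M1^2) - mu1^2
    cache$new_bn1 <- list(mean = (1 - bn_momentum) * model$bn1_mean +
                            bn_momentum * mu1,
                          var = (1 - bn_momentum) * model$bn1_var +
                            bn_momentum * var1)
    cache$raw_bn1 <- list(mean = mu1, var = var1)
  } else {
    mu1 <- model$bn1_mean; var1 <- model$bn1_var
  }
  invstd1 <- 1 / sqrt(var1 + bn_eps)
  xhat1 <- (M1 - mu1) * invstd1
  XTF <- elu(xhat1 * p$bn1_gamma + p$bn1_beta)
  cache$xhat1 <- xhat1; cache$invstd1 <- invstd1; cache$XTF <- XTF

  # --- spatial block / channel pooling / global pooling --------------
  if (model$variant == "minimal") {
    XOUT <- vapply(seq_len(B), function(i)
      rowMeans(matrix(XTF[, ((i - 1) * CT1 + 1):(i * CT1)], N, CT1)),
      numeric(N))
    if (N == 1L) XOUT <- matrix(XOUT, 1L)
  } else if (has$spatial) {
    XTF3 <- array(XTF, c(N, CT1, B))
    X2 <- array(0, c(N * Cn, T1, B))
    for (i in seq_len(B)) {
      X2[, , i] <- matrix(aperm(array(XTF3[, , i], c(N, T1, Cn)),
                                c(1L, 3L, 2L)), N * Cn, T1)
    }
    X2m <- matrix(X2, N * Cn, T1 * B)
    OUT2 <- p$S %*% X2m                     # m x (T1*B)
    if (train) {
      mu2 <- rowMeans(OUT2)
      var2 <- rowMeans(OUT2^2) - mu2^2
      cache$new_bn2 <- list(mean = (1 - bn_momentum) * model$bn2_mean +
                              bn_momentum * mu2,
                            var = (1 - bn_momentum) * model$bn2_var +
                              bn_momentum * var2)
      cache$raw_bn2 <- list(mean = mu2, var = var2)
    } else {
      mu2 <- model$bn2_mean; var2 <- model$bn2_var
    }
    invstd2 <- 1 / sqrt(var2 + bn_eps)
    xhat2 <- (OUT2 - mu2) * invstd2
    XSCm <- elu(xhat2 * p$bn2_gamma + p$bn2_beta)
    XSC <- array(XSCm, c(cfg$m, T1, B))
    cache$X2m <- X2m; cache$xhat2 <- xhat2; cache$invstd2 <- invstd2
    cache$XSCm <- XSCm
    mch <- cfg$m
  } else {                                  # no_spatial: mean over channels
    XTF4 <- array(XTF, c(N, T1, Cn, B))
    XSC <- array(0, c(N, T1, B))
    for (ci in seq_len(Cn)) {
      XSC <- XSC + array(XTF4[, , ci, , drop = FALSE], c(N, T1, B)) / Cn
    }
    mch <- N
  }

  # --- temporal block / pooling --------------------------------------
  if (model$variant == "minimal") {
    # XOUT already computed
  } else if (has$temporal) {
    n <- cfg$n_windows; w <- cfg$w
    tmp <- array(XSC[, seq_len(n * w), , drop = FALSE], c(mch, w, n, B))
    WC <- matrix(aperm(tmp, c(2L, 1L, 3L, 4L)), w, mch * n * B)
    muW <- colMeans(WC)
    XC <- WC - rep(muW, each = w)
    Vvec <- colMeans(XC^2)
    V <- matrix(Vvec, mch * n, B)            # rows: channel fastest, then q
    A <- if (cfg$attention_softmax) softmax_rows(p$U) else p$U
    gidx <- ((seq_len(mch) - 1L) %% cfg$h) + 1L
    Afull <- A[gidx, , drop = FALSE]
    XOUT <- rowsum(V * as.vector(Afull), rep(seq_len(mch), n))
    cache$XC <- XC; cache$V <- V; cache$A <- A; cache$Afull <- Afull
    cache$gidx <- gidx; cache$mch <- mch
  } else {                                   # no_temporal: mean over time
    XOUT <- vapply(seq_len(B), function(i) rowMeans(XSC[, , i, drop = FALSE]),
                   numeric(mch))
    if (mch == 1L) XOUT <- matrix(XOUT, 1L)
  }
  if (model$variant != "minimal") cache$XSC <- XSC
  cache$XOUT <- XOUT

  # --- dropout + classifier ------------------------------------------
  if (mode == "train" && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(XOUT), 1L, keep) / keep,
                   nrow(XOUT), B)
    XD <- XOUT * mask
    cache$mask <- mask
  } else {
    XD <- XOUT
  }
  LOGITS <- p$FC %*% XD
  P <- softmax_cols(LOGITS)
  cache$XD <- XD
  list(probs = P, pi = PI,
       cache = if (mode == "train") cache
               else cache[intersect(c("PI", "raw_bn1", "raw_bn2"),
                                    names(cache))])
}

net_loss <- function(P, labels) {
  B <- ncol(P)
  -mean(log(pmax(P[cbind(labels + 1L, seq_len(B))], 1e-12)))
}

# Backward pass; returns gradients named like model$params.
net_backward <- function(model, Xtil, G, cache, P, labels) {
  cfg <- model$cfg
  p <- model$params
  has <- variant_has(model$variant)
  B <- length(Xtil)
  N <- cfg$N; Cn <- cfg$C; T1 <- cfg$T1; CT1 <- Cn * T1
  K <- dim(p$Wk)[1]
  g <- list()

  Y <- matrix(0, cfg$Nc, B)
  Y[cbind(labels + 1L, seq_len(B))] <- 1
  dL <- (P - Y) / B
  g$FC <- dL %*% t(cache$XD)
  dXD <- crossprod(p$FC, dL)
  dXOUT <- if (!is.null(cache$mask)) dXD * cache$mask else dXD

  if (model$variant == "minimal") {
    dXTFm <- matrix(0, N, CT1 * B)
    for (i in seq_len(B)) {
      dXTFm[, ((i - 1) * CT1 + 1):(i * CT1)] <- dXOUT[, i] / CT1
    }
  } else {
    mch <- if (has$spatial) cfg$m else N
    if (has$temporal) {
      n <- cfg$n_windows; w <- cfg$w
      rep_ch <- rep(seq_len(mch), n)
      dV <- dXOUT[rep_ch, , drop = FALSE] * as.vector(cache$Afull)
      dAfull <- matrix(rowSums(cache$V * dXOUT[rep_ch, , drop = FALSE]),
                       mch, n)
      dA <- rowsum(dAfull, cache$gidx)
      if (cfg$attention_softmax) {
        s <- rowSums(dA * cache$A)
        g$U <- (dA - s) * cache$A
      } else {
        g$U <- dA
      }
      dXCw <- cache$XC * rep(as.vector(dV) * 2 / w, each = w)
      arr <- aperm(array(dXCw, c(w, mch, n, B)), c(2L, 1L, 3L, 4L))
      dXSC <- array(0, c(mch, T1, B))
      dXSC[, seq_len(n * w), ] <- array(arr, c(mch, n * w, B))
    } else {                                 # no_temporal
      dXSC <- array(0, c(mch, T1, B))
      for (i in seq_len(B)) dXSC[, , i] <- matrix(dXOUT[, i] / T1, mch, T1)
    }
    if (has$spatial) {
      dXSCm <- matrix(dXSC, cfg$m, T1 * B)
      dPre2 <- dXSCm * elu_grad_from_out(cache$XSCm)
      # batch-norm backward (population statistics)
      dyh <- dPre2 * p$bn2_gamma
      g$bn2_gamma <- rowSums(dPre2 * cache$xhat2)
      g$bn2_beta <- rowSums(dPre2)
      dOUT2 <- cache$invstd2 *
        (dyh - rowMeans(dyh) - cache$xhat2 * rowMeans(dyh * cache$xhat2))
      g$S <- dOUT2 %*% t(cache$X2m)
      dX2m <- crossprod(p$S, dOUT2)
      dX2 <- array(dX2m, c(N * Cn, T1, B))
      dXTFm <- matrix(0, N, CT1 * B)
      for (i in seq_len(B)) {
        dXTFm[, ((i - 1) * CT1 + 1):(i * CT1)] <-
          matrix(aperm(array(dX2[, , i], c(N, Cn, T1)), c(1L, 3L, 2L)),
                 N, CT1)
      }
    } else {                                 # no_spatial channel pooling
      dXTFm <- matrix(0, N, CT1 * B)
      colrep <- rep(seq_len(T1), Cn)
      for (i in seq_len(B)) {
        dXTFm[, ((i - 1) * CT1 + 1):(i * CT1)] <-
          dXSC[, colrep, i, drop = TRUE] / Cn
      }
    }
  }

  dAct1 <- dXTFm * elu_grad_from_out(cache$XTF)
  dyh1 <- dAct1 * p$bn1_gamma
  g$bn1_gamma <- rowSums(dAct1 * cache$xhat1)
  g$bn1_beta <- rowSums(dAct1)
  dOUT1m <- cache$invstd1 *
    (dyh1 - rowMeans(dyh1) - cache$xhat1 * rowMeans(dyh1 * cache$xhat1))
  dOUT1 <- array(dOUT1m, c(N, CT1, B))

  Wmats <- kernel_mats(p$Wk)
  gWk <- lapply(seq_len(K), function(k) matrix(0, N, dim(p$Wk)[3]))
  gbk <- matrix(0, K, N)
  PI <- cache$PI
  dPI <- matrix(0, K, B)
  for (i in seq_len(B)) {
    Di <- matrix(dOUT1[, , i], N, CT1)
    dbeff <- rowSums(Di)
    dWeff <- Di %*% t(Xtil[[i]])
    for (k in seq_len(K)) {
      gWk[[k]] <- gWk[[k]] + PI[k, i] * dWeff
      gbk[k, ] <- gbk[k, ] + PI[k, i] * dbeff
      if (has$dynamic) {
        dPI[k, i] <- sum(Wmats[[k]] * dWeff) + sum(p$bk[k, ] * dbeff)
      }
    }
  }
  g$Wk <- array(0, dim(p$Wk))
  for (k in seq_len(K)) g$Wk[k, , ] <- gWk[[k]]
  g$bk <- gbk

  if (has$dynamic) {
    s <- colSums(dPI * PI)
    dZ <- (dPI - rep(s, each = K)) * PI / cfg$tau_d
    g$se_w2 <- dZ %*% t(cache$Arelu)
    dArelu <- crossprod(p$se_w2, dZ)
    dApre <- dArelu * (cache$Apre > 0)
    g$se_w1 <- dApre %*% t(G)
  }
  g
}

#' Adapt normalization statistics to a new input distribution
#'
#' Recomputes the batch-normalization running statistics of a trained
#' model from a forward pass over the supplied inputs, leaving every
#' learned weight untouched (no labels and no gradient steps are
#' involved). Used when probing a trained network with inputs whose
#' scale differs systematically from the training data, e.g. band-masked
#' tensors.
#'
#' @param model A `dcamnet_model`.
#' @param inputs A `dcamnet_inputs` object.
#' @return The model with refreshed normalization statistics.
#' @export
bn_adapt <- function(model, inputs) {
  fw <- net_forward(model, inputs$Xtil, inputs$G, mode = "stats")
  model$bn1_mean <- fw$cache$raw_bn1$mean
  model$bn1_var <- fw$cache$raw_bn1$var
  if (!is.null(fw$cache$raw_bn2)) {
    model$bn2_mean <- fw$cache$raw_bn2$mean
    model$bn2_var <- fw$cache$raw_bn2$var
  }
  model
}

#' Predict class probabilities
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout). Probabilities sum to one per sample; the predicted class is
#' the argmax, with exact ties broken toward alert (class 0).
#'
#' @param model A `dcamnet_model`.
#' @param inputs A `dcamnet_inputs` object from [prepare_model_inputs()].
#' @param batch_size Samples per forward batch.
#' @return List with `probs` (n x Nc matrix, columns `alert`, `fatigued`),
#'   `class` (integer 0/1) and `pi` (n x K kernel-attention matrix).
#' @export
predict_dcamnet <- function(model, inputs, batch_size = 256L) {
  n <- inputs$n
  K <- dim(model$params$Wk)[1]
  probs <- matrix(0, n, model$cfg$Nc,
                  dimnames = list(NULL, c("alert", "fatigued")[seq_len(model$cfg$Nc)]))
  pis <- matrix(0, n, K)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- net_forward(model, inputs$Xtil[idx],
                      inputs$G[, idx, drop = FALSE], mode = "eval")
    probs[idx, ] <- t(fw$probs)
    pis[idx, ] <- t(fw$pi)
  }
  cls <- as.integer(probs[, 2L] > probs[, 1L])   # tie -> alert
  list(probs = probs, class = cls, pi = pis)
}
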