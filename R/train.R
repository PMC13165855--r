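#' Training configuration
#'
#' Optimizer and schedule defaults: Adam with learning rate 1e-3,
#' `beta1 = 0.9`, `beta2 = 0.999`, weight decay 1e-4 (L2 added to the
#' gradient, applied to all parameters), learning rate halved every 50
#' epochs, up to 300 epochs with batch size 64, early stopping on
#' validation loss with patience 30, 10% of the training data held out for
#' validation.
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 coefficient added to gradients.
#' @param lr_step Epoch interval at which the learning rate is halved.
#' @param lr_factor Multiplier applied every `lr_step` epochs.
#' @param max_epochs Maximum number of epochs.
#' @param batch Mini-batch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param val_fraction Fraction of the training set held out for
#'   validation when the split plan does not already provide one.
#' @param seed Seed controlling model initialization, shuffling and
#'   dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, lr_step = 50L,
                         lr_factor = 0.5, max_epochs = 300L, batch = 64L,
                         patience = 30L, val_fraction = 0.1, seed = 0L) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            weight_decay >= 0, lr_step >= 1, lr_factor > 0,
            max_epochs >= 1, batch >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, lr_step = as.integer(lr_step),
                 lr_factor = lr_factor, max_epochs = as.integer(max_epochs),
                 batch = as.integer(batch), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    gname <- if (nm %in% names(params)) nm else next
    g <- grads[[nm]] + cfg$weight_decay * params[[gname]]
    state$m[[gname]] <- cfg$beta1 * state$m[[gname]] + (1 - cfg$beta1) * g
    state$v[[gname]] <- cfg$beta2 * state$v[[gname]] + (1 - cfg$beta2) * g^2
    params[[gname]] <- params[[gname]] -
      lr * (state$m[[gname]] / bc1) / (sqrt(state$v[[gname]] / bc2) + 1e-8)
  }
  list(params = params, state = state)
}

#' Learning rate at a given epoch under step decay
#'
#' @param epoch 1-based epoch index.
#' @param cfg A [train_config()].
#' @return The learning rate in effect during that epoch (halved after
#'   every `lr_step` completed epochs).
#' @export
lr_at_epoch <- function(epoch, cfg) {
  cfg$lr * cfg$lr_factor^((epoch - 1L) %/% cfg$lr_step)
}

# map backward-gradient names to parameter names (bn gradients come back
# under the same names as the params)
grad_to_param_names <- function(g) {
  names(g)
}

#' Train a DCAMNet model
#'
#' Minimizes the softmax cross-entropy with Adam under a step-decay
#' learning-rate schedule, stopping early when the validation loss has not
#' improved for `patience` consecutive epochs and restoring the
#' best-validation weights. Fully deterministic given `cfg$seed`: the seed
#' drives weight initialization (unless a pre-initialized model is
#' supplied), epoch shuffling and dropout.
#'
#' @param inputs A `dcamnet_inputs` object holding the full dataset.
#' @param train_idx,val_idx Integer indices into `inputs` for the training
#'   and validation sets.
#' @param model_cfg A [dcamnet_config()] (ignored when `model` is given).
#' @param cfg A [train_config()].
#' @param variant Architecture variant, see [dcamnet_init()].
#' @param model Optional pre-initialized `dcamnet_model` to continue from.
#' @param verbose Print per-epoch progress.
#' @return A `dcamnet_fit` list with `model` (best-validation weights,
#'   running batch-norm statistics committed) and `history` (data frame of
#'   epoch, lr, train_loss, val_loss, val_acc).
#' @export
train_dcamnet <- function(inputs, train_idx, val_idx, model_cfg = NULL,
                          cfg = train_config(), variant = "full",
                          model = NULL, verbose = FALSE) {
  stopifnot(inherits(inputs, "dcamnet_inputs"), length(train_idx) >= 1,
            length(val_idx) >= 1)
  if (is.null(model)) {
    stopifnot(inherits(model_cfg, "dcamnet_config"))
    model <- dcamnet_init(model_cfg, seed = cfg$seed, variant = variant)
  }
  labels <- inputs$labels
  if (any(is.na(labels[c(train_idx, val_idx)]))) {
    stop("training/validation samples must be labeled")
  }
  opt <- adam_init(model$params)
  set.seed(cfg$seed + 1L)   # shuffling + dropout stream
  best <- list(loss = Inf, params = model$params,
               bn1_mean = model$bn1_mean, bn1_var = model$bn1_var,
               bn2_mean = model$bn2_mean, bn2_var = model$bn2_var,
               epoch = 0L)
  hist <- list()
  wait <- 0L
  val_in <- subset_inputs(inputs, val_idx)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_at_epoch(epoch, cfg)
    ord <- sample(train_idx)
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch)) {
      bidx <- ord[start:min(start + cfg$batch - 1L, length(ord))]
      fw <- net_forward(model, inputs$Xtil[bidx],
                        inputs$G[, bidx, drop = FALSE], mode = "train")
      loss <- net_loss(fw$probs, labels[bidx])
      if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ",
                                 epoch)
      gr <- net_backward(model, inputs$Xtil[bidx],
                         inputs$G[, bidx, drop = FALSE], fw$cache,
                         fw$probs, labels[bidx])
      upd <- adam_step(model$params, gr, opt, lr, cfg)
      model$params <- upd$params
      opt <- upd$state
      model$bn1_mean <- fw$cache$new_bn1$mean
      model$bn1_var <- fw$cache$new_bn1$var
      if (!is.null(fw$cache$new_bn2)) {
        model$bn2_mean <- fw$cache$new_bn2$mean
        model$bn2_var <- fw$cache$new_bn2$var
      }
      tl <- tl + loss; nb <- nb + 1L
    }
    pv <- predict_dcamnet(model, val_in)
    vl <- net_loss(t(pv$probs), labels[val_idx])
    va <- mean(pv$class == labels[val_idx])
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = tl / nb, val_loss = vl,
                                val_acc = va)
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f acc %.3f",
                      epoch, lr, tl / nb, vl, va))
    }
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = model$params,
                   bn1_mean = model$bn1_mean, bn1_var = model$bn1_var,
                   bn2_mean = model$bn2_mean, bn2_var = model$bn2_var,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$bn1_mean <- best$bn1_mean
  model$bn1_var <- best$bn1_var
  if (!is.null(best$bn2_mean)) {
    model$bn2_mean <- best$bn2_mean
    model$bn2_var <- best$bn2_var
  }
  model$trained <- TRUE
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best$epoch),
            class = "dcamnet_fit")
}
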