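test_that("configuration validates structural constraints", {
  expect_error(dcamnet_config(C = 4, T_len = 100, m = 16, h = 5),
               "must divide")
  expect_error(dcamnet_config(C = 4, T_len = 20, w = 25), "exceeds")
  expect_error(dcamnet_config(C = 4, T_len = 100, tau_d = 0), "tau_d")
  cfg <- dcamnet_config(C = 17, T_len = 800)
  expect_equal(cfg$T1, 800)          # 'same' padding preserves length
  expect_equal(cfg$n_windows, 32)    # 800 / 25
  expect_equal(cfg$bottleneck, 2)    # floor(9 / 4)
  v <- dcamnet_config(C = 17, T_len = 800, padding = "valid")
  expect_equal(v$T1, 800 - 64 + 1)
  # r sweep {2, 4, 8} gives bottlenecks {4, 2, 1}
  bots <- vapply(c(2, 4, 8), function(r)
    dcamnet_config(C = 17, T_len = 800, r = r)$bottleneck, integer(1))
  expect_equal(bots, c(4L, 2L, 1L))
})

test_that("parameter counts follow the closed-form layer formulas", {
  cfg <- dcamnet_config(C = 4, T_len = 50, Nb = 2, K = 2, N = 3, L = 5,
                        m = 4, w = 10, h = 2)
  pc <- count_parameters(cfg)
  tab <- pc$table
  expect_equal(tab$count[tab$layer == "dynamic_conv"], 2 * 3 * (2 * 5 + 1))
  # reference configuration rows
  ref <- count_parameters(dcamnet_config(C = 17, T_len = 800))
  rt <- ref$table
  expect_equal(rt$count[rt$layer == "dynamic_conv"], 36928)
  expect_equal(rt$count[rt$layer == "spatial_conv"], 16 * 16 * 17)  # 4352
  expect_equal(rt$count[rt$layer == "temporal_attention"], 4 * 32)
  expect_equal(rt$count[rt$layer == "fully_connected"], 2 * 16)
  expect_equal(rt$count[rt$layer == "se_branch"], 2 * 9 + 4 * 2)
  expect_equal(ref$full_total,
               ref$table_total + 2 * 9 + 4 * 2 + 2 * 16 + 2 * 16)
  # a dense first layer on the flattened 17 x 800 input carries ~3.48 M
  expect_equal(dense_layer_params(13600, 256), 3481856)
  expect_equal(dense_layer_params(13600, 256) / 1e6, 3.48, tolerance = 0.001)
})

test_that("initialized models carry exactly the variant's parameter groups", {
  cfg <- toy_config()
  full <- dcamnet_init(cfg, 1, "full")
  expect_setequal(names(full$params),
                  c("Wk", "bk", "se_w1", "se_w2", "bn1_gamma", "bn1_beta",
                    "S", "bn2_gamma", "bn2_beta", "U", "FC"))
  expect_equal(dim(full$params$Wk), c(2, 4, 2 * 5))
  st <- make_ablation_variant(cfg, "static_K1")
  expect_false(any(c("se_w1", "se_w2") %in% names(st$params)))
  expect_equal(dim(st$params$Wk)[1], 1)
  ns <- make_ablation_variant(cfg, "no_spatial")
  expect_false("S" %in% names(ns$params))
  expect_equal(ncol(ns$params$FC), cfg$N)
  nt <- make_ablation_variant(cfg, "no_temporal")
  expect_false("U" %in% names(nt$params))
  expect_equal(ncol(nt$params$FC), cfg$m)
  mi <- make_ablation_variant(cfg, "minimal")
  expect_setequal(names(mi$params),
                  c("Wk", "bk", "bn1_gamma", "bn1_beta", "FC"))
  expect_error(make_ablation_variant(cfg, "bogus"), "unknown variant")
  # same seed -> identical draw
  expect_identical(dcamnet_init(cfg, 5)$params, dcamnet_init(cfg, 5)$params)
})

test_that("SE attention weights live on the simplex and follow the math", {
  # constant input with W1 = 0 -> logits 0 -> uniform weights
  xfb <- array(3, c(2, 3, 4))
  pi1 <- se_attention_weights(xfb, w1 = matrix(0, 1, 2),
                              w2 = matrix(1, 4, 1))
  expect_equal(pi1, rep(0.25, 4))
  # K = 1 degenerates to [1]
  expect_equal(se_attention_weights(xfb, matrix(0.3, 1, 2),
                                    matrix(2, 1, 1)), 1)
  # hand evaluation: g from pooling, two-layer map, softmax
  g <- c(1, -2, 0.5)
  w1 <- matrix(c(0.5, -1, 0.2, 0.3, 0, 0.1), 2, 3)
  w2 <- matrix(c(1, -1, 0.5, 0.25), 2, 2)
  a <- pmax(as.numeric(w1 %*% g), 0)
  z <- as.numeric(w2 %*% a)
  expected <- exp(z / 0.7) / sum(exp(z / 0.7))
  expect_equal(se_attention_weights(g, w1, w2, tau_d = 0.7), expected,
               tolerance = 1e-12)
  expect_error(se_attention_weights(g, w1[, 1:2], w2), "descriptor")
})

test_that("attention entropy is non-increasing as temperature decreases", {
  set.seed(8)
  g <- rnorm(4)
  w1 <- matrix(rnorm(8), 2, 4)
  w2 <- matrix(rnorm(6), 3, 2)
  entropy <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  taus <- c(4, 2, 1, 0.5, 0.25, 0.1)
  ents <- vapply(taus, function(tau)
    entropy(se_attention_weights(g, w1, w2, tau)), numeric(1))
  expect_true(all(diff(ents) <= 1e-12))
})

test_that("kernel aggregation is a convex combination", {
  set.seed(9)
  bank <- list(weights = array(rnorm(2 * 1 * 1 * 2), c(2, 1, 1, 2)),
               biases = matrix(rnorm(2), 2, 1))
  # one-hot selection returns the chosen kernel exactly
  sel <- aggregate_kernels(bank, c(0, 1))
  expect_equal(as.numeric(sel$weights), as.numeric(bank$weights[2, , , ]))
  expect_equal(sel$bias, bank$biases[2, ])
  # identical kernels are invariant to the weights
  same <- list(weights = array(rep(bank$weights[1, , , ], each = 2),
                               c(2, 1, 1, 2)),
               biases = matrix(rep(1.5, 2), 2, 1))
  mix <- aggregate_kernels(same, c(0.3, 0.7))
  expect_equal(as.numeric(mix$weights), as.numeric(bank$weights[1, , , ]))
  # elementwise arithmetic
  ag <- aggregate_kernels(bank, c(0.25, 0.75))
  expect_equal(as.numeric(ag$weights),
               as.numeric(0.25 * bank$weights[1, , , ] +
                            0.75 * bank$weights[2, , , ]))
  # convexity bound: every aggregated entry lies within the basis range
  big <- list(weights = array(rnorm(3 * 4 * 2 * 5), c(3, 4, 2, 5)),
              biases = matrix(rnorm(12), 3, 4))
  pis <- c(0.2, 0.5, 0.3)
  agg <- aggregate_kernels(big, pis)
  lo <- apply(big$weights, c(2, 3, 4), min)
  hi <- apply(big$weights, c(2, 3, 4), max)
  expect_true(all(agg$weights >= lo - 1e-12 & agg$weights <= hi + 1e-12))
  expect_error(aggregate_kernels(bank, c(0.5, 0.4)), "simplex")
})
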