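ns <- asNamespace("schemascore")

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  d <- 5; H <- 3; B <- 3; L <- 4
  seqs <- lapply(c(2, 4, 1), function(Ti) matrix(rnorm(Ti * d), Ti, d))
  bf <- ns$pack_batch(seqs, L)
  bb <- ns$pack_batch(ns$reverse_seqs(seqs), L)
  check_variant <- function(variant, K, y) {
    params <- ns$init_params(d, H, K)
    loss_fn <- function(p) {
      fp <- ns$net_forward(p, bf, bb, NULL)
      ns$head_loss(variant, fp$logits, y)$loss
    }
    fp <- ns$net_forward(params, bf, bb, NULL)
    hl <- ns$head_loss(variant, fp$logits, y)
    gr <- ns$net_backward(params, fp, bf, bb, hl$dlogits, NULL)
    eps <- 1e-6
    maxerr <- 0
    for (part in c("fwd", "bwd", "out")) {
      for (nm in names(params[[part]])) {
        w <- params[[part]][[nm]]
        for (j in sample(length(w), min(12, length(w)))) {
          p2 <- params
          p2[[part]][[nm]][j] <- w[j] + eps
          lp <- loss_fn(p2)
          p2[[part]][[nm]][j] <- w[j] - eps
          lm <- loss_fn(p2)
          num <- (lp - lm) / (2 * eps)
          ana <- gr[[part]][[nm]][j]
          maxerr <- max(maxerr, abs(num - ana) /
                          max(1e-8, abs(num) + abs(ana)))
        }
      }
    }
    maxerr
  }
  expect_lt(check_variant("per_schema", 4L, c(0L, 2L, 3L)), 1e-4)
  expect_lt(check_variant("multi_label", 9L,
                          matrix(sample(0:3, 27, TRUE), 3, 9)), 1e-4)
})

test_that("softmax heads normalize and sigmoid heads stay in range", {
  set.seed(5)
  d <- 4; H <- 3
  seqs <- lapply(c(3, 1), function(Ti) matrix(rnorm(Ti * d), Ti, d))
  bf <- ns$pack_batch(seqs, 3)
  bb <- ns$pack_batch(ns$reverse_seqs(seqs), 3)
  p4 <- ns$init_params(d, H, 4L)
  fp <- ns$net_forward(p4, bf, bb, NULL)
  probs <- ns$head_loss("per_schema", fp$logits, c(0L, 1L))$p
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  p9 <- ns$init_params(d, H, 9L)
  fp9 <- ns$net_forward(p9, bf, bb, NULL)
  out <- ns$head_loss("multi_label", fp9$logits,
                      matrix(0, 2, 9))$p
  expect_true(all(out >= 0 & out <= 1))
})

test_that("median selection follows the lower-middle rule and is order-invariant", {
  expect_equal(ns$median_rank_index(c(0.2, 0.5, 0.9)), 2L)
  perf3 <- c(0.5, 0.9, 0.2)
  expect_equal(perf3[ns$median_rank_index(perf3)], 0.5)
  perf_even <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(perf_even[ns$median_rank_index(perf_even)], 0.4)
  set.seed(9)
  for (i in 1:20) {
    perf <- runif(sample(3:9, 1))
    perm <- sample(length(perf))
    expect_equal(perf[ns$median_rank_index(perf)],
                 perf[perm][ns$median_rank_index(perf[perm])])
  }
})

test_that("a separable toy task is learned above chance by both variants", {
  # two disjoint vocabularies mapped to scores 0 vs 3 on schema 1
  set.seed(61)
  wa <- sprintf("aaa%d", 1:12)
  wb <- sprintf("bbb%d", 1:12)
  tab <- toy_embeddings(c(wa, wb), dim = 10, seed = 3)
  make <- function(n) {
    cl <- rep(c(0L, 3L), length.out = n)
    toks <- lapply(cl, function(y) {
      pool <- if (y == 0) wa else wb
      sample(pool, 5, replace = TRUE)
    })
    y <- matrix(0L, n, 9)
    y[, 1] <- cl
    list(tokens = toks, y = y)
  }
  tr <- make(80); va <- make(20); te <- make(30)
  cfg <- rnn_config("per_schema", recurrent_units = 8, epochs = 25,
                    n_restarts = 1, batch_size = 16, seed = 17)
  fit <- rnn_fit(tr$tokens, tr$y, va$tokens, va$y, tab, cfg)
  pred <- rnn_predict(fit, te$tokens, tab)
  expect_true(all(pred %in% 0:3))
  expect_gte(mean(pred[, 1] == te$y[, 1]), 0.9)

  cfgm <- rnn_config("multi_label", recurrent_units = 8, epochs = 15,
                     n_restarts = 3, batch_size = 16, seed = 23)
  fitm <- rnn_fit(tr$tokens, tr$y, va$tokens, va$y, tab, cfgm)
  med <- select_median_model(fitm, te$tokens, te$y, tab)
  expect_true(all(med$predictions >= 0 & med$predictions <= 1))
  r <- spearman_rho(med$predictions[, 1], te$y[, 1])
  expect_true(r$defined)
  expect_gt(r$rho, 0.5)
  expect_equal(length(med$all_performance), 3)
  # rank-based evaluation is unaffected by affine rescaling of the outputs
  r2 <- spearman_rho(2 * med$predictions[, 1] + 1, te$y[, 1])
  expect_equal(r$rho, r2$rho)
})

test_that("restart seeds are derived from the base seed and refits reproduce", {
  set.seed(3)
  words <- sprintf("w%d", 1:10)
  tab <- toy_embeddings(words, dim = 6, seed = 1)
  toks <- lapply(1:20, function(i) sample(words, 4, replace = TRUE))
  y <- matrix(sample(0:3, 20 * 9, TRUE), 20, 9)
  cfg <- rnn_config("multi_label", recurrent_units = 4, epochs = 2,
                    n_restarts = 2, seed = 41)
  f1 <- rnn_fit(toks[1:14], y[1:14, ], toks[15:20], y[15:20, ], tab, cfg)
  f2 <- rnn_fit(toks[1:14], y[1:14, ], toks[15:20], y[15:20, ], tab, cfg)
  expect_equal(f1$seeds, 41L + 1:2)
  expect_identical(rnn_predict(f1, toks[15:20], tab),
                   rnn_predict(f2, toks[15:20], tab))
})
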