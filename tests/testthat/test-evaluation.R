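test_that("the nine-schema worked pair correlates at 0.59", {
  x <- c(3, 0, 0, 0, 0, 0, 0, 1, 0)
  y <- c(2, 0, 0, 0, 1, 0, 0, 1, 2)
  r <- spearman_rho(x, y)
  expect_true(r$defined)
  expect_equal(round(r$rho, 2), 0.59)
  expect_equal(utterance_accuracy(x, y), r$rho)
})

test_that("spearman handles identity, constants and matches the oracle", {
  x <- c(1, 3, 2, 0, 2)
  expect_equal(spearman_rho(x, x)$rho, 1)
  const <- spearman_rho(rep(2, 5), x)
  expect_false(const$defined)
  expect_true(is.na(const$rho))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  set.seed(123)
  for (i in 1:100) {
    a <- sample(0:3, 9, TRUE)
    b <- sample(0:3, 9, TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b),
                 tolerance = 1e-12)
    # and agrees with the stock implementation as an independent check
    expect_equal(spearman_rho(a, b)$rho, cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("scoring accuracy is invariant to monotone rescaling of predictions", {
  set.seed(7)
  for (i in 1:50) {
    pred <- runif(9)
    truth <- sample(0:3, 9, TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(utterance_accuracy(pred, truth),
                 utterance_accuracy(2 * pred + 1, truth))
  }
  expect_true(is.na(utterance_accuracy(runif(9), rep(0, 9))))
})

test_that("the per-schema table reports undefined columns and sane intervals", {
  set.seed(11)
  truth <- matrix(sample(0:3, 40 * 9, TRUE), 40, 9)
  pred <- truth + matrix(rnorm(360, sd = 0.3), 40, 9)
  pred[, 5] <- 0  # constant prediction: the nan convention
  tab <- per_schema_table(pred, truth, n_boot = 200, seed = 3)
  expect_equal(nrow(tab), 9)
  expect_false(tab$defined[5])
  expect_true(all(is.na(tab[5, c("rho", "ci_low", "ci_high")])))
  ok <- tab$defined
  expect_true(all(tab$ci_low[ok] <= tab$rho[ok] + 1e-9))
  expect_true(all(tab$ci_high[ok] >= tab$rho[ok] - 1e-9))
  # perfect predictions: rho 1 with a degenerate interval
  perfect <- per_schema_table(truth, truth, n_boot = 50, seed = 2)
  expect_equal(perfect$rho, rep(1, 9), tolerance = 1e-12)
  expect_equal(perfect$ci_low, rep(1, 9), tolerance = 1e-12)
  expect_equal(perfect$ci_high, rep(1, 9), tolerance = 1e-12)
})

test_that("bootstrap intervals shrink with the test-set size", {
  set.seed(21)
  width_at <- function(n) {
    truth <- matrix(sample(0:3, n * 9, TRUE), n, 9)
    pred <- truth + matrix(rnorm(n * 9, sd = 1), n, 9)
    tab <- per_schema_table(pred, truth, n_boot = 300, seed = 5)
    mean(tab$ci_high - tab$ci_low, na.rm = TRUE)
  }
  w <- c(width_at(50), width_at(200), width_at(800))
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("weighted kappa is 1 on agreement, 0 under independence, and exact", {
  a <- c(0, 1, 2, 3, 0, 2, 1, 3)
  expect_equal(weighted_kappa(a, a)$kappa, 1)
  # independent raters with product marginals: kappa near 0 at large n
  set.seed(31)
  n <- 20000
  marg <- c(.6, .2, .1, .1)
  r1 <- sample(0:3, n, TRUE, prob = marg)
  r2 <- sample(0:3, n, TRUE, prob = marg)
  expect_lt(abs(weighted_kappa(r1, r2)$kappa), 0.05)
  # closed-form oracle on a fixed contingency fixture, computed per item:
  # kappa = 1 - mean(w(a_i, b_i)) / sum(w * E)
  fa <- c(0, 0, 0, 1, 1, 2, 2, 3, 3, 0, 1, 2, 3, 0, 1)
  fb <- c(0, 1, 0, 1, 2, 2, 1, 3, 2, 0, 1, 2, 3, 1, 0)
  for (wgt in c("linear", "quadratic")) {
    pw <- if (wgt == "linear") 1 else 2
    wmat <- (abs(outer(0:3, 0:3, "-")) / 3)^pw
    pa <- tabulate(fa + 1, 4) / length(fa)
    pb <- tabulate(fb + 1, 4) / length(fb)
    expected_disagreement <- sum(wmat * outer(pa, pb))
    observed_disagreement <- mean((abs(fa - fb) / 3)^pw)
    oracle <- 1 - observed_disagreement / expected_disagreement
    expect_equal(weighted_kappa(fa, fb, wgt)$kappa, oracle,
                 tolerance = 1e-12)
  }
  # degenerate: both raters a single identical category -> undefined
  expect_false(weighted_kappa(rep(2, 5), rep(2, 5))$defined)
})

test_that("descriptives tally scores, depths and type presence exactly", {
  corp <- toy_corpus()
  de <- descriptives(corp)
  N <- nrow(corp)
  # counts per schema sum to the number of utterances
  sums <- tapply(de$score_freq$count, de$score_freq$schema, sum)
  expect_true(all(sums == N))
  # exact counts for schema 2 (participant pA scores 1,2,3 chains)
  sc <- score_matrix(corp)
  for (s in 1:9) {
    f <- de$score_freq[de$score_freq$schema == schema_names()[s], ]
    expect_equal(f$count, vapply(0:3, function(v) sum(sc[, s] == v),
                                 integer(1)))
  }
  # percentages re-derived from counts by an independent tally
  expect_equal(de$score_freq$percent, 100 * de$score_freq$count / N,
               tolerance = 0.01)
  # depth histogram counts records, not utterances
  expect_equal(sum(de$depth_hist), length(unique(corp$record_id)))
  expect_error(descriptives({
    c2 <- as.data.frame(corp); c2$s1[1] <- NA; c2$s2[1] <- NA
    c2[1, score_columns()] <- NA; c2
  }), "missing manual scores")
})
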