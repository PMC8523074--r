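test_that("identical configurations generate bit-identical corpora", {
  cfg <- synth_config(n_participants = 3, seed = 7)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth$theta, b$truth$theta)
  expect_identical(generate_outcomes(a$truth, cfg),
                   generate_outcomes(b$truth, cfg))
})

test_that("generated corpora satisfy the structural invariants and design", {
  gen <- generate_corpus(synth_config(n_participants = 10, seed = 3))
  expect_true(validate_corpus(gen$corpus, check_design = TRUE))
  # happiness records have a single utterance by construction
  happy <- gen$corpus[gen$corpus$emotion == "happiness", ]
  if (nrow(happy) > 0) {
    expect_true(all(table(happy$record_id) == 1))
  }
})

test_that("degenerate propensities give all-zero scores and neutral-only text", {
  cfg <- synth_config(
    n_participants = 4, seed = 2,
    theta_prior = matrix(c(0, 1), 9, 2, byrow = TRUE),
    scenario_boost = matrix(0, 9, 2,
                            dimnames = list(schema_names(),
                                            c("interpersonal", "achievement"))))
  gen <- generate_corpus(cfg)
  expect_true(all(score_matrix(gen$corpus) == 0))
  words <- unlist(strsplit(gen$corpus$text, " "))
  expect_true(all(words %in% default_lexicons()$neutral))
})

test_that("mean score of a boosted schema increases with depth", {
  # Monte-Carlo check of the monotone generative rule on interpersonal
  # records (attachment is boosted there): across 5 seeds, the empirical
  # mean attachment score must increase from depth 1 to 2 to 3
  increases <- vapply(1:5, function(seed) {
    gen <- generate_corpus(synth_config(n_participants = 200, seed = seed,
                                        depth_gain = 0.3))
    corp <- gen$corpus
    rows <- corp$scenario_type == "interpersonal" & corp$depth <= 3
    m <- tapply(corp$s1[rows], corp$depth[rows], mean)
    m[["2"]] > m[["1"]] && m[["3"]] > m[["2"]]
  }, logical(1))
  expect_true(all(increases))
})

test_that("score marginals are zero-dominated for every schema", {
  gen <- generate_corpus(synth_config(n_participants = 150, seed = 19))
  zero_rates <- colMeans(score_matrix(gen$corpus) == 0)
  expect_true(all(zero_rates > 0.5))
})

test_that("schema lexicons are pairwise disjoint and survive preprocessing", {
  lex <- default_lexicons()
  schema_words <- unlist(lex[schema_names()])
  expect_equal(anyDuplicated(schema_words), 0L)
  # every lexicon word must come through the default preprocessing intact,
  # otherwise the generated text would lose its planted signal
  all_words <- unlist(lex)
  kept <- vapply(all_words, function(w) identical(preprocess(w), w),
                 logical(1))
  expect_true(all(kept))
})

test_that("outcome generation follows the noiseless linear rule", {
  gen <- generate_corpus(synth_config(n_participants = 3, seed = 4))
  w <- matrix(0, 5, 9, dimnames = list(scale_names(), schema_names()))
  w["bdi", 3] <- 2.0
  cfg <- synth_config(n_participants = 3, seed = 4, outcome_weights = w,
                      outcome_noise_sd = 0)
  truth <- gen$truth
  truth$scale_true <- truth$summaries %*% t(w)
  out <- generate_outcomes(truth, cfg)
  expect_equal(out$bdi, unname(2.0 * truth$summaries[, 3]))
  # zero weights: scores are pure noise with the configured sd
  cfg2 <- synth_config(n_participants = 3, seed = 4,
                       outcome_weights = w * 0, outcome_noise_sd = 3)
  truth$scale_true <- truth$summaries %*% t(w * 0)
  out2 <- generate_outcomes(truth, cfg2)
  expect_true(all(abs(out2$bdi) < 20))  # finite noise, mean-zero scale
  expect_gt(stats::sd(out2$hdas_depression), 0)
})

test_that("offline embeddings are deterministic unit vectors", {
  gen <- generate_corpus(synth_config(n_participants = 3, seed = 9))
  a <- offline_embeddings(gen$corpus, dimension = 25, seed = 5)
  b <- offline_embeddings(gen$corpus, dimension = 25, seed = 5)
  expect_identical(a$vectors, b$vectors)
  norms <- sqrt(rowSums(a$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  # a different seed changes the vectors
  c_ <- offline_embeddings(gen$corpus, dimension = 25, seed = 6)
  expect_false(isTRUE(all.equal(a$vectors, c_$vectors)))
})

test_that("shared vocabulary implies higher averaged-vector cosine", {
  lex <- default_lexicons()
  words <- unique(unlist(lex))
  corp <- flat_corpus(2)
  corp$text <- c(paste(words[1:50], collapse = " "), "x")
  tab <- offline_embeddings(corp, dimension = 30, seed = 3)
  set.seed(31)
  wins <- vapply(1:100, function(i) {
    shared <- sample(words[1:50], 8)
    u1 <- c(shared, sample(words[1:50], 2))
    u2 <- c(shared, sample(words[1:50], 2))
    disj1 <- sample(words[1:25], 10)
    disj2 <- sample(words[26:50], 10)
    ev <- function(tk) embed_utterance(tk, tab)$values
    cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    cos(ev(u1), ev(u2)) > cos(ev(disj1), ev(disj2))
  }, logical(1))
  expect_gt(mean(wins), 0.95)
})
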