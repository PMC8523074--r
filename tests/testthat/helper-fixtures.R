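# Programmatic fixtures: no data files, everything built in code.

# minimal hand-built corpus: 2 participants x full 5-record design,
# deterministic scores
toy_corpus <- function() {
  rows <- list()
  for (p in c("pA", "pB")) {
    plan <- data.frame(
      record_type = c("closed", "closed", "closed", "closed", "open"),
      scenario_type = c("interpersonal", "interpersonal", "achievement",
                        "achievement", "interpersonal"),
      scenario_id = c("I1", "I2", "A1", "A2", NA),
      emotion = c("sadness", "fear", "anger", "sadness", "sadness"),
      depths = c(2L, 1L, 3L, 1L, 2L))
    for (r in seq_len(5)) {
      D <- plan$depths[r]
      base <- if (p == "pA") 1L else 2L
      sc <- matrix(0L, D, 9)
      sc[, (match(p, c("pA", "pB")) %% 9) + 1] <- pmin(base + seq_len(D) - 1L, 3L)
      df <- data.frame(
        participant_id = p,
        record_id = sprintf("%s_r%d", p, r),
        record_type = plan$record_type[r],
        scenario_type = plan$scenario_type[r],
        scenario_id = plan$scenario_id[r],
        emotion = plan$emotion[r],
        depth = seq_len(D),
        text = sprintf("utterance %s %d", p, seq_len(D)),
        stringsAsFactors = FALSE)
      colnames(sc) <- score_columns()
      rows[[length(rows) + 1]] <- cbind(df, as.data.frame(sc))
    }
  }
  as_corpus(do.call(rbind, rows))
}

# single-utterance-record corpus of exactly n rows with seeded random scores
flat_corpus <- function(n, seed = 1) {
  set.seed(seed)
  sc <- matrix(sample(0:3, n * 9, replace = TRUE, prob = c(.7, .1, .1, .1)),
               n, 9, dimnames = list(NULL, score_columns()))
  open <- runif(n) < 0.2
  df <- data.frame(
    participant_id = sprintf("p%d", seq_len(n)),
    record_id = sprintf("r%d", seq_len(n)),
    record_type = ifelse(open, "open", "closed"),
    scenario_type = sample(c("interpersonal", "achievement"), n, TRUE),
    scenario_id = NA_character_,
    emotion = "sadness",
    depth = 1L,
    text = sprintf("word%d thing", seq_len(n)),
    stringsAsFactors = FALSE)
  df$scenario_id[!open] <- "I1"
  as_corpus(cbind(df, as.data.frame(sc)))
}

# small deterministic embedding table over the given words
toy_embeddings <- function(words, dim = 8, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(m) <- words
  embedding_table(m)
}

# independent Spearman oracle: mid-rank ties, explicit Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
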