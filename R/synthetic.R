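# Synthetic thought-record corpora with known ground truth.
#
# The generator emulates the structure of the study design it is meant to
# exercise: participants with latent per-schema propensities complete four
# closed thought records (two interpersonal, two achievement scenarios) and
# one open record; scenario types boost matching schemas; downward-arrow
# depth increases schema signal; utterance text is drawn from a mixture of
# schema lexicons weighted by the utterance's true scores; participant-level
# mental-health scale scores are a noisy linear function of the schema
# summary counts.

#' Configuration for the synthetic corpus generator
#'
#' All defaults are fixed study conditions: a corpus of `n_participants`
#' with five records each, ordinal scores emitted by a gated ordered-logistic
#' mechanism (zero at non-positive base activation
#' `propensity_scale * theta_s + boost`, otherwise located at
#' `base + depth_gain * (depth - 1)`), and heavily zero-dominated
#' per-schema marginals with two
#' high-frequency schemas (attachment boosted in interpersonal scenarios,
#' competence in achievement scenarios).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   corpora.
#' @param theta_prior 9x2 matrix of per-schema Beta(shape1, shape2)
#'   parameters for the latent propensity `theta` in `[0,1]`.
#' @param scenario_boost 9x2 matrix (columns interpersonal, achievement) of
#'   additive activation bonuses for schema-scenario pairs.
#' @param propensity_scale Multiplier mapping `theta` onto the activation
#'   scale.
#' @param depth_gain Per-downward-arrow-step activation increment.
#' @param depth_distribution Probabilities of record depth 1..6; mass is
#'   concentrated on depths 1-4 by default.
#' @param cutpoints Three increasing ordered-logistic cutpoints separating
#'   scores 0|1, 1|2, 2|3.
#' @param lexicons Named list of 10 word lists (nine pairwise-disjoint schema
#'   lexicons plus `neutral`); see [default_lexicons()].
#' @param words_per_utterance Integer range (min, max) of words per
#'   utterance.
#' @param neutral_weight Mixture weight of the neutral lexicon relative to a
#'   score point.
#' @param p_happiness Probability that a record's emotion is happiness
#'   (which suppresses the downward-arrow chain, forcing depth 1).
#' @param outcome_weights 5x9 matrix of linear weights mapping schema
#'   summary counts to the five mental-health scales.
#' @param outcome_noise_sd Standard deviation of the Gaussian noise added to
#'   scale scores; must be non-negative.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_participants = 300L,
                         seed = 11L,
                         theta_prior = default_theta_prior(),
                         scenario_boost = default_scenario_boost(),
                         propensity_scale = 4,
                         depth_gain = 0.3,
                         depth_distribution = c(0.25, 0.30, 0.25, 0.12, 0.05, 0.03),
                         cutpoints = c(3.0, 4.2, 5.0),
                         lexicons = default_lexicons(),
                         words_per_utterance = c(4L, 12L),
                         neutral_weight = 2,
                         p_happiness = 0.05,
                         outcome_weights = default_outcome_weights(),
                         outcome_noise_sd = 1) {
  cfg <- list(n_participants = as.integer(n_participants), seed = as.integer(seed),
              theta_prior = theta_prior, scenario_boost = scenario_boost,
              propensity_scale = propensity_scale, depth_gain = depth_gain,
              depth_distribution = depth_distribution, cutpoints = cutpoints,
              lexicons = lexicons, words_per_utterance = words_per_utterance,
              neutral_weight = neutral_weight, p_happiness = p_happiness,
              outcome_weights = outcome_weights,
              outcome_noise_sd = outcome_noise_sd)
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @export
default_theta_prior <- function() {
  m <- rbind(
    attachment             = c(2.0, 4.0),
    competence             = c(2.0, 4.0),
    global_self_evaluation = c(1.5, 5.0),
    health                 = c(1.0, 8.0),
    power_control          = c(1.2, 6.0),
    meta_cognition         = c(0.3, 15.0),
    other_people           = c(0.6, 10.0),
    hopelessness           = c(1.5, 6.0),
    others_views_on_self   = c(1.5, 5.5))
  colnames(m) <- c("shape1", "shape2")
  m
}

#' @rdname synth_config
#' @export
default_scenario_boost <- function() {
  m <- matrix(0, nrow = N_SCHEMAS, ncol = 2,
              dimnames = list(schema_names(), SCENARIO_TYPES))
  m["attachment", "interpersonal"] <- 2.0
  m["competence", "achievement"]   <- 2.0
  m
}

#' @rdname synth_config
#' @export
default_outcome_weights <- function() {
  w <- matrix(0, nrow = 5, ncol = N_SCHEMAS,
              dimnames = list(scale_names(), schema_names()))
  w["hdas_depression", "hopelessness"]           <- 0.9
  w["hdas_depression", "global_self_evaluation"] <- 0.4
  w["hdas_anxiety",    "global_self_evaluation"] <- 0.6
  w["hdas_anxiety",    "power_control"]          <- 0.3
  w["bdi",             "hopelessness"]           <- 1.5
  w["bdi",             "attachment"]             <- 0.6
  w["cds_relatedness", "global_self_evaluation"] <- 2.0
  w["cds_relatedness", "power_control"]          <- 1.5
  w["cds_achievement", "global_self_evaluation"] <- 2.0
  w["cds_achievement", "competence"]             <- 0.8
  w
}

validate_synth_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (abs(sum(cfg$depth_distribution) - 1) > 1e-8) {
    stop("depth_distribution must sum to 1", call. = FALSE)
  }
  if (any(cfg$depth_distribution < 0)) {
    stop("depth_distribution must be non-negative", call. = FALSE)
  }
  if (is.unsorted(cfg$cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  if (cfg$outcome_noise_sd < 0) stop("outcome_noise_sd must be >= 0", call. = FALSE)
  schema_lex <- cfg$lexicons[schema_names()]
  if (any(vapply(schema_lex, is.null, logical(1))) || is.null(cfg$lexicons$neutral)) {
    stop("lexicons must name all nine schemas plus 'neutral'", call. = FALSE)
  }
  all_words <- unlist(schema_lex, use.names = FALSE)
  if (anyDuplicated(all_words)) {
    stop("schema lexicons must be pairwise disjoint; duplicated: ",
         paste(unique(all_words[duplicated(all_words)]), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(dim(cfg$theta_prior), c(N_SCHEMAS, 2L)) &&
      !identical(dim(cfg$theta_prior), c(9L, 2L))) {
    stop("theta_prior must be a 9x2 matrix", call. = FALSE)
  }
  w <- cfg$words_per_utterance
  if (length(w) != 2L || w[1] < 1L || w[2] < w[1]) {
    stop("words_per_utterance must be an increasing pair of positive integers",
         call. = FALSE)
  }
  invisible(TRUE)
}

# run expr with a local, restored RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# gated ordered-logistic score draw: activation 0 is a structural zero,
# positive activations shift the ordinal location monotonically upward
draw_ordinal_score <- function(activation, cutpoints, u) {
  if (activation <= 0) return(0L)
  p_le <- stats::plogis(cutpoints - activation)  # P(score <= 0,1,2)
  as.integer(findInterval(u, p_le))
}

#' Generate a synthetic thought-record corpus with ground truth
#'
#' Each participant receives two interpersonal closed records, two
#' achievement closed records and one open record (scenario type sampled).
#' Record depth follows `depth_distribution` except for happiness records,
#' which have depth 1. Per utterance and schema, the ordinal score is drawn
#' from the gated ordered-logistic emission: with base activation
#' `propensity_scale * theta_s + scenario_boost`, a schema with
#' non-positive base is a structural zero at every depth, and otherwise the
#' ordinal location is `base + depth_gain * (depth - 1)`;
#' the utterance's words are sampled from the schema lexicons weighted by
#' its scores plus the neutral lexicon. The same configuration always yields
#' a bit-identical result.
#'
#' @param config A [synth_config()].
#' @return A list with components `corpus` (a `tr_corpus`) and `truth`, a
#'   list carrying `theta` (participants x 9 latent propensities),
#'   `summaries` (participants x 9 summary counts under the
#'   max-binarize-sum rule), and `scale_true` (participants x 5 noiseless
#'   scale scores).
#' @export
generate_corpus <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  P <- config$n_participants
  pids <- sprintf("p%03d", seq_len(P))
  theta <- matrix(NA_real_, nrow = P, ncol = N_SCHEMAS,
                  dimnames = list(pids, schema_names()))
  for (s in seq_len(N_SCHEMAS)) {
    # shape1 = 0 is the degenerate point mass at zero propensity
    theta[, s] <- if (config$theta_prior[s, 1] == 0) 0 else
      stats::rbeta(P, config$theta_prior[s, 1], config$theta_prior[s, 2])
  }
  rows <- vector("list", P * 5L)
  k <- 0L
  for (i in seq_len(P)) {
    plan <- data.frame(
      record_type   = c("closed", "closed", "closed", "closed", "open"),
      scenario_type = c("interpersonal", "interpersonal",
                        "achievement", "achievement",
                        sample(SCENARIO_TYPES, 1L)),
      stringsAsFactors = FALSE)
    plan$scenario_id <- c(paste0("I", sample.int(5L, 2L)),
                          paste0("A", sample.int(5L, 2L)),
                          NA_character_)
    for (r in seq_len(5L)) {
      emo <- if (stats::runif(1) < config$p_happiness) "happiness"
             else sample(c("sadness", "fear", "anger"), 1L)
      D <- if (emo == "happiness") 1L
           else sample.int(length(config$depth_distribution), 1L,
                           prob = config$depth_distribution)
      boost <- config$scenario_boost[, plan$scenario_type[r]]
      utts <- vector("list", D)
      base <- config$propensity_scale * theta[i, ] + boost
      for (d in seq_len(D)) {
        # the downward-arrow gain amplifies only schemas with positive base
        # activation; a schema with no propensity stays silent at any depth
        act <- ifelse(base > 0, base + config$depth_gain * (d - 1), 0)
        u <- stats::runif(N_SCHEMAS)
        sc <- vapply(seq_len(N_SCHEMAS), function(s) {
          draw_ordinal_score(act[s], config$cutpoints, u[s])
        }, integer(1))
        utts[[d]] <- c(list(depth = d, text = sample_utterance_text(sc, config)),
                       as.list(sc))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = pids[i],
        record_id = sprintf("%s_r%d", pids[i], r),
        record_type = plan$record_type[r],
        scenario_type = plan$scenario_type[r],
        scenario_id = plan$scenario_id[r],
        emotion = emo,
        depth = vapply(utts, function(u) u$depth, integer(1)),
        text = vapply(utts, function(u) u$text, character(1)),
        stringsAsFactors = FALSE)
      scm <- t(vapply(utts, function(u) unlist(u[-(1:2)]), integer(N_SCHEMAS)))
      colnames(scm) <- score_columns()
      rows[[k]] <- cbind(rows[[k]], as.data.frame(scm))
    }
  }
  corpus <- as_corpus(do.call(rbind, rows))
  summaries <- schema_summary_matrix(corpus)
  scale_true <- summaries %*% t(config$outcome_weights)
  truth <- list(theta = theta, summaries = summaries, scale_true = scale_true,
                participant_ids = pids)
  list(corpus = corpus, truth = truth)
}

# sample one utterance's text from the score-weighted lexicon mixture
sample_utterance_text <- function(scores, config) {
  n_words <- sample(seq(config$words_per_utterance[1],
                        config$words_per_utterance[2]), 1L)
  weights <- c(scores, config$neutral_weight)
  lex <- c(config$lexicons[schema_names()], config$lexicons["neutral"])
  src <- sample.int(10L, n_words, replace = TRUE, prob = weights / sum(weights))
  words <- vapply(src, function(j) {
    pool <- lex[[j]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  paste(words, collapse = " ")
}

#' Generate participant-level mental-health scale scores
#'
#' For each of the five scales, the score is the weighted sum of the
#' participant's nine schema summary counts (the max-binarize-sum statistic
#' computed from the generated manual scores) plus Gaussian noise of
#' standard deviation `outcome_noise_sd`. Deterministic given the
#' configuration seed.
#'
#' @param truth The `truth` component returned by [generate_corpus()].
#' @param config The [synth_config()] used to generate the corpus.
#' @return Data frame with `participant_id` and one column per scale.
#' @export
generate_outcomes <- function(truth, config) {
  validate_synth_config(config)
  noisy <- with_seed(config$seed + 1L, {
    truth$scale_true +
      matrix(stats::rnorm(length(truth$scale_true), 0, config$outcome_noise_sd),
             nrow = nrow(truth$scale_true))
  })
  out <- data.frame(participant_id = truth$participant_ids,
                    stringsAsFactors = FALSE)
  out[colnames(truth$scale_true)] <- as.data.frame(noisy)
  out
}

#' Deterministic offline word embeddings
#'
#' Maps every token of the corpus (after preprocessing) to a unit-length
#' vector derived from a hash of the word and the seed, via a Lehmer
#' generator seeded per word. The same word always receives the same vector
#' across runs and machines, so the table is a download-free, fully
#' reproducible embedding backend with the interface of a pretrained table.
#'
#' @param corpus A corpus table (non-empty).
#' @param dimension Embedding dimension (default 100).
#' @param seed Integer seed folded into every word hash.
#' @param prep A [prep_config()] used to tokenize the corpus text.
#' @return An [embedding_table()].
#' @export
offline_embeddings <- function(corpus, dimension = 100L, seed = 1L,
                               prep = prep_config()) {
  stopifnot(nrow(corpus) > 0L)
  vocab <- unique(unlist(lapply(corpus$text, preprocess, config = prep)))
  vocab <- vocab[nzchar(vocab)]
  m <- t(vapply(vocab, hashed_unit_vector, numeric(dimension),
                dimension = dimension, seed = seed))
  rownames(m) <- vocab
  embedding_table(m)
}

# unit vector from a word hash: fold the UTF-8 bytes into a 31-bit state,
# mix in the seed, then iterate a Park-Miller generator; exact in doubles
hashed_unit_vector <- function(word, dimension, seed) {
  M <- 2147483647
  h <- 7
  for (b in utf8ToInt(word)) h <- (h * 131 + b) %% M
  x <- (h + 104729 * (seed %% 20063)) %% (M - 1) + 1
  u <- numeric(dimension)
  for (i in seq_len(dimension)) {
    x <- (48271 * x) %% M
    u[i] <- x / M
  }
  v <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  v / sqrt(sum(v^2))
}
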