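# End-to-end orchestration: generate (or load) a corpus, embed it, build
# the distribution-matched split, fit the scoring models, evaluate them,
# and run the three downstream analyses. All randomness flows from the
# explicit seeds in the stage configurations; no stage mutates its inputs.

#' Run the full scoring-and-analysis pipeline
#'
#' Chains the stages on a synthetic corpus: corpus generation with ground
#' truth, deterministic offline embeddings, preprocessing and averaged
#' embedding, distribution-matched splitting, kNN and SVM scoring (and
#' optionally the recurrent networks), per-schema evaluation with bootstrap
#' confidence intervals, the depth analysis on per-utterance accuracies,
#' the closed-to-open transfer regressions, and the schema-to-scale
#' regressions.
#'
#' @param synth A [synth_config()].
#' @param split A [split_config()].
#' @param prep A [prep_config()].
#' @param hypo A [hypothesis_config()].
#' @param embedding_dim Dimension of the offline embedding backend.
#' @param embedding An optional [embedding_table()] (e.g. from
#'   [read_glove_text()]); when supplied it replaces the offline backend.
#' @param models Character subset of `c("knn_c", "knn_r", "svc", "svr")`.
#' @param rnn `NULL` (skip the recurrent models) or an [rnn_config()];
#'   both variants are then trained and the per-schema median model feeds
#'   the depth analysis.
#' @param n_boot Bootstrap resamples for the evaluation tables.
#' @param accuracy_model Which model's test predictions feed the depth analysis
#'   when no RNN is trained (default `"knn_c"`).
#' @return A list with the corpus, ground truth, outcomes, split,
#'   per-model predictions and evaluation tables, descriptives, and the
#'   three analysis results (`depth`, `transfer`, `scales`).
#' @export
run_pipeline <- function(synth = synth_config(),
                         split = split_config(seed = synth$seed + 101L),
                         prep = prep_config(),
                         hypo = hypothesis_config(),
                         embedding_dim = 100L,
                         embedding = NULL,
                         models = c("knn_c", "knn_r", "svc", "svr"),
                         rnn = NULL,
                         n_boot = 1000L,
                         accuracy_model = "knn_c") {
  models <- match.arg(models, several.ok = TRUE)
  gen <- generate_corpus(synth)
  corpus <- gen$corpus
  outcomes <- generate_outcomes(gen$truth, synth)
  table <- if (is.null(embedding)) {
    offline_embeddings(corpus, dimension = embedding_dim,
                       seed = synth$seed, prep = prep)
  } else embedding
  emb <- embed_corpus(corpus, table, prep)
  sp <- matched_split(corpus, split)
  truth <- score_matrix(corpus)
  tr_x <- emb$matrix[sp$train, , drop = FALSE]
  tr_y <- truth[sp$train, , drop = FALSE]
  te_x <- emb$matrix[sp$test, , drop = FALSE]
  te_y <- truth[sp$test, , drop = FALSE]
  preds <- list()
  flags <- list()
  if ("knn_c" %in% models) {
    preds$knn_c <- knn_predict(te_x, tr_x, tr_y, knn_config("classification"))
  }
  if ("knn_r" %in% models) {
    preds$knn_r <- knn_predict(te_x, tr_x, tr_y, knn_config("regression"))
  }
  if ("svc" %in% models) {
    f <- svm_fit_predict(tr_x, tr_y, te_x, svm_config("classification"))
    preds$svc <- f$predictions
    flags$svc <- f$constant
  }
  if ("svr" %in% models) {
    f <- svm_fit_predict(tr_x, tr_y, te_x, svm_config("regression"))
    preds$svr <- f$predictions
    flags$svr <- f$constant
  }
  rnn_fits <- NULL
  if (!is.null(rnn)) {
    va_tok <- emb$tokens[sp$validation]
    va_y <- truth[sp$validation, , drop = FALSE]
    tr_tok <- emb$tokens[sp$train]
    te_tok <- emb$tokens[sp$test]
    rnn_fits <- list()
    for (variant in c("per_schema", "multi_label")) {
      cfg <- rnn
      cfg$variant <- variant
      fit <- rnn_fit(tr_tok, tr_y, va_tok, va_y, table, cfg)
      med <- select_median_model(fit, te_tok, te_y, table)
      rnn_fits[[variant]] <- list(fit = fit, median = med)
      preds[[if (variant == "per_schema") "rnn_ps" else "rnn_ml"]] <-
        med$predictions
    }
  }
  evaluation <- lapply(seq_along(preds), function(i) {
    per_schema_table(preds[[i]], te_y, n_boot = n_boot,
                     seed = split$seed + i)
  })
  names(evaluation) <- names(preds)
  h2_pred <- if (!is.null(rnn_fits)) preds$rnn_ps else preds[[accuracy_model]]
  acc <- accuracy_table(corpus, sp$test, h2_pred)
  depth_res <- tryCatch(fit_depth_model(acc$data), error = function(e) e)
  tf <- build_transfer_features(corpus)
  transfer <- fit_transfer_models(tf$features)
  summaries <- build_schema_summaries(corpus, hypo)
  scales <- fit_scale_models(summaries, outcomes, hypo)
  list(corpus = corpus, truth = gen$truth, outcomes = outcomes,
       embedding = table, split = sp, predictions = preds,
       constant_flags = flags, rnn = rnn_fits, evaluation = evaluation,
       descriptives = descriptives(corpus),
       depth = depth_res, depth_excluded = acc$n_excluded,
       transfer = transfer, transfer_excluded = tf$excluded,
       summaries = summaries, scales = scales)
}

#' Write a predictions table
#'
#' One row per scored utterance: the corpus keys, the nine real-valued
#' predictions `p1..p9`, and a model tag.
#'
#' @param corpus The corpus the predictions refer to.
#' @param indices Row indices of the predicted utterances.
#' @param pred Prediction matrix aligned with `indices`.
#' @param model Model tag string.
#' @param path Output path (comma-separated).
#' @return Invisibly `path`.
#' @export
write_predictions <- function(corpus, indices, pred, model, path) {
  keys <- as.data.frame(corpus)[indices, c("participant_id", "record_id",
                                           "depth")]
  pm <- as.data.frame(pred)
  names(pm) <- paste0("p", 1:9)
  out <- cbind(keys, pm, model = model)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
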