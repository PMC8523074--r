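# Downstream statistical analyses: the depth effect on scoring accuracy
# (three-level random-intercept model with a likelihood-ratio test), the
# closed-to-open schema transfer regressions, and the schema-summary to
# mental-health-scale regressions with Bonferroni control.

#' Hypothesis-analysis configuration
#'
#' @param alpha_scales Significance threshold for the five scale regressions;
#'   default 0.01 (Bonferroni, 0.05 over five models).
#' @param binarize_threshold Scores up to this value map to 0 and higher
#'   scores to 1 in the summary-score construction; the default 2 means
#'   only unambiguous score-3 records count.
#' @return A `hypothesis_config` list.
#' @export
hypothesis_config <- function(alpha_scales = 0.01, binarize_threshold = 2L) {
  stopifnot(alpha_scales > 0, alpha_scales < 1, binarize_threshold %in% 0:2)
  structure(list(alpha_scales = alpha_scales,
                 binarize_threshold = as.integer(binarize_threshold)),
            class = "hypothesis_config")
}

#' Depth effect on scoring accuracy (three-level model)
#'
#' Fits two multilevel linear models of per-utterance scoring accuracy by
#' maximum likelihood: the null model with random intercepts for
#' participants and for thought records nested within participants, and a
#' model adding utterance depth as a fixed effect. Returns the likelihood
#' ratio test between them together with the depth slope and its
#' t-statistic. Utterances with undefined accuracy must already be
#' excluded.
#'
#' @param data Data frame with columns `accuracy`, `depth`,
#'   `participant_id`, `record_id`.
#' @return List with `chi2`, `df`, `p`, `fixed_effect_b`,
#'   `fixed_effect_t`, `n`, and the two fitted models (`null_model`,
#'   `depth_model`).
#' @export
fit_depth_model <- function(data) {
  stopifnot(all(c("accuracy", "depth", "participant_id", "record_id") %in%
                  names(data)))
  data <- data[is.finite(data$accuracy), , drop = FALSE]
  if (length(unique(data$participant_id)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  m0 <- lme4::lmer(
    accuracy ~ 1 + (1 | participant_id) + (1 | participant_id:record_id),
    data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  m1 <- lme4::lmer(
    accuracy ~ depth + (1 | participant_id) + (1 | participant_id:record_id),
    data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  lrt <- stats::anova(m0, m1)
  coefs <- summary(m1)$coefficients
  list(chi2 = lrt$Chisq[2], df = lrt$Df[2], p = lrt$`Pr(>Chisq)`[2],
       fixed_effect_b = coefs["depth", "Estimate"],
       fixed_effect_t = coefs["depth", "t value"],
       n = nrow(data), null_model = m0, depth_model = m1)
}

# per-record maximum score for each schema: records x 9 matrix
record_max_scores <- function(corpus) {
  sc <- score_matrix(corpus)
  if (anyNA(sc)) stop("manual scores required on every utterance",
                      call. = FALSE)
  rid <- factor(corpus$record_id, levels = unique(corpus$record_id))
  m <- apply(sc, 2L, function(col) tapply(col, rid, max))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                   dimnames = list(levels(rid), schema_names()))
  m
}

#' Closed-to-open transfer features
#'
#' For every participant and schema: the predictor is the mean of the two
#' per-record maximum scores from the closed records whose scenario type
#' matches the open record's; the outcome is the per-record maximum over
#' the open record's utterances. Participants lacking exactly one open
#' record or a matched closed pair are excluded (their ids are returned).
#'
#' @param corpus A scored corpus.
#' @return List with `features` (data frame: participant_id, schema,
#'   predictor, outcome) and `excluded` (character vector of participant
#'   ids).
#' @export
build_transfer_features <- function(corpus) {
  recmax <- record_max_scores(corpus)
  rec_info <- unique(as.data.frame(corpus)[c("record_id", "participant_id",
                                             "record_type", "scenario_type")])
  rows <- list()
  excluded <- character(0)
  for (pid in unique(rec_info$participant_id)) {
    ri <- rec_info[rec_info$participant_id == pid, ]
    open <- ri[ri$record_type == "open", ]
    if (nrow(open) != 1L) { excluded <- c(excluded, pid); next }
    closed <- ri[ri$record_type == "closed" &
                   ri$scenario_type == open$scenario_type, ]
    if (nrow(closed) != 2L) { excluded <- c(excluded, pid); next }
    pred <- colMeans(recmax[closed$record_id, , drop = FALSE])
    outc <- recmax[open$record_id, ]
    rows[[pid]] <- data.frame(participant_id = pid, schema = schema_names(),
                              predictor = unname(pred),
                              outcome = unname(outc),
                              stringsAsFactors = FALSE)
  }
  features <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(participant_id = character(0), schema = character(0),
               predictor = numeric(0), outcome = numeric(0))
  rownames(features) <- NULL
  list(features = features, excluded = excluded)
}

# one simple OLS with the full reporting set (b, CI, t, p, F, adj R^2)
simple_regression <- function(outcome, predictor) {
  fit <- stats::lm(outcome ~ predictor)
  sm <- summary(fit)
  ci <- stats::confint(fit)["predictor", ]
  data.frame(b = stats::coef(fit)[["predictor"]],
             ci_low = ci[[1]], ci_high = ci[[2]],
             t = sm$coefficients["predictor", "t value"],
             p = sm$coefficients["predictor", "Pr(>|t|)"],
             F = sm$fstatistic[["value"]],
             df1 = sm$fstatistic[["numdf"]], df2 = sm$fstatistic[["dendf"]],
             adj_r2 = sm$adj.r.squared)
}

#' Per-schema closed-to-open transfer regressions
#'
#' Nine ordinary least squares fits (with intercept) of the open-record
#' schema presence on the matched closed-record schema presence. Schemas
#' with a zero-variance predictor are flagged and not fit.
#'
#' @param features The `features` component of [build_transfer_features()].
#' @return Data frame with one row per schema: `schema`, `b`, `ci_low`,
#'   `ci_high`, `t`, `p`, `F`, `df1`, `df2`, `adj_r2`, `fitted`.
#' @export
fit_transfer_models <- function(features) {
  out <- do.call(rbind, lapply(schema_names(), function(s) {
    f <- features[features$schema == s, ]
    if (nrow(f) < 3L) stop("need at least 3 participants per schema model",
                           call. = FALSE)
    if (stats::var(f$predictor) == 0) {
      return(data.frame(schema = s, b = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, t = NA_real_, p = NA_real_,
                        F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                        adj_r2 = NA_real_, fitted = FALSE))
    }
    cbind(data.frame(schema = s), simple_regression(f$outcome, f$predictor),
          data.frame(fitted = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Per-participant schema summary counts
#'
#' The max-binarize-sum statistic: per participant, record and schema take
#' the maximum score across utterances, recode it to 1 only when it equals
#' 3 (scores up to 2 map to 0), and sum over the participant's records.
#' With the full five-record design the summary ranges over 0..5.
#'
#' @param corpus A scored corpus.
#' @param config A [hypothesis_config()].
#' @return Integer matrix, participants x 9, rownames = participant ids.
#' @export
build_schema_summaries <- function(corpus, config = hypothesis_config()) {
  schema_summary_matrix(corpus, config$binarize_threshold)
}

schema_summary_matrix <- function(corpus, binarize_threshold = 2L) {
  recmax <- record_max_scores(corpus)
  rec_pid <- corpus$participant_id[match(rownames(recmax), corpus$record_id)]
  pid <- factor(rec_pid, levels = unique(rec_pid))
  bin <- (recmax > binarize_threshold) * 1L
  m <- apply(bin, 2L, function(col) tapply(col, pid, sum))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                   dimnames = list(levels(pid), schema_names()))
  colnames(m) <- schema_names()
  m
}

#' Schema-to-scale multiple regressions
#'
#' Five OLS models (one per mental-health scale), each with the nine
#' summary counts as simultaneous predictors and an intercept.
#' Standardized slopes are computed by refitting on z-scored predictors and
#' outcome. Significance is assessed at the Bonferroni-corrected threshold.
#'
#' @param summaries Participants x 9 summary matrix
#'   ([build_schema_summaries()]).
#' @param outcomes Data frame with `participant_id` and the five scale
#'   columns ([scale_names()]).
#' @param config A [hypothesis_config()].
#' @return List with `results` (data frame: scale, schema, b, beta, t, p,
#'   significant) and `model_fits` (named list of `lm` objects).
#' @export
fit_scale_models <- function(summaries, outcomes, config = hypothesis_config()) {
  stopifnot(all(scale_names() %in% names(outcomes)))
  if (nrow(summaries) < 20L) stop("need at least 20 participants",
                                  call. = FALSE)
  idx <- match(rownames(summaries), outcomes$participant_id)
  if (anyNA(idx)) stop("outcomes missing for some participants",
                       call. = FALSE)
  X <- as.data.frame(summaries)
  fits <- list()
  rows <- list()
  for (scl in scale_names()) {
    y <- outcomes[[scl]][idx]
    df <- cbind(data.frame(.y = y), X)
    fit <- stats::lm(.y ~ ., data = df)
    fits[[scl]] <- fit
    sm <- summary(fit)$coefficients
    # standardized slopes from a z-scored refit
    zX <- as.data.frame(lapply(X, function(col) {
      if (stats::sd(col) == 0) col * 0 else (col - mean(col)) / stats::sd(col)
    }))
    zy <- if (stats::sd(y) == 0) y * 0 else (y - mean(y)) / stats::sd(y)
    zfit <- stats::lm(zy ~ ., data = cbind(data.frame(zy = zy), zX))
    beta <- stats::coef(zfit)[-1]
    rows[[scl]] <- data.frame(
      scale = scl, schema = schema_names(),
      b = sm[-1, "Estimate"],
      beta = unname(beta),
      t = sm[-1, "t value"],
      p = sm[-1, "Pr(>|t|)"],
      significant = sm[-1, "Pr(>|t|)"] < config$alpha_scales,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, model_fits = fits)
}

#' Simulate scoring-accuracy data under the three-level model
#'
#' Generates per-utterance accuracies from the random-intercept model that
#' [fit_depth_model()] fits: participant and record intercepts plus an
#' optional fixed depth slope and residual noise, with the thought-record
#' structure (five records per participant, record depth drawn from
#' `depth_distribution`). Used for calibration studies of the
#' likelihood-ratio test (type-I error, slope recovery).
#'
#' @param n_participants Number of participants.
#' @param depth_slope Fixed effect of depth (0 for the null configuration).
#' @param intercept Grand mean accuracy.
#' @param sd_participant,sd_record,sd_resid Standard deviations of the
#'   participant intercepts, record intercepts and residuals.
#' @param depth_distribution Probabilities of record depth 1..k.
#' @param seed Integer seed.
#' @return Data frame with `accuracy`, `depth`, `participant_id`,
#'   `record_id`.
#' @export
simulate_accuracy_data <- function(n_participants, depth_slope = 0,
                                   intercept = 0.5, sd_participant = 0.15,
                                   sd_record = 0.1, sd_resid = 0.2,
                                   depth_distribution = c(0.3, 0.3, 0.25, 0.15),
                                   seed = 1L) {
  with_seed(seed, {
    rows <- vector("list", n_participants * 5L)
    k <- 0L
    for (i in seq_len(n_participants)) {
      u_p <- stats::rnorm(1, 0, sd_participant)
      for (r in 1:5) {
        u_r <- stats::rnorm(1, 0, sd_record)
        D <- sample.int(length(depth_distribution), 1L,
                        prob = depth_distribution)
        d <- seq_len(D)
        k <- k + 1L
        rows[[k]] <- data.frame(
          accuracy = intercept + u_p + u_r + depth_slope * d +
            stats::rnorm(D, 0, sd_resid),
          depth = d,
          participant_id = sprintf("p%d", i),
          record_id = sprintf("p%d_r%d", i, r),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Per-utterance scoring-accuracy table for the depth analysis
#'
#' Computes [utterance_accuracy()] for every test utterance, joins the
#' participant, record and depth keys, and drops utterances whose accuracy
#' is undefined (constant truth or prediction vector), reporting how many
#' were excluded.
#'
#' @param corpus The corpus (rows aligned with `indices`).
#' @param indices Row indices of the scored utterances (e.g. a test set).
#' @param pred Prediction matrix aligned with `indices`.
#' @return List with `data` (data frame ready for [fit_depth_model()]) and
#'   `n_excluded`.
#' @export
accuracy_table <- function(corpus, indices, pred) {
  truth <- score_matrix(corpus)[indices, , drop = FALSE]
  acc <- vapply(seq_along(indices), function(i) {
    utterance_accuracy(pred[i, ], truth[i, ])
  }, numeric(1))
  keep <- is.finite(acc)
  data <- data.frame(
    accuracy = acc[keep],
    depth = corpus$depth[indices][keep],
    participant_id = corpus$participant_id[indices][keep],
    record_id = corpus$record_id[indices][keep],
    stringsAsFactors = FALSE)
  list(data = data, n_excluded = sum(!keep))
}
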