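# Rank-correlation evaluation with bootstrap confidence intervals, the
# per-utterance nine-vector scoring-accuracy statistic, weighted Cohen's
# kappa reliability, and descriptive corpus summaries. Undefined
# correlations (a constant prediction or truth vector) are reported as
# explicitly undefined, never silently as 0.

#' Spearman rank correlation with explicit undefined handling
#'
#' Ranks both vectors with mid-rank ties and returns the Pearson
#' correlation of the ranks. If either vector is constant the correlation
#' is undefined and `defined` is `FALSE` (the "nan" convention: a model
#' predicting a single value for every item cannot be rank-correlated).
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return List with `rho`, `defined` and `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 paired observations",
                           call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, defined = FALSE, n = length(x)))
  }
  rx <- rank(x)
  ry <- rank(y)
  list(rho = stats::cor(rx, ry), defined = TRUE, n = length(x))
}

#' Per-utterance scoring accuracy
#'
#' The Spearman correlation between an utterance's predicted and manually
#' assigned nine-schema score vectors; rank-based, so invariant to any
#' strictly increasing transformation of the predictions. Undefined when
#' either vector is constant (e.g. an all-zero truth vector).
#'
#' @param pred,truth Numeric vectors of length 9.
#' @return Scalar rho, or `NA` when undefined.
#' @export
utterance_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == 9L, length(truth) == 9L)
  r <- spearman_rho(pred, truth)
  if (r$defined) r$rho else NA_real_
}

#' Per-schema evaluation table with bootstrap confidence intervals
#'
#' For each schema, the Spearman correlation between predicted and manual
#' scores over the test utterances, with a seeded percentile bootstrap
#' (2.5/97.5) over utterance resamples. Schemas with a constant prediction
#' or constant truth are reported as undefined with no interval.
#'
#' @param pred Prediction matrix (utterances x 9).
#' @param truth Manual score matrix (utterances x 9).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @return Data frame with one row per schema: `schema`, `rho`, `ci_low`,
#'   `ci_high`, `defined`, `n`.
#' @export
per_schema_table <- function(pred, truth, n_boot = 1000L, seed = 1L) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (nrow(pred) == 0L) stop("empty test set", call. = FALSE)
  stopifnot(nrow(pred) == nrow(truth), ncol(pred) == 9L, ncol(truth) == 9L)
  n <- nrow(pred)
  res <- with_seed(seed, {
    lapply(seq_len(9L), function(s) {
      pt <- spearman_rho(pred[, s], truth[, s])
      if (!pt$defined) {
        return(data.frame(schema = schema_names()[s], rho = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          defined = FALSE, n = n))
      }
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- spearman_rho(pred[idx, s], truth[idx, s])
        if (r$defined) r$rho else NA_real_
      }, numeric(1))
      qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE)
      data.frame(schema = schema_names()[s], rho = pt$rho,
                 ci_low = qs[1], ci_high = qs[2], defined = TRUE, n = n)
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Weighted Cohen's kappa for paired ordinal ratings
#'
#' Chance-corrected agreement on the fixed 0..3 score scale with
#' distance-based disagreement weights: `kappa = 1 - sum(w * O) /
#' sum(w * E)` where `O` is the observed joint proportion table, `E` the
#' product of the marginals, and `w` the linear (default) or quadratic
#' disagreement weights. Equals 1 exactly on perfect agreement; undefined
#' (flagged) when both raters use a single identical category throughout.
#'
#' @param rater_a,rater_b Integer vectors of paired scores in `{0..3}`.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return List with `kappa`, `weighting`, `n_items`, `defined`.
#' @export
weighted_kappa <- function(rater_a, rater_b,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(rater_a) != length(rater_b)) {
    stop("raters must score the same items", call. = FALSE)
  }
  if (length(rater_a) < 2L) stop("need at least 2 paired items", call. = FALSE)
  if (!all(rater_a %in% 0:3) || !all(rater_b %in% 0:3)) {
    stop("scores must be integers in 0..3", call. = FALSE)
  }
  K <- 4L
  O <- table(factor(rater_a, levels = 0:3), factor(rater_b, levels = 0:3))
  O <- O / sum(O)
  pa <- rowSums(O)
  pb <- colSums(O)
  E <- outer(pa, pb)
  dist <- abs(outer(0:3, 0:3, "-")) / (K - 1)
  w <- if (weighting == "linear") dist else dist^2
  denom <- sum(w * E)
  if (denom == 0) {
    return(list(kappa = NA_real_, weighting = weighting,
                n_items = length(rater_a), defined = FALSE))
  }
  list(kappa = 1 - sum(w * O) / denom, weighting = weighting,
       n_items = length(rater_a), defined = TRUE)
}

#' Descriptive summaries of a scored corpus
#'
#' Returns the per-schema score-frequency table (counts and percentages of
#' scores 0..3), the record-depth histogram (one entry per thought record,
#' depth = number of utterances), and the per-record-type schema presence
#' percentages (share of utterances with score > 0) together with the mean
#' absolute open-versus-closed difference across schemas.
#'
#' @param corpus A corpus with manual scores on every utterance.
#' @return List with `score_freq` (data frame: schema, score, count,
#'   percent), `depth_hist` (named integer vector), `presence_by_type`
#'   (data frame: schema, record_type, percent) and `mean_abs_presence_diff`.
#' @export
descriptives <- function(corpus) {
  sc <- score_matrix(corpus)
  if (anyNA(sc)) {
    bad <- which(apply(is.na(sc), 1L, any))
    stop("missing manual scores in rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  N <- nrow(sc)
  freq <- do.call(rbind, lapply(seq_len(9L), function(s) {
    counts <- vapply(0:3, function(v) sum(sc[, s] == v), integer(1))
    data.frame(schema = schema_names()[s], score = 0:3, count = counts,
               percent = 100 * counts / N)
  }))
  rec_depth <- tapply(corpus$depth, corpus$record_id, max)
  depth_hist <- table(factor(rec_depth, levels = seq_len(max(rec_depth))))
  pres <- do.call(rbind, lapply(RECORD_TYPES, function(rt) {
    rows <- corpus$record_type == rt
    data.frame(schema = schema_names(),
               record_type = rt,
               percent = 100 * colMeans(sc[rows, , drop = FALSE] > 0))
  }))
  rownames(pres) <- NULL
  wide <- matrix(pres$percent, ncol = 2,
                 dimnames = list(schema_names(), RECORD_TYPES))
  list(score_freq = freq,
       depth_hist = depth_hist,
       presence_by_type = pres,
       mean_abs_presence_diff = mean(abs(wide[, "open"] - wide[, "closed"])))
}
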