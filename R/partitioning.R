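# Distribution-matched train/validation/test splitting.
#
# Candidate test sets are drawn uniformly without replacement and scored on
# three distributional criteria against the full corpus: (1) the nine
# per-schema nonzero-score proportions, (2) the proportion of utterances
# from open records, (3) the depth histogram (depths binned 1..6+). The
# minimum-deviation draw wins; the procedure is then repeated on the
# remaining utterances for the validation set.

#' Split configuration
#'
#' @param test_fraction Fraction of all utterances for the test set
#'   (default 0.15).
#' @param val_fraction Fraction of the remaining utterances for the
#'   validation set (default 0.15, i.e. 12.75% of all data).
#' @param n_draws Number of candidate draws per stage (default 1000).
#' @param seed Integer seed.
#' @param schema_criterion `"presence"` (default) compares per-schema
#'   nonzero-score proportions; `"histogram"` compares the full 4-level
#'   score histogram per schema.
#' @return A `split_config` list.
#' @export
split_config <- function(test_fraction = 0.15, val_fraction = 0.15,
                         n_draws = 1000L, seed = 1L,
                         schema_criterion = c("presence", "histogram")) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction > 0, val_fraction < 1, n_draws >= 1)
  structure(list(test_fraction = test_fraction, val_fraction = val_fraction,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 schema_criterion = match.arg(schema_criterion)),
            class = "split_config")
}

# round half away from zero, so 0.15 * 400 = 60 and 0.15 * 340 = 51 exactly
round_half_up <- function(x) floor(x + 0.5)

# per-utterance criterion features: presence indicators (or score-level
# indicators), open-record indicator, depth-bin indicators
split_features <- function(corpus, schema_criterion = "presence") {
  sc <- score_matrix(corpus)
  if (anyNA(sc)) stop("splitting requires manual scores on every utterance",
                      call. = FALSE)
  if (schema_criterion == "presence") {
    schema_f <- (sc > 0) * 1
  } else {
    schema_f <- do.call(cbind, lapply(0:3, function(v) (sc == v) * 1))
  }
  depth_bin <- pmin(corpus$depth, 6L)
  depth_f <- vapply(1:6, function(d) (depth_bin == d) * 1,
                    numeric(nrow(corpus)))
  list(schema = schema_f,
       open = (corpus$record_type == "open") * 1,
       depth = depth_f)
}

# deviation of a sample (given features) from population means
deviation_from_features <- function(idx, feats, pop) {
  d1 <- mean(abs(colMeans(feats$schema[idx, , drop = FALSE]) - pop$schema))
  d2 <- abs(mean(feats$open[idx]) - pop$open)
  d3 <- 0.5 * sum(abs(colMeans(feats$depth[idx, , drop = FALSE]) - pop$depth))
  d1 + d2 + d3
}

#' Distributional deviation of a candidate sample
#'
#' Returns `d1 + d2 + d3`: the mean absolute difference of the nine
#' per-schema nonzero-score proportions, the absolute difference in
#' open-record proportion, and the total-variation distance between the
#' depth histograms (depths binned 1..6+). A sample identical in
#' distribution to the population scores 0.
#'
#' @param sample Integer vector of utterance row indices.
#' @param population The full corpus.
#' @param schema_criterion See [split_config()].
#' @return Non-negative scalar deviation.
#' @export
split_deviation <- function(sample, population,
                            schema_criterion = "presence") {
  if (length(sample) == 0L) stop("sample must be non-empty", call. = FALSE)
  if (any(sample < 1L | sample > nrow(population))) {
    stop("sample indices out of range", call. = FALSE)
  }
  feats <- split_features(population, schema_criterion)
  pop <- list(schema = colMeans(feats$schema), open = mean(feats$open),
              depth = colMeans(feats$depth))
  deviation_from_features(sample, feats, pop)
}

#' Distribution-matched train/validation/test split
#'
#' Draws `n_draws` candidate test sets of size
#' `round(test_fraction * N)` uniformly without replacement, keeps the one
#' with minimum summed deviation (ties keep the first drawn), then repeats
#' on the remaining utterances for the validation set. With the defaults the
#' sets comprise 15%, 12.75% and 72.25% of the data. Deterministic given the
#' configuration seed.
#'
#' @param corpus A scored corpus with at least 10 utterances.
#' @param config A [split_config()].
#' @return A `data_split` list with integer index vectors `train`,
#'   `validation`, `test` (disjoint, covering the corpus) and
#'   `deviation_report`, the chosen deviation of the test and validation
#'   draws.
#' @export
matched_split <- function(corpus, config = split_config()) {
  N <- nrow(corpus)
  if (N < 10L) stop("corpus too small to split (need >= 10 utterances)",
                    call. = FALSE)
  n_test <- as.integer(round_half_up(config$test_fraction * N))
  n_val <- as.integer(round_half_up(config$val_fraction * (N - n_test)))
  if (n_test < 1L || n_val < 1L || n_test + n_val >= N) {
    stop("corpus too small for the requested fractions", call. = FALSE)
  }
  feats <- split_features(corpus, config$schema_criterion)
  pop <- list(schema = colMeans(feats$schema), open = mean(feats$open),
              depth = colMeans(feats$depth))
  with_seed(config$seed, {
    test_pick <- best_draw(seq_len(N), n_test, config$n_draws, feats, pop)
    remainder <- setdiff(seq_len(N), test_pick$idx)
    val_pick <- best_draw(remainder, n_val, config$n_draws, feats, pop)
    train <- setdiff(remainder, val_pick$idx)
    structure(list(train = sort(train),
                   validation = sort(val_pick$idx),
                   test = sort(test_pick$idx),
                   deviation_report = c(test = test_pick$deviation,
                                        validation = val_pick$deviation)),
              class = "data_split")
  })
}

best_draw <- function(pool, size, n_draws, feats, pop) {
  best <- NULL
  best_dev <- Inf
  for (i in seq_len(n_draws)) {
    idx <- pool[sample.int(length(pool), size)]
    dev <- deviation_from_features(idx, feats, pop)
    if (dev < best_dev) {  # strict: ties keep the first drawn
      best_dev <- dev
      best <- idx
    }
  }
  list(idx = best, deviation = best_dev)
}

#' Persist / restore a split as a membership table
#'
#' Three columns: utterance row index, subset name, and the chosen-draw
#' deviation of that subset's stage, so downstream stages can be re-run
#' bit-identically.
#'
#' @param split A `data_split`.
#' @param path Output path (tab-separated).
#' @return `write_split()` invisibly returns `path`; `read_split()` returns
#'   a `data_split`.
#' @export
write_split <- function(split, path) {
  rows <- rbind(
    data.frame(index = split$train, subset = "train",
               deviation = NA_real_),
    data.frame(index = split$validation, subset = "validation",
               deviation = split$deviation_report[["validation"]]),
    data.frame(index = split$test, subset = "test",
               deviation = split$deviation_report[["test"]]))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  structure(list(
    train = sort(rows$index[rows$subset == "train"]),
    validation = sort(rows$index[rows$subset == "validation"]),
    test = sort(rows$index[rows$subset == "test"]),
    deviation_report = c(
      test = rows$deviation[rows$subset == "test"][1],
      validation = rows$deviation[rows$subset == "validation"][1])),
    class = "data_split")
}
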