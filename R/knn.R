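# k-nearest-neighbour scoring on cosine similarity of averaged utterance
# embeddings. Classification combines neighbour scores with a conservative
# mode (the lowest value among co-modal scores); regression averages them.

#' kNN configuration
#'
#' @param mode `"classification"` (conservative mode combiner) or
#'   `"regression"` (mean combiner).
#' @param k Number of neighbours; defaults to 4 for classification and 5
#'   for regression, the values selected on the validation set of the
#'   original evaluation.
#' @return A `knn_config` list.
#' @export
knn_config <- function(mode = c("classification", "regression"), k = NULL) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- if (mode == "classification") 4L else 5L
  stopifnot(k >= 1)
  structure(list(mode = mode, k = as.integer(k)), class = "knn_config")
}

# cosine similarity of rows of q against rows of m; zero rows (all-OOV
# utterances) have similarity 0 to everything
cosine_similarity <- function(q, m) {
  qn <- sqrt(rowSums(q^2))
  mn <- sqrt(rowSums(m^2))
  qn[qn == 0] <- Inf
  mn[mn == 0] <- Inf
  (q %*% t(m)) / (qn %o% mn)
}

# conservative mode: most frequent value; the smallest among co-modal ones
conservative_mode <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Score utterances by k-nearest neighbours
#'
#' For each query, the `k` training utterances with the highest cosine
#' similarity are found (similarity ties broken by training index order).
#' Per schema, classification returns the modal neighbour score taking the
#' lowest value when several scores are equally frequent; regression
#' returns the arithmetic mean of the neighbour scores. A zero (all
#' out-of-vocabulary) query vector has similarity 0 to all training items.
#'
#' @param query Numeric matrix of query utterance vectors (rows), or a
#'   single vector.
#' @param train_x Numeric matrix of training utterance vectors.
#' @param train_y Numeric matrix of training scores (rows aligned with
#'   `train_x`, nine columns).
#' @param config A [knn_config()].
#' @return Numeric matrix, one row of nine predicted scores per query.
#' @export
knn_predict <- function(query, train_x, train_y, config = knn_config()) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  train_y <- as.matrix(train_y)
  if (config$k > nrow(train_x)) {
    stop("k exceeds the training-set size", call. = FALSE)
  }
  sims <- cosine_similarity(query, train_x)
  out <- matrix(NA_real_, nrow = nrow(query), ncol = ncol(train_y))
  for (i in seq_len(nrow(query))) {
    nb <- order(-sims[i, ])[seq_len(config$k)]  # stable: ties by train index
    ys <- train_y[nb, , drop = FALSE]
    out[i, ] <- if (config$mode == "classification") {
      apply(ys, 2L, conservative_mode)
    } else {
      colMeans(ys)
    }
  }
  colnames(out) <- colnames(train_y)
  out
}
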