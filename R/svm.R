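# Per-schema support-vector scoring with an RBF kernel on standardized
# averaged-embedding features. One independent model per schema;
# classification treats the four scores as nominal classes (one-versus-one
# multi-class), regression fits a real score clipped to [0, 3]. A schema
# whose training scores are constant cannot be fit: its predictions are that
# constant and the schema is flagged, which surfaces downstream as an
# undefined (nan) correlation.

#' SVM configuration
#'
#' @param mode `"classification"` or `"regression"`.
#' @param cost,gamma Optional RBF cost / bandwidth; `NULL` uses the
#'   library-conventional defaults (cost 1, gamma 1/dimension), which are
#'   recorded in the returned fit.
#' @return An `svm_config` list.
#' @export
svm_config <- function(mode = c("classification", "regression"),
                       cost = NULL, gamma = NULL) {
  structure(list(mode = match.arg(mode), cost = cost, gamma = gamma),
            class = "svm_config")
}

#' Fit per-schema SVMs and predict test scores
#'
#' Features are standardized by the training moments only (zero-variance
#' feature columns are left unscaled). Classification outputs integers in
#' `{0..3}`; regression outputs are clipped to `[0, 3]`.
#'
#' @param train_x,test_x Numeric feature matrices.
#' @param train_y Training score matrix (nine columns).
#' @param config An [svm_config()].
#' @return List with `predictions` (test rows x 9), `constant` (logical
#'   flag per schema: training scores had a single class, so the model
#'   predicts a constant) and `settings` (the kernel parameters used).
#' @export
svm_fit_predict <- function(train_x, train_y, test_x,
                            config = svm_config()) {
  train_y <- as.matrix(train_y)
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  tr <- sweep(sweep(train_x, 2L, mu), 2L, sdv, "/")
  te <- sweep(sweep(test_x, 2L, mu), 2L, sdv, "/")
  cost <- if (is.null(config$cost)) 1 else config$cost
  gamma <- if (is.null(config$gamma)) 1 / ncol(train_x) else config$gamma
  n_schema <- ncol(train_y)
  preds <- matrix(NA_real_, nrow = nrow(test_x), ncol = n_schema,
                  dimnames = list(NULL, colnames(train_y)))
  constant <- logical(n_schema)
  for (s in seq_len(n_schema)) {
    y <- train_y[, s]
    if (length(unique(y)) < 2L) {
      preds[, s] <- y[1]
      constant[s] <- TRUE
      next
    }
    if (config$mode == "classification") {
      fit <- e1071::svm(tr, factor(y, levels = 0:3), kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      preds[, s] <- as.numeric(as.character(stats::predict(fit, te)))
    } else {
      fit <- e1071::svm(tr, y, kernel = "radial", type = "eps-regression",
                        cost = cost, gamma = gamma, scale = FALSE)
      preds[, s] <- pmin(pmax(as.numeric(stats::predict(fit, te)), 0), 3)
    }
  }
  list(predictions = preds, constant = constant,
       settings = list(kernel = "radial", cost = cost, gamma = gamma,
                       mode = config$mode))
}
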