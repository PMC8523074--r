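# Recurrent scoring networks: an embedding-lookup input layer feeding a
# bidirectional LSTM whose final states drive either nine per-schema
# four-way softmax heads (one independent network per schema) or a single
# nine-unit sigmoid multi-label head. The networks are implemented directly
# in matrix code: forward pass, backpropagation through time, Adam updates,
# inverted dropout, and per-epoch validation checkpointing. Gradients are
# validated against numerical differentiation in the test suite.
#
# Training is deliberately stochastic across restarts; the unit of
# reproducibility is the median-of-restarts protocol (train n_restarts
# times, predict the test set with every restart, keep the median model by
# mean per-schema rank correlation), with every restart seed derived from
# the configuration seed.

#' RNN configuration
#'
#' @param variant `"per_schema"` (nine independent four-way softmax
#'   networks) or `"multi_label"` (one network with nine sigmoid outputs).
#' @param recurrent_units LSTM units per direction (default 100).
#' @param dropout Dropout probability on the recurrent output (default
#'   0.1).
#' @param batch_size Utterances per minibatch (default 32).
#' @param epochs Training epochs (default 100).
#' @param n_restarts Number of restarts for the median-model protocol
#'   (default 30).
#' @param learning_rate Adam step size.
#' @param max_len Pad/truncate length; `NULL` uses the 95th percentile of
#'   training sequence lengths.
#' @param seed Base seed; restart `r` trains with `seed + r`.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(variant = c("per_schema", "multi_label"),
                       recurrent_units = 100L, dropout = 0.1,
                       batch_size = 32L, epochs = 100L, n_restarts = 30L,
                       learning_rate = 1e-3, max_len = NULL, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_restarts >= 1, dropout >= 0, dropout < 1, epochs >= 1,
            recurrent_units >= 1, batch_size >= 1)
  structure(list(variant = variant,
                 recurrent_units = as.integer(recurrent_units),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_restarts = as.integer(n_restarts),
                 learning_rate = learning_rate, max_len = max_len,
                 seed = as.integer(seed)),
            class = "rnn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# parameter set for one network: forward + backward LSTM cells and a dense
# output layer on the concatenated final states
init_params <- function(d, H, K) {
  cell <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    list(Wx = glorot(d, 4 * H), Wh = glorot(H, 4 * H), b = b)
  }
  list(fwd = cell(), bwd = cell(),
       out = list(W = glorot(2 * H, K), b = numeric(K)))
}

# convert a token vector to an embedded sequence matrix (T x d), with each
# in-vocabulary vector L2-normalized and OOV tokens as zero rows; an empty
# sequence becomes a single zero row (null token)
tokens_to_seq <- function(tokens, table) {
  d <- table$dimension
  if (length(tokens) == 0L) return(matrix(0, 1L, d))
  idx <- match(tokens, rownames(table$vectors))
  m <- matrix(0, length(tokens), d)
  hit <- !is.na(idx)
  if (any(hit)) {
    v <- table$vectors[idx[hit], , drop = FALSE]
    norms <- sqrt(rowSums(v^2))
    norms[norms == 0] <- 1
    m[hit, ] <- v / norms
  }
  m
}

# pack sequences into time-major batch tensors, right-padded to L
pack_batch <- function(seqs, L) {
  B <- length(seqs)
  d <- ncol(seqs[[1]])
  X <- lapply(seq_len(L), function(t) matrix(0, B, d))
  mask <- matrix(0, B, L)
  for (i in seq_len(B)) {
    Ti <- min(nrow(seqs[[i]]), L)
    mask[i, seq_len(Ti)] <- 1
    for (t in seq_len(Ti)) X[[t]][i, ] <- seqs[[i]][t, ]
  }
  list(X = X, mask = mask, B = B, L = L)
}

# reverse the valid portion of each sequence (for the backward direction)
reverse_seqs <- function(seqs) {
  lapply(seqs, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
}

# LSTM forward over a packed batch; returns final hidden state and caches
lstm_forward <- function(cell, batch) {
  H <- length(cell$b) / 4L
  B <- batch$B
  h <- matrix(0, B, H)
  c_ <- matrix(0, B, H)
  caches <- vector("list", batch$L)
  for (t in seq_len(batch$L)) {
    m <- batch$mask[, t]
    z <- batch$X[[t]] %*% cell$Wx + h %*% cell$Wh +
      matrix(cell$b, B, 4 * H, byrow = TRUE)
    i_ <- sigmoid(z[, 1:H, drop = FALSE])
    f_ <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_ * c_ + i_ * g_
    tc <- tanh(c_new)
    h_new <- o_ * tc
    caches[[t]] <- list(i = i_, f = f_, g = g_, o = o_, tc = tc,
                        c_prev = c_, h_prev = h, x = batch$X[[t]], m = m)
    c_ <- m * c_new + (1 - m) * c_
    h <- m * h_new + (1 - m) * h
  }
  list(h = h, caches = caches)
}

# backpropagation through time; dh_final is the gradient at the final
# (post-mask) hidden state. Returns parameter gradients.
lstm_backward <- function(cell, batch, caches, dh_final) {
  H <- ncol(dh_final)
  dWx <- matrix(0, nrow(cell$Wx), ncol(cell$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), H)
  for (t in rev(seq_len(batch$L))) {
    cc <- caches[[t]]
    m <- cc$m
    dh_new <- m * dh
    dc_new <- m * dc
    dh_pass <- (1 - m) * dh
    dc_pass <- (1 - m) * dc
    do_ <- dh_new * cc$tc
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tc^2)
    di <- dc_new * cc$g
    df <- dc_new * cc$c_prev
    dg <- dc_new * cc$i
    dc_prev <- dc_new * cc$f + dc_pass
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$x) %*% dz
    dWh <- dWh + t(cc$h_prev) %*% dz
    db <- db + colSums(dz)
    dh <- dz %*% t(cell$Wh) + dh_pass
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# full forward pass to output logits; drop_mask NULL disables dropout
net_forward <- function(params, batch_fwd, batch_bwd, drop_mask = NULL) {
  fw <- lstm_forward(params$fwd, batch_fwd)
  bw <- lstm_forward(params$bwd, batch_bwd)
  hcat <- cbind(fw$h, bw$h)
  if (!is.null(drop_mask)) hcat <- hcat * drop_mask
  logits <- hcat %*% params$out$W +
    matrix(params$out$b, nrow(hcat), length(params$out$b), byrow = TRUE)
  list(logits = logits, hcat = hcat, fw = fw, bw = bw)
}

# gradients of all parameters given dLogits
net_backward <- function(params, fwd_pass, batch_fwd, batch_bwd, dlogits,
                         drop_mask = NULL) {
  H <- ncol(fwd_pass$fw$h)
  dW_out <- t(fwd_pass$hcat) %*% dlogits
  db_out <- colSums(dlogits)
  dhcat <- dlogits %*% t(params$out$W)
  if (!is.null(drop_mask)) dhcat <- dhcat * drop_mask
  g_fwd <- lstm_backward(params$fwd, batch_fwd, fwd_pass$fw$caches,
                         dhcat[, seq_len(H), drop = FALSE])
  g_bwd <- lstm_backward(params$bwd, batch_bwd, fwd_pass$bw$caches,
                         dhcat[, (H + 1):(2 * H), drop = FALSE])
  list(fwd = g_fwd, bwd = g_bwd, out = list(W = dW_out, b = db_out))
}

# loss + dLogits for the two heads
head_loss <- function(variant, logits, y) {
  if (variant == "per_schema") {
    # y: integer scores 0..3; categorical cross-entropy over 4 classes
    zmax <- apply(logits, 1L, max)
    ez <- exp(logits - zmax)
    p <- ez / rowSums(ez)
    B <- nrow(logits)
    onehot <- matrix(0, B, ncol(logits))
    onehot[cbind(seq_len(B), y + 1L)] <- 1
    loss <- -mean(log(pmax(rowSums(p * onehot), 1e-12)))
    list(loss = loss, dlogits = (p - onehot) / B, p = p)
  } else {
    # y: score matrix 0..3 scaled to [0,1]; elementwise cross-entropy
    t_ <- y / 3
    p <- sigmoid(logits)
    eps <- 1e-12
    loss <- -mean(t_ * log(p + eps) + (1 - t_) * log(1 - p + eps))
    list(loss = loss, dlogits = (p - t_) / length(p), p = p)
  }
}

# flatten/apply utilities over the nested parameter list
param_walk <- function(p, g, mom1, mom2, lr, b1, b2, eps, t) {
  for (part in names(p)) {
    for (nm in names(p[[part]])) {
      gr <- g[[part]][[nm]]
      mom1[[part]][[nm]] <- b1 * mom1[[part]][[nm]] + (1 - b1) * gr
      mom2[[part]][[nm]] <- b2 * mom2[[part]][[nm]] + (1 - b2) * gr^2
      mh <- mom1[[part]][[nm]] / (1 - b1^t)
      vh <- mom2[[part]][[nm]] / (1 - b2^t)
      p[[part]][[nm]] <- p[[part]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(p = p, mom1 = mom1, mom2 = mom2)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# train one network; y is an integer vector (per_schema) or matrix
# (multi_label). Checkpoints the epoch with the best validation metric
# (cross-entropy loss for per_schema, mean absolute error for multi_label).
train_net <- function(seqs, y, val_seqs, val_y, variant, d, H, K, cfg) {
  params <- init_params(d, H, K)
  mom1 <- zero_like(params)
  mom2 <- zero_like(params)
  n <- length(seqs)
  L <- cfg$L
  val_fwd <- pack_batch(val_seqs, L)
  val_bwd <- pack_batch(reverse_seqs(val_seqs), L)
  best <- list(metric = Inf, params = params)
  step <- 0L
  diverged <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bf <- pack_batch(seqs[idx], L)
      bb <- pack_batch(reverse_seqs(seqs[idx]), L)
      drop_mask <- if (cfg$dropout > 0) {
        matrix(stats::rbinom(length(idx) * 2 * H, 1L, 1 - cfg$dropout) /
                 (1 - cfg$dropout), length(idx), 2 * H)
      } else NULL
      fp <- net_forward(params, bf, bb, drop_mask)
      yb <- if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]
      hl <- head_loss(variant, fp$logits, yb)
      if (!is.finite(hl$loss)) { diverged <- TRUE; break }
      grads <- net_backward(params, fp, bf, bb, hl$dlogits, drop_mask)
      step <- step + 1L
      upd <- param_walk(params, grads, mom1, mom2, cfg$learning_rate,
                        0.9, 0.999, 1e-8, step)
      params <- upd$p; mom1 <- upd$mom1; mom2 <- upd$mom2
    }
    if (diverged) break
    vp <- net_forward(params, val_fwd, val_bwd, NULL)
    vl <- head_loss(variant, vp$logits,
                    if (is.matrix(val_y)) val_y else val_y)
    metric <- if (variant == "multi_label") {
      mean(abs(vl$p - val_y / 3))
    } else vl$loss
    if (is.finite(metric) && metric < best$metric) {
      best$metric <- metric
      best$params <- params
    }
  }
  list(params = best$params, val_metric = best$metric, diverged = diverged)
}

#' Fit recurrent scoring networks with restarts
#'
#' Trains `n_restarts` models (per restart: nine independent networks for
#' the `per_schema` variant, one network for `multi_label`), each restart
#' seeded with `seed + restart`. Sequences are padded or truncated to the
#' 95th percentile of training lengths; empty sequences become a single
#' null token. Restarts whose loss becomes non-finite are flagged and
#' excluded from selection.
#'
#' @param train_tokens,val_tokens Lists of token vectors (from
#'   [preprocess()]).
#' @param train_y,val_y Score matrices (utterances x 9).
#' @param table An [embedding_table()] supplying the frozen lookup layer.
#' @param config An [rnn_config()].
#' @return An `rnn_fit` list: `restarts` (list of parameter sets),
#'   `flagged`, `seeds`, `max_len`, `config`.
#' @export
rnn_fit <- function(train_tokens, train_y, val_tokens, val_y, table,
                    config = rnn_config()) {
  train_y <- as.matrix(train_y)
  val_y <- as.matrix(val_y)
  d <- table$dimension
  H <- config$recurrent_units
  seqs <- lapply(train_tokens, tokens_to_seq, table = table)
  vseqs <- lapply(val_tokens, tokens_to_seq, table = table)
  L <- config$max_len
  if (is.null(L)) {
    L <- max(1L, as.integer(ceiling(
      stats::quantile(vapply(seqs, nrow, integer(1)), 0.95))))
  }
  cfg <- config
  cfg$L <- L
  restarts <- vector("list", config$n_restarts)
  flagged <- logical(config$n_restarts)
  seeds <- config$seed + seq_len(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    restarts[[r]] <- with_seed(seeds[r], {
      if (config$variant == "per_schema") {
        nets <- lapply(seq_len(ncol(train_y)), function(s) {
          train_net(seqs, as.integer(train_y[, s]), vseqs,
                    as.integer(val_y[, s]), "per_schema", d, H, 4L, cfg)
        })
        list(nets = nets,
             diverged = any(vapply(nets, `[[`, logical(1), "diverged")))
      } else {
        net <- train_net(seqs, train_y, vseqs, val_y, "multi_label",
                         d, H, ncol(train_y), cfg)
        list(nets = list(net), diverged = net$diverged)
      }
    })
    flagged[r] <- restarts[[r]]$diverged
  }
  structure(list(restarts = restarts, flagged = flagged, seeds = seeds,
                 max_len = L, config = config),
            class = "rnn_fit")
}

# predictions of one restart on a list of token sequences
rnn_predict_restart <- function(restart, tokens, table, config, max_len) {
  seqs <- lapply(tokens, tokens_to_seq, table = table)
  bf <- pack_batch(seqs, max_len)
  bb <- pack_batch(reverse_seqs(seqs), max_len)
  if (config$variant == "per_schema") {
    cols <- lapply(restart$nets, function(net) {
      fp <- net_forward(net$params, bf, bb, NULL)
      p <- head_loss("per_schema", fp$logits,
                     integer(nrow(fp$logits)))$p
      max.col(p, ties.method = "first") - 1
    })
    do.call(cbind, cols)
  } else {
    fp <- net_forward(restart$nets[[1]]$params, bf, bb, NULL)
    sigmoid(fp$logits)
  }
}

#' Predict schema scores with a fitted RNN restart
#'
#' The `per_schema` variant returns integer scores in `{0..3}` (the class
#' with the highest softmax confidence per schema); `multi_label` returns
#' the raw sigmoid outputs in `[0, 1]`, which downstream rank-based
#' evaluation consumes without rescaling.
#'
#' @param fit An `rnn_fit`.
#' @param tokens List of token vectors.
#' @param table The embedding table used for fitting.
#' @param restart Which restart to use (default the first unflagged one).
#' @return Numeric matrix, utterances x 9.
#' @export
rnn_predict <- function(fit, tokens, table, restart = NULL) {
  if (is.null(restart)) restart <- which(!fit$flagged)[1]
  if (is.na(restart)) stop("all restarts are flagged", call. = FALSE)
  rnn_predict_restart(fit$restarts[[restart]], tokens, table, fit$config,
                      fit$max_len)
}

#' Select the median model across restarts
#'
#' Every unflagged restart predicts the test set; its performance is the
#' mean over schemas of the per-schema rank correlation between predicted
#' and manual scores (schemas with an undefined correlation are excluded
#' from the mean). Restarts are sorted ascending by performance and the
#' element at rank `ceiling(n/2)` is returned (the lower middle for even
#' `n`), deterministically and invariantly to restart order.
#'
#' @param fit An `rnn_fit`.
#' @param test_tokens List of token vectors for the test set.
#' @param test_y Manual score matrix of the test set.
#' @param table The embedding table used for fitting.
#' @return List with `restart` (index into `fit$restarts`), `performance`,
#'   `predictions` (the median restart's test predictions) and
#'   `all_performance`.
#' @export
select_median_model <- function(fit, test_tokens, test_y, table) {
  ok <- which(!fit$flagged)
  if (length(ok) == 0L) stop("all restarts are flagged", call. = FALSE)
  test_y <- as.matrix(test_y)
  preds <- lapply(ok, function(r) {
    rnn_predict_restart(fit$restarts[[r]], test_tokens, table, fit$config,
                        fit$max_len)
  })
  perf <- vapply(preds, function(p) mean_schema_spearman(p, test_y),
                 numeric(1))
  med <- median_rank_index(perf)
  list(restart = ok[med], performance = perf[med],
       predictions = preds[[med]],
       all_performance = stats::setNames(perf, ok))
}

# mean per-schema Spearman, undefined schemas excluded; NA if none defined
mean_schema_spearman <- function(pred, truth) {
  rhos <- vapply(seq_len(ncol(truth)), function(s) {
    r <- spearman_rho(pred[, s], truth[, s])
    if (r$defined) r$rho else NA_real_
  }, numeric(1))
  if (all(is.na(rhos))) NA_real_ else mean(rhos, na.rm = TRUE)
}

# index of the lower-middle element of x under ascending order; stable
median_rank_index <- function(x) {
  ord <- order(x)  # stable; NA last
  ord[ceiling(sum(!is.na(x)) / 2)]
}
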