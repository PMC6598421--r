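#' @useDynLib dealerscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

param_shapes <- function(config, vocab_size) {
  De <- config$embedding_dim; H <- config$lstm_units
  D <- config$dense_units
  list(
    emb_t = c(vocab_size, De), w_t = c(De, 4 * H), u_t = c(H, 4 * H),
    b_t = c(1, 4 * H), wd_t = c(H, D), bd_t = c(1, D),
    emb_h = c(vocab_size, De), w_h = c(De, 4 * H), u_h = c(H, 4 * H),
    b_h = c(1, 4 * H), wd_h = c(H, D), bd_h = c(1, D),
    w_c = c(2 * D, D), b_c = c(1, D), w_o = c(D, 1), b_o = c(1, 1)
  )
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the untrained two-branch recurrent classifier
#'
#' Architecture: a text branch (embedding over `l_text` positions, one
#' layer of long short-term memory units, a sigmoid dense layer) and a
#' hashtag branch of the same shape over `l_hash` positions; the two
#' branch vectors are merged by concatenation and passed through a third
#' sigmoid dense layer and a final 1-unit sigmoid layer emitting the
#' dealer probability. Padding index 0 is masked out of the recurrent
#' computation. Initialization is deterministic in `config$seed`
#' (Glorot-uniform weights, forget-gate bias 1, embeddings uniform in
#' +/- 0.05).
#'
#' @param config A [model_config()].
#' @param vocab_size Number of distinct nonzero indices the model accepts
#'   (dictionary size plus the reserved unknown index).
#' @return An object of class `deep_dealer_model`.
#' @export
build_deep_model <- function(config, vocab_size) {
  stopifnot(inherits(config, "model_config"), vocab_size >= 1)
  H <- config$lstm_units
  shapes <- param_shapes(config, vocab_size)
  params <- with_seed(config$seed, {
    p <- lapply(shapes, function(s) glorot(s[1], s[2]))
    p$emb_t <- matrix(stats::runif(prod(shapes$emb_t), -0.05, 0.05),
                      shapes$emb_t[1], shapes$emb_t[2])
    p$emb_h <- matrix(stats::runif(prod(shapes$emb_h), -0.05, 0.05),
                      shapes$emb_h[1], shapes$emb_h[2])
    for (b in c("b_t", "b_h", "bd_t", "bd_h", "b_c", "b_o")) {
      p[[b]][] <- 0
    }
    p$b_t[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
    p$b_h[1, (H + 1):(2 * H)] <- 1
    p
  })
  structure(list(params = params, config = config,
                 vocab_size = as.integer(vocab_size),
                 trained = FALSE, state = NULL),
            class = "deep_dealer_model")
}

#' Number of trainable parameters
#'
#' @param model A `deep_dealer_model`.
#' @return Integer count of trainable scalars, a deterministic function of
#'   the configuration and vocabulary size.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.deep_dealer_model <- function(x, ...) {
  cat(sprintf(
    "<deep_dealer_model: vocab %d, emb %d, lstm %d, dense %d, %s params%s>\n",
    x$vocab_size, x$config$embedding_dim, x$config$lstm_units,
    x$config$dense_units, format(n_parameters(x), big.mark = ","),
    if (x$trained) ", trained" else ""))
  invisible(x)
}

# Drop all-padding trailing columns (masked anyway); keeps >= 1 column.
trim_cols <- function(m) {
  nz <- which(colSums(m != 0L) > 0L)
  keep <- if (length(nz) == 0L) 1L else seq_len(max(nz))
  m[, keep, drop = FALSE]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

forward_prob <- function(params, text, hash, chunk = 512L) {
  n <- nrow(text)
  p <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    p[idx] <- cpp_deep_forward(params, text[idx, , drop = FALSE],
                               hash[idx, , drop = FALSE])
  }
  p
}

#' Train the two-branch classifier
#'
#' Minimizes mean [binary_cross_entropy()] by minibatch Adam at the
#' configured learning rate. After every epoch the validation loss is
#' recorded; training stops early when [early_stop_check()] fires (the
#' most recent validation loss exceeds each of the previous
#' `early_stop_window` losses) or at `max_epochs`. All randomness (batch
#' order, dropout masks) derives from `config$seed`.
#'
#' @param model An untrained [build_deep_model()] object.
#' @param train,val Encoded example sets (lists with integer matrices
#'   `text`, `hash` and binary vector `label`), disjoint and non-empty.
#' @param config Training configuration; defaults to the model's own.
#' @param verbose Print per-epoch losses.
#' @return The model with trained parameters and a `state` list: `epochs`
#'   run, `train_loss` history, `val_loss` history, `stopped_early` flag.
#' @export
train_deep <- function(model, train, val, config = model$config,
                       verbose = FALSE) {
  stopifnot(inherits(model, "deep_dealer_model"))
  if (length(train$label) == 0L || length(val$label) == 0L) {
    stop("training and validation sets must both be non-empty")
  }
  if (!is.null(train$post_id) && !is.null(val$post_id) &&
      length(intersect(train$post_id, val$post_id)) > 0L) {
    stop("training and validation sets must be disjoint")
  }
  tr_text <- trim_cols(train$text); tr_hash <- trim_cols(train$hash)
  va_text <- trim_cols(val$text);   va_hash <- trim_cols(val$hash)
  y <- as.numeric(train$label)
  n <- length(y)
  params <- model$params
  opt <- adam_init(params)
  train_hist <- val_hist <- numeric(0)
  stopped <- FALSE
  step <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1L)]
        step <- step + 1L
        drop_seed <- salt_seed(config$seed, step * 104729)
        res <- cpp_deep_grad(params,
                             tr_text[idx, , drop = FALSE],
                             tr_hash[idx, , drop = FALSE],
                             y[idx], config$lstm_dropout,
                             config$lstm_recurrent_dropout,
                             as.integer(drop_seed))
        upd <- adam_step(params, res$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        batch_losses <- c(batch_losses, res$loss)
      }
      train_hist <- c(train_hist, mean(batch_losses))
      vp <- forward_prob(params, va_text, va_hash)
      val_hist <- c(val_hist, binary_cross_entropy(val$label, vp))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                        train_hist[epoch], val_hist[epoch]))
      }
      if (early_stop_check(val_hist, config$early_stop_window)) {
        stopped <- TRUE
        break
      }
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$state <- list(epochs = length(val_hist), train_loss = train_hist,
                      val_loss = val_hist, stopped_early = stopped)
  model
}

#' Predict dealer probabilities and labels
#'
#' One prediction per example; the decision rule is strict: label 1 iff
#' the probability is strictly greater than the configured threshold
#' (default 0.5), so a probability of exactly 0.5 yields label 0.
#'
#' @param object A trained `deep_dealer_model`.
#' @param newdata Encoded examples (list with matrices `text`, `hash`).
#' @param ... Unused.
#' @return A data.frame with columns `prob` and `label` (and `post_id`
#'   when available in `newdata`).
#' @export
predict.deep_dealer_model <- function(object, newdata, ...) {
  if (ncol(newdata$text) != object$config$l_text ||
      ncol(newdata$hash) != object$config$l_hash) {
    stop(sprintf(
      "encoded lengths (%d, %d) do not match model config (%d, %d)",
      ncol(newdata$text), ncol(newdata$hash),
      object$config$l_text, object$config$l_hash))
  }
  p <- forward_prob(object$params, trim_cols(newdata$text),
                    trim_cols(newdata$hash))
  out <- data.frame(prob = p,
                    label = as.integer(p > object$config$decision_threshold))
  if (!is.null(newdata$post_id)) out <- cbind(post_id = newdata$post_id, out)
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `config.json` (architecture and
#' training configuration plus vocabulary size) and `weights.json` (all
#' parameter matrices). Loading restores predictions exactly.
#'
#' @param model A `deep_dealer_model`.
#' @param dir Checkpoint directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg_out <- unclass(cfg)
  jsonlite::write_json(
    list(config = cfg_out, vocab_size = model$vocab_size,
         trained = model$trained),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$params, file.path(dir, "weights.json"),
                       digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[
    setdiff(names(meta$config), character())])
  raw <- jsonlite::fromJSON(file.path(dir, "weights.json"),
                            simplifyVector = TRUE)
  params <- lapply(raw, function(x) {
    if (is.matrix(x)) x else matrix(x, nrow = 1)
  })
  model <- build_deep_model(cfg, meta$vocab_size)
  model$params <- params[names(model$params)]
  model$trained <- meta$trained
  model
}
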