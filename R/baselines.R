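#' Term feature matrix for the classical baselines
#'
#' The baselines consume untruncated term vectors over the shared
#' dictionary: one column per dictionary index plus the unknown index,
#' holding binary presence (default) or term frequency. Text and hashtag
#' tokens contribute according to the active dataset variant (the
#' restriction already applied by [make_variants()]).
#'
#' @param posts List of clean posts (a variant's `posts`).
#' @param vocab A `vocabulary`.
#' @param type `"presence"` or `"frequency"`.
#' @return A numeric matrix, rows = posts, columns `f1..f<size+1>`.
#' @export
term_features <- function(posts, vocab, type = c("presence", "frequency")) {
  type <- match.arg(type)
  ncol <- vocab$size + 1L
  x <- matrix(0, length(posts), ncol,
              dimnames = list(NULL, paste0("f", seq_len(ncol))))
  for (i in seq_along(posts)) {
    toks <- c(posts[[i]]$text_tokens, posts[[i]]$hashtag_tokens)
    if (length(toks) == 0L) next
    idx <- unname(vocab$word_to_index[toks])
    idx[is.na(idx)] <- vocab$unknown_index
    tab <- table(idx)
    cols <- as.integer(names(tab))
    x[i, cols] <- if (type == "presence") 1 else as.numeric(tab)
  }
  x
}

#' Train a classical baseline classifier
#'
#' Fits one of the three reference models on a term feature matrix:
#' a CART decision tree (`rpart`), a random forest (`randomForest`), or a
#' linear-kernel support vector machine (`e1071::svm`). All three expose
#' a predicted probability -- class frequency in the tree leaf, forest
#' vote fraction, or the SVM decision value mapped through a logistic
#' link -- so ranking metrics (AUC) are computable for every model.
#'
#' @param kind `"decision_tree"`, `"random_forest"` or `"svm"`.
#' @param x Feature matrix from [term_features()].
#' @param y Binary label vector.
#' @param seed Integer seed (tree bagging, etc.).
#' @param ntree Number of trees for the random forest.
#' @param ... Passed to the underlying fitting function.
#' @return An object of class `baseline_model`.
#' @export
train_baseline <- function(kind = c("decision_tree", "random_forest", "svm"),
                           x, y, seed = 1L, ntree = 200L, ...) {
  kind <- match.arg(kind)
  stopifnot(nrow(x) == length(y), nrow(x) > 0)
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(seed, switch(kind,
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class", ...)
    },
    random_forest = randomForest::randomForest(x, yf, ntree = ntree, ...),
    svm = e1071::svm(x, yf, kernel = "linear", scale = FALSE, ...)
  ))
  structure(list(kind = kind, fit = fit, n_features = ncol(x)),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model %s over %d term features>\n",
              x$kind, x$n_features))
  invisible(x)
}

#' Predict with a baseline classifier
#'
#' @param object A `baseline_model`.
#' @param newdata Feature matrix with the same columns as at training.
#' @param threshold Decision threshold (strictly greater, default 0.5).
#' @param ... Unused.
#' @return A data.frame with columns `prob` (probability of the dealer
#'   class) and `label`.
#' @export
predict.baseline_model <- function(object, newdata, threshold = 0.5, ...) {
  prob <- switch(object$kind,
    decision_tree = {
      stats::predict(object$fit, as.data.frame(newdata), type = "prob")[, "1"]
    },
    random_forest = {
      stats::predict(object$fit, newdata, type = "prob")[, "1"]
    },
    svm = {
      pr <- stats::predict(object$fit, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values are signed towards the first level named in the
      # column label ("a/b" means positive favours class a)
      lv <- strsplit(colnames(dv)[1], "/")[[1]]
      d <- as.numeric(dv[, 1])
      if (lv[1] == "1") stats::plogis(d) else stats::plogis(-d)
    })
  data.frame(prob = unname(prob), label = as.integer(prob > threshold))
}
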