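# Binary food / non-food post classification on tf-idf features. Detected
# multiword phrases enter the vocabulary as single features and consume their
# component unigrams. Class order convention everywhere: (food, non-food).

CLASS_LEVELS <- c("food", "non-food")

# Feature tokens of one post: matched phrase forms (single features) plus
# residual canonical unigrams.
post_feature_tokens <- function(post, inventory = NULL) {
  toks <- if (inherits(post, "clean_post")) post$tokens else as.character(post)
  if (!length(toks)) return(character(0))
  canon <- singularize_tokens(toks)
  if (is.null(inventory) || !length(inventory$forms)) return(canon)
  feats <- character(0)
  for (g in extract_content_groups(post)) {
    m <- match_mwe(g, inventory)
    covered <- integer(0)
    for (mm in m$matches) {
      feats <- c(feats, mm$key)
      covered <- c(covered, mm$positions)
    }
    rest <- setdiff(g$positions, covered)
    feats <- c(feats, canon[rest])
  }
  feats
}

#' Build tf-idf features for a corpus
#'
#' Vocabulary is the union of unigrams and matched phrase forms (phrase
#' occurrences consume their unigrams). Term frequency is the raw count,
#' `idf = ln((1 + N) / (1 + df)) + 1` (smoothed), and rows are L2-normalized.
#'
#' @param posts Non-empty list of `clean_post` objects (or token vectors).
#' @param inventory Optional `phrase_inventory` whose forms become single
#'   features.
#' @param spec Optional `feature_spec` from a previous call; when given, the
#'   corpus is projected onto that vocabulary and idf (out-of-vocabulary
#'   features are dropped) — use this to featurize test data.
#' @return List with `spec` (vocabulary, idf, norm) and `x`, a sparse
#'   document-feature matrix (`Matrix::dgCMatrix`, one row per post).
#' @export
build_features <- function(posts, inventory = NULL, spec = NULL) {
  if (!length(posts)) schema_error("build_features: empty corpus")
  docs <- lapply(posts, post_feature_tokens, inventory = inventory)
  n <- length(docs)
  if (is.null(spec)) {
    vocabulary <- sort(unique(unlist(docs, use.names = FALSE)))
    df <- integer(length(vocabulary))
    for (d in docs) {
      df <- df + (vocabulary %in% d)
    }
    idf <- log((1 + n) / (1 + df)) + 1
    spec <- structure(list(vocabulary = vocabulary, idf = idf, norm = "l2"),
                      class = "feature_spec")
  }
  doc_id <- rep(seq_len(n), lengths(docs))
  term_id <- match(unlist(docs, use.names = FALSE), spec$vocabulary)
  keep <- !is.na(term_id)
  x <- Matrix::sparseMatrix(
    i = doc_id[keep], j = term_id[keep], x = 1,
    dims = c(n, length(spec$vocabulary)),
    dimnames = list(NULL, spec$vocabulary))
  x <- x %*% Matrix::Diagonal(x = spec$idf)
  rn <- sqrt(Matrix::rowSums(x^2))
  rn[rn == 0] <- 1
  x <- Matrix::Diagonal(x = 1 / rn) %*% x
  colnames(x) <- spec$vocabulary
  list(spec = spec, x = methods::as(x, "CsparseMatrix"))
}

# Multinomial naive Bayes with Laplace smoothing, the standard naive Bayes
# variant for weighted bag-of-words features.
fit_multinomial_nb <- function(x, y, alpha = 1) {
  x <- methods::as(x, "CsparseMatrix")
  log_prior <- log(as.numeric(table(y)) / length(y))
  names(log_prior) <- levels(y)
  log_lik <- sapply(levels(y), function(cl) {
    counts <- Matrix::colSums(x[y == cl, , drop = FALSE]) + alpha
    log(counts / sum(counts))
  })
  structure(list(log_prior = log_prior, log_lik = log_lik, alpha = alpha),
            class = "multinomial_nb")
}

predict_multinomial_nb <- function(fit, x) {
  scores <- as.matrix(x %*% fit$log_lik)
  scores <- sweep(scores, 2, fit$log_prior, "+")
  colnames(scores)[max.col(scores, ties.method = "first")]
}

LR_LAMBDA_PATH <- exp(seq(log(1), log(1e-4), length.out = 50))

#' Train a food / non-food classifier
#'
#' @param kind One of `"nb"` (multinomial naive Bayes with Laplace
#'   smoothing), `"lr"` (ridge-regularized logistic regression along a
#'   `glmnet` path, predictions at the smallest penalty), `"rf"`
#'   (random forest, `ranger`), `"svm"` (linear-kernel SVM, `e1071::svm`).
#' @param x Document-feature matrix from [build_features()].
#' @param labels Vector coercible to factor with levels food / non-food;
#'   both classes must be present.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `food_classifier` object with a [predict][predict.food_classifier]
#'   method.
#' @export
food_classifier <- function(kind = c("nb", "lr", "rf", "svm"), x, labels,
                            seed = 1L) {
  kind <- match.arg(kind)
  y <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (anyNA(y)) schema_error("labels must be 'food' or 'non-food'")
  if (length(unique(y)) < 2L) {
    schema_error("training labels contain a single class")
  }
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  fit <- switch(kind,
    nb = fit_multinomial_nb(x, y),
    lr = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = LR_LAMBDA_PATH, standardize = FALSE),
    rf = ranger::ranger(x = as.matrix(x), y = y, num.trees = 200L,
                        seed = seed, num.threads = 1L),
    svm = e1071::svm(as.matrix(x), y, kernel = "linear", scale = FALSE,
                     cost = 1))
  structure(list(kind = kind, fit = fit, levels = CLASS_LEVELS, seed = seed),
            class = "food_classifier")
}

#' @export
print.food_classifier <- function(x, ...) {
  cat(sprintf("<food_classifier kind=%s seed=%d>\n", x$kind, x$seed))
  invisible(x)
}

#' Predict food / non-food labels
#'
#' @param object A `food_classifier`.
#' @param newdata Feature matrix built with the training `feature_spec`.
#' @param ... Unused.
#' @return Factor with levels `food`, `non-food`.
#' @export
predict.food_classifier <- function(object, newdata, ...) {
  out <- switch(object$kind,
    nb = predict_multinomial_nb(object$fit, newdata),
    lr = {
      p <- as.numeric(predict(object$fit, newdata, type = "response",
                              s = min(LR_LAMBDA_PATH)))
      # glmnet models P(second level) = P(non-food)
      ifelse(p > 0.5, CLASS_LEVELS[2], CLASS_LEVELS[1])
    },
    rf = predict(object$fit, data = as.matrix(newdata),
                 num.threads = 1L)$predictions,
    svm = predict(object$fit, as.matrix(newdata)))
  factor(as.character(out), levels = CLASS_LEVELS)
}

#' Evaluation report: confusion matrix, accuracy, false-positive rate
#'
#' Rows of the confusion matrix are the true class, columns the predicted
#' class, in the fixed order (food, non-food). The false-positive rate is the
#' proportion of true non-food posts predicted food, i.e.
#' `row_normalized["non-food", "food"]`.
#'
#' @param truth,predicted Vectors coercible to the food / non-food factor;
#'   both true classes must be present (row normalization).
#' @return An `eval_report`: list with `confusion`, `row_normalized`,
#'   `accuracy`, `false_positive_rate`, `n`.
#' @export
eval_report <- function(truth, predicted) {
  t <- factor(as.character(truth), levels = CLASS_LEVELS)
  p <- factor(as.character(predicted), levels = CLASS_LEVELS)
  if (!length(t)) schema_error("empty test set")
  if (length(unique(t[!is.na(t)])) < 2L) {
    schema_error("both true classes must be present for row normalization")
  }
  confusion <- table(truth = t, predicted = p)
  row_normalized <- sweep(confusion, 1, rowSums(confusion), "/")
  structure(list(
    confusion = confusion,
    row_normalized = row_normalized,
    accuracy = sum(diag(confusion)) / sum(confusion),
    false_positive_rate = row_normalized["non-food", "food"],
    n = sum(confusion)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.3f, false-positive rate %.3f (n = %d)\n",
              x$accuracy, x$false_positive_rate, x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a classifier on a test set
#'
#' @param model A `food_classifier`.
#' @param x Test feature matrix (built with the training spec).
#' @param labels True labels.
#' @return An [eval_report()].
#' @export
evaluate_classifier <- function(model, x, labels) {
  if (!nrow(x)) schema_error("empty test set")
  eval_report(labels, predict(model, x))
}

#' Stratified train/test split
#'
#' @param labels Label vector.
#' @param p Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, p = 0.8, seed = 8020L) {
  set.seed(seed)
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(g) {
    sample(g, floor(p * length(g)))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Learning curve: held-out accuracy vs training size
#'
#' A stratified 80/20 split with a fixed seed defines a common held-out set.
#' For each training size (strictly increasing) and each seed, a stratified
#' subsample of the training pool is drawn, a classifier is trained, and
#' held-out accuracy recorded; points are means over seeds.
#'
#' @param kind Classifier kind (see [food_classifier()]).
#' @param x Feature matrix for the whole corpus.
#' @param labels Labels for the whole corpus.
#' @param sizes Strictly increasing training sizes (each within the training
#'   pool).
#' @param seeds Integer vector of seeds.
#' @return A `learning_curve` data frame with columns `size`, `accuracy`
#'   (mean over seeds), `se` (standard error over seeds).
#' @export
learning_curve <- function(kind, x, labels, sizes, seeds = 1:5) {
  if (is.unsorted(sizes, strictly = TRUE)) {
    schema_error("training sizes must be strictly increasing")
  }
  split <- stratified_split(labels, 0.8)
  pool <- split$train
  if (max(sizes) > length(pool)) {
    schema_error("training size %d exceeds the training pool (%d)",
                 max(sizes), length(pool))
  }
  x_test <- x[split$test, , drop = FALSE]
  y_test <- labels[split$test]
  acc <- matrix(NA_real_, length(sizes), length(seeds))
  for (j in seq_along(seeds)) {
    for (i in seq_along(sizes)) {
      set.seed(seeds[j] * 1000L + i)
      sub <- unlist(lapply(split(pool, labels[pool]), function(g) {
        sample(g, max(1L, round(sizes[i] * length(g) / length(pool))))
      }), use.names = FALSE)
      m <- food_classifier(kind, x[sub, , drop = FALSE], labels[sub],
                           seed = seeds[j])
      acc[i, j] <- eval_report(y_test, predict(m, x_test))$accuracy
    }
  }
  out <- data.frame(size = sizes, accuracy = rowMeans(acc),
                    se = apply(acc, 1, stats::sd) / sqrt(length(seeds)))
  structure(out, seeds = seeds, class = c("learning_curve", "data.frame"))
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$size, x$accuracy, type = "b", pch = 19,
                 xlab = "training samples", ylab = "held-out accuracy", ...)
  graphics::arrows(x$size, x$accuracy - x$se, x$size, x$accuracy + x$se,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Weak-supervision labels from lexicon matches
#'
#' Labels a post "food" iff at least one unmasked token or phrase matches the
#' food lexicon; idiom-masked food words do not count.
#'
#' @param posts List of `clean_post` objects.
#' @param food_lexicon A food lexicon.
#' @param masks Optional list of per-post masks from [flag_food_idioms()].
#' @return Factor with levels food / non-food, one per post.
#' @export
weak_labels <- function(posts, food_lexicon, masks = NULL) {
  lab <- vapply(seq_along(posts), function(i) {
    counts <- count_mentions(posts[i], food_lexicon,
                             if (!is.null(masks)) masks[i] else NULL)
    if (length(counts)) "food" else "non-food"
  }, character(1))
  factor(lab, levels = CLASS_LEVELS)
}
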