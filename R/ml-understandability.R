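#' @title Machine-learning understandability estimators
#' @description
#' Latent semantic features (TF-IDF followed by a rank-10 truncated SVD)
#' computed on three background corpora of graded difficulty — lay forum
#' text (label 1), encyclopedic text (label 2) and biomedical literature
#' (label 3) — and a zoo of regressors and classifiers trained on those
#' labels. A regressor's output is read as a difficulty score (higher =
#' harder); classifiers return one of the three class labels. Cross-fitted
#' predictions keep each assessed document's estimate out-of-fold, with a
#' final model trained on all assessed data for scoring unassessed
#' documents.
#' @name ml_understandability
NULL

.rr_regressors <- c("linear_regressor", "mlp_regressor",
                    "random_forest_regressor", "svm_regressor",
                    "gbt_regressor")
.rr_classifiers <- c("logistic", "mlp_classifier", "random_forest_classifier",
                     "svm_classifier", "multinomial_nb", "gbt_classifier")

.rr_dtm <- function(token_list, vocab) {
  m <- matrix(0, nrow = length(token_list), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_list)) {
    tf <- table(token_list[[i]])
    tf <- tf[names(tf) %in% vocab]
    if (length(tf)) m[i, names(tf)] <- as.numeric(tf)
  }
  m
}

#' Fit a latent semantic model (TF-IDF + truncated SVD)
#'
#' Term frequencies are natural counts; idf uses add-one smoothing,
#' `idf(t) = log((1 + N) / (1 + df(t))) + 1`; TF-IDF rows are
#' L2-normalized before a truncated SVD retains `dims` right singular
#' vectors. Singular-vector signs are fixed deterministically (the entry of
#' largest magnitude in each component is made positive), so the model is
#' identical across runs and platforms.
#'
#' @param corpus_docs document collection (texts, word vectors or
#'   `tokenized_text`s); must contain at least `dims` documents.
#' @param dims number of latent dimensions (default 10).
#' @param seed recorded for provenance (the fit itself is deterministic).
#' @return object of class `lsa_model`: `vocab`, `idf`, `v` (projection
#'   matrix), `dims`, `seed`.
#' @export
fit_lsa <- function(corpus_docs, dims = 10, seed = 1L) {
  tokens <- .rr_as_token_list(corpus_docs)
  if (length(tokens) < dims)
    stop("need at least ", dims, " documents to fit ", dims, " dimensions")
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  if (length(vocab) < dims) stop("vocabulary smaller than dims")
  x <- .rr_dtm(tokens, vocab)
  n <- nrow(x)
  df <- colSums(x > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  xt <- sweep(x, 2L, idf, `*`)
  norms <- sqrt(rowSums(xt^2)); norms[norms == 0] <- 1
  xt <- xt / norms
  sv <- svd(xt, nu = 0, nv = dims)
  v <- sv$v[, seq_len(dims), drop = FALSE]
  for (j in seq_len(dims)) {          # deterministic sign convention
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- vocab
  structure(list(vocab = vocab, idf = setNames(idf, vocab), v = v,
                 dims = dims, seed = seed), class = "lsa_model")
}

#' Project documents into the latent space
#'
#' Out-of-vocabulary terms are dropped; an empty or fully-OV document maps
#' to the zero vector (it can still be scored downstream).
#'
#' @param model an `lsa_model`.
#' @param docs documents (texts, word vectors or `tokenized_text`s).
#' @return numeric matrix, one row per document, `model$dims` columns.
#' @export
lsa_transform <- function(model, docs) {
  stopifnot(inherits(model, "lsa_model"))
  tokens <- .rr_as_token_list(docs)
  x <- .rr_dtm(tokens, model$vocab)
  xt <- sweep(x, 2L, model$idf, `*`)
  norms <- sqrt(rowSums(xt^2)); norms[norms == 0] <- 1
  (xt / norms) %*% model$v
}

.rr_fit_mnb <- function(x, y, alpha = 1) {
  # multinomial naive Bayes on features shifted to be non-negative
  shift <- min(x, 0)
  xs <- x - shift
  classes <- sort(unique(y))
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  theta <- t(vapply(classes, function(cl) {
    s <- colSums(xs[y == cl, , drop = FALSE]) + alpha
    s / sum(s)
  }, numeric(ncol(x))))
  list(classes = classes, shift = shift, log_prior = log(prior),
       log_theta = log(theta))
}

.rr_predict_mnb <- function(fit, x) {
  xs <- x - fit$shift
  scores <- xs %*% t(fit$log_theta) +
    matrix(fit$log_prior, nrow(x), length(fit$classes), byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Train an understandability estimator
#'
#' The model zoo mirrors common practice: linear, multilayer-perceptron,
#' random-forest, support-vector and gradient-boosted-tree regressors, and
#' logistic, MLP, random-forest, SVM, multinomial naive Bayes and
#' gradient-boosted-tree classifiers, all with library-default
#' hyperparameters and a recorded seed. Regressors treat the class labels
#' `{1, 2, 3}` as ordinal reals; classifiers require all three classes in
#' the training data.
#'
#' @param x numeric feature matrix (typically latent vectors from
#'   [lsa_transform()]).
#' @param y numeric labels in `{1, 2, 3}` (regressors accept any reals).
#' @param kind one of the model kinds listed above.
#' @param seed integer seed; training is reproducible for a fixed seed.
#' @return object of class `understandability_model`.
#' @export
train_estimator <- function(x, y,
                            kind = c(.rr_regressors, .rr_classifiers),
                            seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.vector(y)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  is_reg <- kind %in% .rr_regressors
  if (!is_reg && length(unique(y)) < 2L)
    stop("classifiers require at least two classes in the training data")
  set.seed(seed)
  fit <- switch(kind,
    linear_regressor = lm(y ~ ., data = data.frame(y = y, x)),
    mlp_regressor = nnet::nnet(x, y, size = 8, linout = TRUE, maxit = 500,
                               trace = FALSE, decay = 1e-3),
    random_forest_regressor = suppressWarnings(randomForest::randomForest(x, y)),
    svm_regressor = e1071::svm(x, y),
    gbt_regressor = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 50, verbose = 0),
    logistic = nnet::multinom(y ~ ., data = data.frame(y = factor(y), x),
                              trace = FALSE),
    mlp_classifier = nnet::nnet(x, nnet::class.ind(factor(y)), size = 8,
                                softmax = TRUE, maxit = 500, trace = FALSE,
                                decay = 1e-3),
    random_forest_classifier = randomForest::randomForest(x, factor(y)),
    svm_classifier = e1071::svm(x, factor(y)),
    multinomial_nb = .rr_fit_mnb(x, y),
    gbt_classifier = xgboost::xgb.train(
      params = list(objective = "multi:softmax",
                    num_class = length(unique(y)), nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(factor(y)) - 1L,
                                  nthread = 1),
      nrounds = 50, verbose = 0)
  )
  structure(list(kind = kind, fit = fit, seed = seed, is_regressor = is_reg,
                 n_features = ncol(x),
                 levels = if (!is_reg) sort(unique(y)) else NULL),
            class = "understandability_model")
}

#' Predict understandability for new documents
#'
#' Regressors return a real difficulty score on the label scale (higher =
#' harder, since label 3 is the most formal corpus); classifiers return a
#' label in the training label set.
#'
#' @param model an `understandability_model`.
#' @param newx feature matrix, or (with `lsa`) raw documents to be projected
#'   first.
#' @param lsa optional `lsa_model` used to transform raw documents.
#' @return numeric vector of scores or labels.
#' @export
predict_understandability <- function(model, newx, lsa = NULL) {
  stopifnot(inherits(model, "understandability_model"))
  if (!is.null(lsa)) newx <- lsa_transform(lsa, newx)
  newx <- as.matrix(newx)
  colnames(newx) <- paste0("f", seq_len(ncol(newx)))
  if (ncol(newx) != model$n_features)
    stop("feature dimensionality mismatch")
  kind <- model$kind
  out <- switch(kind,
    linear_regressor = ,
    logistic = predict(model$fit, newdata = data.frame(newx),
                       type = if (kind == "logistic") "class" else "response"),
    mlp_regressor = predict(model$fit, newx)[, 1L],
    mlp_classifier = colnames(predict(model$fit, newx))[
      max.col(predict(model$fit, newx), ties.method = "first")],
    random_forest_regressor = ,
    random_forest_classifier = ,
    svm_regressor = ,
    svm_classifier = predict(model$fit, newx),
    multinomial_nb = .rr_predict_mnb(model$fit, newx),
    gbt_regressor = predict(model$fit, xgboost::xgb.DMatrix(newx, nthread = 1)),
    gbt_classifier = model$levels[
      predict(model$fit, xgboost::xgb.DMatrix(newx, nthread = 1)) + 1L]
  )
  as.numeric(as.character(out))
}

#' Cross-fitted predictions for assessed documents
#'
#' Splits the assessed documents into `folds` seeded folds; each document's
#' prediction comes from a model trained on the other folds, so no document
#' is scored by a model that saw its target. A final model trained on all
#' assessed data is returned for scoring unassessed documents.
#'
#' @param x feature matrix for the assessed documents.
#' @param y assessment targets.
#' @param folds number of folds (default 10); must not exceed `nrow(x)`.
#' @param seed integer seed controlling the fold assignment and model fits.
#' @param kind estimator kind (default the gradient-boosted regressor).
#' @return list with `predictions` (numeric, one per row of `x`), `fold`
#'   (assignments) and `final_model`.
#' @export
cross_fit_predictions <- function(x, y, folds = 10, seed = 1L,
                                  kind = "gbt_regressor") {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (folds > n) stop("more folds than documents")
  if (length(y) != n) stop("targets must match rows of x")
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  preds <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold == f
    m <- train_estimator(x[!hold, , drop = FALSE], y[!hold], kind = kind,
                         seed = seed + f)
    preds[hold] <- predict_understandability(m, x[hold, , drop = FALSE])
  }
  final <- train_estimator(x, y, kind = kind, seed = seed)
  list(predictions = preds, fold = fold, final_model = final)
}

#' Save / load an understandability model with a JSON sidecar
#'
#' The fitted state is serialized with R's native serialization; a JSON
#' sidecar (`<path>.json`) records kind, seed and feature dimensionality so
#' models can be audited without loading them.
#'
#' @param model an `understandability_model`.
#' @param path file path for the binary blob.
#' @return `load_estimator` returns the model; `save_estimator` returns
#'   `path` invisibly.
#' @export
save_estimator <- function(model, path) {
  stopifnot(inherits(model, "understandability_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(kind = model$kind, seed = model$seed,
         n_features = model$n_features, version = 1L),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "understandability_model"))
  m
}
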