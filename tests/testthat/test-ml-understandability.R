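# small labeled corpus shared across tests
ml_fixture <- local({
  corp <- gen_background_corpora(generator_config(seed = 21, docs_per_corpus = 20))
  lsa <- fit_lsa(corp$texts, dims = 10, seed = 1)
  list(corp = corp, lsa = lsa, z = lsa_transform(lsa, corp$texts))
})

test_that("latent models have ten finite dimensions and are deterministic", {
  z <- ml_fixture$z
  expect_equal(ncol(z), 10L)
  expect_true(all(is.finite(z)))
  # identical documents map to identical latent vectors
  d <- ml_fixture$corp$texts[1]
  zz <- lsa_transform(ml_fixture$lsa, c(d, d))
  expect_equal(zz[1, ], zz[2, ])
  # refitting gives the identical model (sign convention fixed)
  lsa2 <- fit_lsa(ml_fixture$corp$texts, dims = 10, seed = 1)
  expect_identical(ml_fixture$lsa$v, lsa2$v)
  expect_error(fit_lsa(ml_fixture$corp$texts[1:5], dims = 10), "at least")
})

test_that("ten dimensions reconstruct no worse than two", {
  corp <- ml_fixture$corp$texts[1:30]
  recon_err <- function(dims) {
    toks <- lapply(corp, function(t) tokenize_text(t)$words)
    lsa <- fit_lsa(toks, dims = dims, seed = 1)
    x <- readrank:::.rr_dtm(toks, lsa$vocab)
    xt <- sweep(x, 2, lsa$idf, `*`)
    n <- sqrt(rowSums(xt^2)); n[n == 0] <- 1
    xt <- xt / n
    sum((xt - (xt %*% lsa$v) %*% t(lsa$v))^2)
  }
  expect_lte(recon_err(10), recon_err(2) + 1e-9)
})

test_that("regressors fit constant targets and fixed seeds reproduce", {
  z <- ml_fixture$z[1:20, ]
  m <- train_estimator(z, rep(2, 20), "gbt_regressor", seed = 3)
  expect_true(all(abs(predict_understandability(m, z) - 2) < 1e-6))
  m1 <- train_estimator(ml_fixture$z, ml_fixture$corp$labels,
                        "gbt_regressor", seed = 7)
  m2 <- train_estimator(ml_fixture$z, ml_fixture$corp$labels,
                        "gbt_regressor", seed = 7)
  expect_identical(predict_understandability(m1, ml_fixture$z),
                   predict_understandability(m2, ml_fixture$z))
  expect_error(train_estimator(z, rep(1, 20), "gbt_classifier"),
               "at least two classes")
})

test_that("every model kind in the zoo trains and predicts on 3-class data", {
  z <- ml_fixture$z; y <- ml_fixture$corp$labels
  regs <- c("linear_regressor", "mlp_regressor", "random_forest_regressor",
            "svm_regressor", "gbt_regressor")
  for (k in regs) {
    m <- train_estimator(z, y, k, seed = 2)
    p <- predict_understandability(m, z)
    expect_true(all(is.finite(p)), info = k)
    # class-mean ordering on the training corpora
    mu <- tapply(p, y, mean)
    expect_true(mu[1] < mu[2] && mu[2] < mu[3], info = k)
  }
  cls <- c("logistic", "mlp_classifier", "random_forest_classifier",
           "svm_classifier", "multinomial_nb", "gbt_classifier")
  for (k in cls) {
    m <- train_estimator(z, y, k, seed = 2)
    p <- predict_understandability(m, z)
    expect_true(all(p %in% 1:3), info = k)
    expect_gte(mean(p == y), 0.8)
  }
})

test_that("forum-style and journal-style documents are classified apart", {
  cfg <- generator_config(seed = 31)
  corp <- gen_background_corpora(cfg)
  lsa <- fit_lsa(corp$texts, seed = 1)
  z <- lsa_transform(lsa, corp$texts)
  m <- train_estimator(z, corp$labels, "gbt_classifier", seed = 1)
  test_corp <- gen_background_corpora(generator_config(seed = 32, docs_per_corpus = 10))
  zt <- lsa_transform(lsa, test_corp$texts)
  p <- predict_understandability(m, zt)
  expect_gte(mean(p[test_corp$labels == 1] == 1), 0.6)
  expect_gte(mean(p[test_corp$labels == 3] == 3), 0.6)
})

test_that("cross-fitting keeps predictions out of fold", {
  # n = folds gives a leave-one-out partition
  z <- ml_fixture$z[1:10, ]; y <- ml_fixture$corp$labels[1:10]
  cf <- cross_fit_predictions(z, y, folds = 10, seed = 2)
  expect_equal(sort(unique(cf$fold)), 1:10)
  expect_equal(as.integer(table(cf$fold)), rep(1L, 10))
  expect_error(cross_fit_predictions(z, y, folds = 11), "more folds")
  # constant targets give constant predictions
  cf2 <- cross_fit_predictions(z, rep(2, 10), folds = 5, seed = 2)
  expect_true(all(abs(cf2$predictions - 2) < 1e-6))
  # noiseless linear function of one feature is recovered out of fold
  set.seed(5)
  x <- matrix(rnorm(300), ncol = 3)
  target <- 2 * x[, 1] + 1
  cf3 <- cross_fit_predictions(x, target, folds = 10, seed = 2,
                               kind = "linear_regressor")
  expect_lt(sqrt(mean((cf3$predictions - target)^2)), 1e-8)
})

test_that("permuting targets destroys cross-fitted accuracy", {
  z <- ml_fixture$z; y <- ml_fixture$corp$labels
  cf <- cross_fit_predictions(z, y, folds = 5, seed = 4)
  acc <- cor(cf$predictions, y)
  set.seed(99)
  yp <- sample(y)
  cfp <- cross_fit_predictions(z, yp, folds = 5, seed = 4)
  acc_perm <- cor(cfp$predictions, yp)
  expect_gt(acc, 0.8)
  expect_lt(acc_perm, 0.4)
})

test_that("models survive a save/load round trip with a JSON sidecar", {
  m <- train_estimator(ml_fixture$z, ml_fixture$corp$labels,
                       "random_forest_classifier", seed = 6)
  path <- tempfile(fileext = ".rds")
  save_estimator(m, path)
  m2 <- load_estimator(path)
  expect_identical(predict_understandability(m2, ml_fixture$z),
                   predict_understandability(m, ml_fixture$z))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$kind, "random_forest_classifier")
  expect_equal(side$n_features, 10L)
})
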