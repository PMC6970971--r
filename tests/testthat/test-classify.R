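# tf-idf features, classifier training/evaluation, learning curves,
# weak-supervision labels.

test_that("tf-idf follows the smoothed-idf + L2 row dialect", {
  # feature in every document: idf = ln((1+N)/(1+N)) + 1 = 1
  posts <- list(mk_post(c("alpha", "beta")), mk_post(c("alpha", "gamma")))
  f <- build_features(posts)
  expect_equal(f$spec$idf[f$spec$vocabulary == "alpha"], 1)

  # single document, single token: normalized row = [1]
  f1 <- build_features(list(mk_post("solo")))
  expect_equal(as.numeric(f1$x), 1)

  # hand-computed tf-idf on a 2-doc, 3-feature toy corpus
  posts2 <- list(mk_post(c("aa", "aa", "bb")), mk_post("cc"))
  f2 <- build_features(posts2)
  n <- 2
  idf <- function(df) log((1 + n) / (1 + df)) + 1
  raw1 <- c(aa = 2 * idf(1), bb = 1 * idf(1), cc = 0)
  exp1 <- raw1 / sqrt(sum(raw1^2))
  got1 <- as.numeric(f2$x[1, c("aa", "bb", "cc")])
  expect_equal(got1, unname(exp1))
  # disjoint support rows
  expect_equal(as.numeric(f2$x[2, c("aa", "bb")]), c(0, 0))
  expect_equal(as.numeric(f2$x[2, "cc"]), 1)
})

test_that("matched phrases become single features consuming their unigrams", {
  inv <- phrase_inventory("sweet potato")
  f <- build_features(list(mk_post(c("sweet", "potatoes", "tonight"))), inv)
  expect_true("sweet potato" %in% f$spec$vocabulary)
  expect_false(any(c("sweet", "potato") %in% f$spec$vocabulary))
  expect_true("tonight" %in% f$spec$vocabulary)
})

test_that("an empty corpus is a schema error", {
  err <- tryCatch(build_features(list()), error = identity)
  expect_s3_class(err, "caloscope_schema_error")
})

separable_fixture <- function(n = 300, seed = 5) {
  set.seed(seed)
  lab <- rep(c("food", "non-food"), length.out = n)
  vocab_f <- c("pizza", "coffee", "cakey", "sushi")
  vocab_n <- c("meeting", "traffic", "podcast", "budget")
  posts <- lapply(seq_len(n), function(i) {
    pool <- if (lab[i] == "food") vocab_f else vocab_n
    mk_post(sample(pool, 4, replace = TRUE), id = as.character(i))
  })
  list(posts = posts, y = factor(lab, levels = c("food", "non-food")))
}

test_that("every classifier kind fits separable data and is seed-deterministic", {
  fx <- separable_fixture()
  f <- build_features(fx$posts)
  for (kind in c("nb", "lr", "rf", "svm")) {
    m <- food_classifier(kind, f$x, fx$y, seed = 11)
    acc <- mean(predict(m, f$x) == fx$y)
    expect_gte(acc, 0.99)
    m2 <- food_classifier(kind, f$x, fx$y, seed = 11)
    expect_identical(predict(m, f$x), predict(m2, f$x), label = kind)
  }
})

test_that("single-class labels are a training error", {
  f <- build_features(list(mk_post("pizza"), mk_post("pasta")))
  err <- tryCatch(
    food_classifier("lr", f$x, factor(c("food", "food"),
                                      levels = c("food", "non-food"))),
    error = identity)
  expect_s3_class(err, "caloscope_schema_error")
})

test_that("evaluation reports conserve counts and compute the FPR", {
  y <- factor(rep(c("food", "non-food"), each = 10),
              levels = c("food", "non-food"))
  r <- eval_report(y, y)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$false_positive_rate), 0)
  expect_equal(sum(r$confusion), 20)

  all_food <- factor(rep("food", 20), levels = c("food", "non-food"))
  r2 <- eval_report(y, all_food)
  expect_equal(r2$accuracy, 0.5)
  expect_equal(unname(r2$false_positive_rate), 1)

  # 3 of 20 true non-food predicted food
  truth <- factor(rep(c("food", "non-food"), each = 20),
                  levels = c("food", "non-food"))
  pred <- truth
  pred[21:23] <- "food"
  r3 <- eval_report(truth, pred)
  expect_equal(unname(r3$false_positive_rate), 0.15)
  expect_equal(unname(rowSums(r3$row_normalized)), c(1, 1))

  err <- tryCatch(eval_report(factor(character(0)), factor(character(0))),
                  error = identity)
  expect_s3_class(err, "caloscope_schema_error")
  err2 <- tryCatch(eval_report(rep("food", 4), rep("food", 4)),
                   error = identity)
  expect_s3_class(err2, "caloscope_schema_error")
})

test_that("learning curves validate sizes and return one point per size", {
  fx <- separable_fixture(200)
  f <- build_features(fx$posts)
  lc <- learning_curve("lr", f$x, fx$y, sizes = 40, seeds = 1:2)
  expect_equal(nrow(lc), 1)

  err <- tryCatch(learning_curve("lr", f$x, fx$y, sizes = c(50, 40)),
                  error = identity)
  expect_s3_class(err, "caloscope_schema_error")
  err2 <- tryCatch(learning_curve("lr", f$x, fx$y, sizes = c(40, 10000)),
                   error = identity)
  expect_s3_class(err2, "caloscope_schema_error")
})

test_that("weak labels fire on unmasked lexicon hits only", {
  lex <- tiny_food_lexicon()
  posts <- list(mk_post(c("pizza", "tonight"), id = "a"),
                mk_post(c("piece", "cake"), id = "b"),
                mk_post(character(0), id = "c"))
  masks <- list(c(FALSE, FALSE), c(TRUE, TRUE), logical(0))
  y <- weak_labels(posts, lex, masks)
  expect_equal(as.character(y), c("food", "non-food", "non-food"))
})
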