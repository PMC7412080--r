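# Tiny separable feature tables built directly, bypassing the signal stage.
toy_features <- function(n_per_class = 20, classes = c("a", "b"),
                         sep = 10, seed = 1, subjects = NULL) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    data.frame(subject_id = if (is.null(subjects)) "s1" else
                 sample(subjects, n_per_class, replace = TRUE),
               window_start = seq_len(n_per_class),
               label = classes[k], n_valid = 10L,
               f1 = rnorm(n_per_class, mean = sep * k),
               f2 = rnorm(n_per_class))
  })
  structure(do.call(rbind, rows), feature_cols = c("f1", "f2"),
            class = c("har_features", "data.frame"))
}

test_that("both classifier kinds separate well-separated clusters", {
  tr <- toy_features(seed = 1)
  te <- toy_features(seed = 2)
  for (cls in c("random_forest", "svm_rbf")) {
    m <- har_fit(tr, classifier = cls, n_trees = 100)
    expect_equal(evaluate_model(m, te)$accuracy, 1.0)
  }
})

test_that("fits are deterministic given a seed and refuse one class", {
  tr <- toy_features(seed = 3)
  te <- toy_features(seed = 4)
  m1 <- har_fit(tr, n_trees = 100, seed = 7)
  m2 <- har_fit(tr, n_trees = 100, seed = 7)
  expect_identical(predict(m1, te), predict(m2, te))
  expect_error(har_fit(tr[tr$label == "a", ]), "two classes")
})

test_that("label-permuted balanced training scores at chance", {
  accs <- vapply(1:50, function(i) {
    tr <- toy_features(n_per_class = 20, classes = c("a", "b", "c"),
                       sep = 10, seed = i)
    set.seed(i + 500)
    tr$label <- sample(tr$label)           # break the feature-label link
    te <- toy_features(n_per_class = 20, classes = c("a", "b", "c"),
                       sep = 10, seed = i + 1000)
    evaluate_model(har_fit(tr, n_trees = 100, seed = i), te)$accuracy
  }, 1)
  expect_equal(mean(accs), 1 / 3, tolerance = 0.05 / (1 / 3))
})

test_that("evaluation identities hold", {
  tr <- toy_features(seed = 5)
  te <- toy_features(seed = 6)
  m <- har_fit(tr, n_trees = 100)
  ev <- evaluate_model(m, te)
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
  expect_equal(rowSums(ev$confusion),
               c(a = 20, b = 20))  # row sums = per-class test counts

  # all-wrong predictions score 0
  te_flip <- te
  te_flip$label <- ifelse(te$label == "a", "b", "a")
  expect_equal(evaluate_model(m, te_flip)$accuracy,
               1 - ev$accuracy)
})

test_that("accuracy is invariant to feature-row order", {
  tr <- toy_features(seed = 8)
  te <- toy_features(seed = 9)
  m <- har_fit(tr, n_trees = 100, seed = 2)
  shuffled <- te[sample(nrow(te)), ]
  expect_equal(evaluate_model(m, shuffled)$accuracy,
               evaluate_model(m, te)$accuracy)
})

test_that("schema mismatches are rejected", {
  m <- har_fit(toy_features(seed = 1), n_trees = 50)
  bad <- toy_features(seed = 2)
  names(bad)[names(bad) == "f2"] <- "g2"
  attr(bad, "feature_cols") <- c("f1", "g2")
  expect_error(predict(m, bad), "schema")
})

test_that("leave-one-person-out folds partition the subjects", {
  ft <- toy_features(n_per_class = 50, subjects = paste0("p", 1:5), seed = 10)
  folds <- lopo_splits(ft)
  expect_length(folds, 5L)
  test_ids <- vapply(folds, `[[`, "", "test_id")
  expect_setequal(test_ids, paste0("p", 1:5))
  for (f in folds)
    expect_false(f$test_id %in% f$train_ids)
})
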