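# A scaled-down synthetic dataset keeps the scenario tests quick while
# preserving the three-class structure.
small_data <- function(train_seed = 1, test_seed = 2) {
  build_simulated_dataset(n_per_class = 200, train_seed = train_seed,
                          test_seed = test_seed)
}

test_that("clean pipeline recognizes the three waveforms perfectly", {
  d <- small_data()
  for (cls in c("random_forest", "svm_rbf")) {
    r <- run_scenario(d$train, d$test, "clean_clean", config = window_config(1, 0.25),
                      classifier = cls, n_trees = 200, seed = 1)
    expect_equal(r$accuracy, 1.0)
  }
})

test_that("zero missing rate makes the three protocols coincide", {
  d <- small_data()
  cfg <- window_config(1, 0.5)
  accs <- vapply(c("clean_clean", "clean_missing", "missing_missing"),
                 function(case)
                   run_scenario(d$train, d$test, case, missing_rate = 0,
                                config = cfg, n_trees = 100, seed = 9)$accuracy,
                 1)
  expect_true(all(accs == accs[1]))
})

test_that("scenario runs are reproducible and masks are independent", {
  d <- small_data()
  r1 <- run_scenario(d$train, d$test, "missing_missing", 0.3,
                     config = window_config(1, 0.5), n_trees = 100, seed = 4)
  r2 <- run_scenario(d$train, d$test, "missing_missing", 0.3,
                     config = window_config(1, 0.5), n_trees = 100, seed = 4)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)

  r3 <- run_scenario(d$train, d$test, "missing_missing", 0.3,
                     config = window_config(1, 0.5), n_trees = 100, seed = 5)
  expect_s3_class(r3, "scenario_result")  # different seed still runs
})

test_that("train-rate override decouples the two corruption levels", {
  d <- small_data()
  r <- run_scenario(d$train, d$test, "missing_missing", missing_rate = 0.4,
                    train_missing_rate = 0.1, config = window_config(1, 0.5),
                    n_trees = 100, seed = 2)
  expect_equal(r$train_missing_rate, 0.1)
  expect_equal(r$missing_rate, 0.4)
})

test_that("sweep executes the full factor product and is repeatable", {
  d <- small_data()
  sw <- sweep_scenarios(d$train, d$test, missing_rates = c(0.1, 0.3),
                        window_sizes = c(1, 2), classifiers = "random_forest",
                        cases = c("clean_missing", "missing_missing"),
                        seeds = 1L, n_trees = 50)
  expect_equal(nrow(sw), 8L)
  expect_true(all(!is.na(sw$accuracy)))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))

  sw2 <- sweep_scenarios(d$train, d$test, missing_rates = c(0.1, 0.3),
                         window_sizes = c(1, 2), classifiers = "random_forest",
                         cases = c("clean_missing", "missing_missing"),
                         seeds = 1L, n_trees = 50)
  expect_equal(sw, sw2)
})

test_that("a failing sweep cell is recorded, not fatal", {
  d <- small_data()
  single <- lapply(d$train["sine"], identity)  # one class only -> fit error
  sw <- sweep_scenarios(single, d$test, missing_rates = 0.1,
                        cases = "clean_missing", seeds = 1L, n_trees = 50)
  expect_equal(nrow(sw), 1L)
  expect_true(is.na(sw$accuracy))
  expect_match(sw$error, "two classes")
})

test_that("headline comparison returns a coherent summary", {
  h <- headline_comparison(rates = c(0, 0.4), n_seeds = 2, n_per_class = 200,
                           seed = 3)
  expect_s3_class(h, "har_headline")
  expect_equal(nrow(h$summary), 2L)
  # at rate zero the two protocols are identical by construction
  expect_equal(h$summary$gap[h$summary$missing_rate == 0], 0)
  # the reported pair is the argmax of the gap, so proposed >= traditional
  expect_gte(h$proposed_acc, h$traditional_acc)
  expect_equal(nrow(h$table), 2L * 2L * 2L)
})
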