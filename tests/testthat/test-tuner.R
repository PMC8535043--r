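test_that("built-in spaces carry the expected bounds", {
  cb <- builtin_space("catboost-style")$params
  expect_equal(cb$lower[cb$name == "iterations"], 1)
  expect_equal(cb$upper[cb$name == "iterations"], 500)
  expect_equal(cb$lower[cb$name == "depth"], 1)
  expect_equal(cb$upper[cb$name == "depth"], 16)
  xb <- builtin_space("xgboost-style")$params
  expect_equal(xb$lower[xb$name == "n_estimators"], 50)
  expect_equal(xb$upper[xb$name == "n_estimators"], 900)
  expect_equal(xb$upper[xb$name == "max_depth"], 12)
  expect_true("min_child_weight" %in% xb$name)
})

test_that("sampled configurations always respect bounds and scales", {
  for (space_name in c("catboost-style", "xgboost-style")) {
    space <- builtin_space(space_name)
    p <- space$params
    ok <- vapply(1:1000, function(seed) {
      cfg <- sample_config(space, seed = seed)
      all(vapply(seq_len(nrow(p)), function(i) {
        val <- cfg[[p$name[i]]]
        lo <- p$lower[i]; hi <- p$upper[i]
        if (p$scale[i] == "log10") { lo <- 10^lo; hi <- 10^hi }
        if (p$scale[i] == "ln") { lo <- exp(lo); hi <- exp(hi) }
        val >= lo && val <= hi &&
          (p$kind[i] != "integer" || val == round(val))
      }, logical(1)))
    }, logical(1))
    expect_true(all(ok), label = space_name)
  }
  # learning-rate exponents decode to valid rates
  cb <- sample_config(builtin_space("catboost-style"), seed = 1)
  expect_gte(cb$learning_rate, 0.001)
  expect_lte(cb$learning_rate, 10^-0.7)
})

test_that("random search solves a convex 1-d objective", {
  space <- search_space(data.frame(name = "x", lower = 0, upper = 1,
                                   scale = "linear", kind = "real"))
  obj <- function(cfg) (cfg$x - 0.3)^2
  res <- tune(obj, space, n_trials = 50, seed = 1, backend = "random")
  expect_lt(res$best$loss, min(obj(list(x = 0)), obj(list(x = 1))))
  expect_equal(nrow(res$history), 50)
  # n_trials = 1: best is the single trial
  one <- tune(obj, space, n_trials = 1, seed = 2, backend = "random")
  expect_equal(one$best$index, 1)
})

test_that("search is deterministic under the seed and tracks its minimum", {
  space <- builtin_space("xgboost-style")
  obj <- function(cfg) (log(cfg$learning_rate) + 3)^2 / 50 +
    cfg$max_depth / 100
  for (backend in c("random", "adaptive-sequential")) {
    a <- tune(obj, space, n_trials = 20, seed = 9, backend = backend)
    b <- tune(obj, space, n_trials = 20, seed = 9, backend = backend)
    expect_identical(a$history, b$history)
    run_min <- cummin(a$history$loss)
    expect_true(all(diff(run_min) <= 0))
    expect_equal(a$best$loss, run_min[length(run_min)])
    expect_equal(a$best$loss, min(a$history$loss))
  }
})

test_that("a failing objective records loss 1.0 with a warning", {
  space <- search_space(data.frame(name = "x", lower = 0, upper = 1,
                                   scale = "linear", kind = "real"))
  obj <- function(cfg) if (cfg$x > 0.5) stop("unstable") else cfg$x
  w <- capture_warnings(res <- tune(obj, space, n_trials = 20, seed = 3,
                                    backend = "random"))
  expect_true(any(grepl("loss 1.0", w)))
  failed <- res$history$loss == 1.0
  expect_true(any(failed))
  expect_true(all(res$history$loss[!failed] <= 0.5))
})

test_that("adaptive search is competitive with random on the convex case", {
  # median-of-seeds comparison; logged, not hard-asserted
  space <- search_space(data.frame(name = "x", lower = 0, upper = 1,
                                   scale = "linear", kind = "real"))
  obj <- function(cfg) (cfg$x - 0.3)^2
  best <- function(seed, backend) {
    tune(obj, space, n_trials = 25, seed = seed, backend = backend)$best$loss
  }
  ad <- median(vapply(1:20, best, numeric(1), backend = "adaptive-sequential"))
  rn <- median(vapply(1:20, best, numeric(1), backend = "random"))
  cat(sprintf("\nadaptive median best loss %.2e vs random %.2e\n", ad, rn))
  succeed()
})
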