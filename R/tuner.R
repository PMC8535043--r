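# Seed-deterministic hyperparameter search over bounded spaces.

#' Define a hyperparameter search space
#'
#' @param params data.frame with columns `name`, `lower`, `upper`,
#'   `scale` (`"linear"`, `"log10"`, `"ln"`; for log scales the bounds are
#'   exponents and the sampled value is `10^u` resp. `exp(u)`) and `kind`
#'   (`"integer"` or `"real"`).
#' @return object of class `search_space`.
#' @export
search_space <- function(params) {
  needed <- c("name", "lower", "upper", "scale", "kind")
  if (!all(needed %in% names(params)))
    stopf("search space needs columns: %s", paste(needed, collapse = ", "))
  if (any(params$lower >= params$upper))
    stopf("every lower bound must be below its upper bound")
  if (!all(params$scale %in% c("linear", "log10", "ln")))
    stopf("scale must be linear, log10 or ln")
  if (!all(params$kind %in% c("integer", "real")))
    stopf("kind must be integer or real")
  bad <- params$kind == "integer" & params$scale == "linear" &
    (params$lower != floor(params$lower) | params$upper != floor(params$upper))
  if (any(bad))
    stopf("integer parameters need integer bounds: %s",
          paste(params$name[bad], collapse = ", "))
  structure(list(params = params), class = "search_space")
}

#' Built-in search spaces for the two boosted-tree vocabularies
#'
#' Returns the bounded space native to each classifier's parameter
#' vocabulary. Learning-rate bounds are exponents: base-10 for the
#' catboost-style space (\[-3, -0.7\] -> rates 0.001..0.2) and natural-log
#' for the xgboost-style space (\[ln 0.001, ln 0.3\]).
#'
#' @param classifier `"catboost-style"` or `"xgboost-style"`.
#' @return [search_space()].
#' @export
builtin_space <- function(classifier = c("catboost-style", "xgboost-style")) {
  classifier <- match.arg(classifier)
  df <- if (classifier == "catboost-style") {
    data.frame(
      name = c("iterations", "depth", "subsample", "rsm", "learning_rate",
               "l2_leaf_reg", "random_strength", "bagging_temperature",
               "scale_pos_weight"),
      lower = c(1, 1, 0.5, 0.75, -3.0, 1, 1e-9, 0.0, 0.01),
      upper = c(500, 16, 1, 1.0, -0.7, 10, 10, 1.0, 1.0),
      scale = c("linear", "linear", "linear", "linear", "log10", "linear",
                "linear", "linear", "linear"),
      kind = c("integer", "integer", "real", "real", "real", "real", "real",
               "real", "real"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("n_estimators", "max_depth", "min_child_weight", "gamma",
               "subsample", "learning_rate", "colsample_bytree"),
      lower = c(50, 1, 1, 0.5, 0.5, log(0.001), 0.5),
      upper = c(900, 12, 6, 1, 1, log(0.3), 1),
      scale = c("linear", "linear", "linear", "linear", "linear", "ln",
                "linear"),
      kind = c("integer", "integer", "integer", "real", "real", "real",
               "real"),
      stringsAsFactors = FALSE)
  }
  search_space(df)
}

# map a unit-cube point to a named config respecting scales and kinds
decode_unit <- function(u, space) {
  p <- space$params
  vals <- p$lower + u * (p$upper - p$lower)
  vals <- ifelse(p$scale == "log10", 10^vals,
                 ifelse(p$scale == "ln", exp(vals), vals))
  int <- p$kind == "integer"
  vals[int] <- pmin(pmax(round(vals[int]), p$lower[int]), p$upper[int])
  stats::setNames(as.list(vals), p$name)
}

#' Sample one configuration uniformly from a space
#'
#' @param space [search_space()].
#' @param seed integer seed.
#' @return named list of parameter values within bounds.
#' @export
sample_config <- function(space, seed = 0) {
  u <- with_seed(seed, stats::runif(nrow(space$params)))
  decode_unit(u, space)
}

#' Sequential hyperparameter search
#'
#' Minimises `objective(config)` over the space with a fixed trial budget.
#' Backends: `"random"` draws every trial uniformly; `"adaptive-sequential"`
#' spends a third of the budget on uniform warm-up draws, then alternates
#' exploitation (Gaussian perturbations of the incumbent best in unit-cube
#' coordinates, with shrinking width) with occasional uniform exploration.
#' Both are exactly reproducible under `seed`. A trial whose objective
#' throws is recorded with loss 1.0 and a warning.
#'
#' @param objective function(named list) -> loss in \[0, 1\]
#'   (conventionally 1 - mean CV accuracy).
#' @param space [search_space()].
#' @param n_trials number of evaluations.
#' @param seed integer seed.
#' @param backend `"adaptive-sequential"` (default) or `"random"`.
#' @return list with `best` (trial of minimum loss; first on ties) and
#'   `history` (data.frame of index, loss and parameter columns).
#' @export
tune <- function(objective, space, n_trials = 30, seed = 0,
                 backend = c("adaptive-sequential", "random")) {
  backend <- match.arg(backend)
  if (n_trials < 1) stopf("n_trials must be >= 1")
  d <- nrow(space$params)
  losses <- numeric(n_trials)
  units <- matrix(NA_real_, n_trials, d)
  configs <- vector("list", n_trials)
  with_seed(seed, {
    warmup <- if (backend == "random") n_trials else
      min(n_trials, max(3, ceiling(n_trials / 3)))
    best_i <- NA_integer_
    for (i in seq_len(n_trials)) {
      if (i <= warmup || stats::runif(1) < 0.2) {
        u <- stats::runif(d)
      } else {
        width <- 0.2 * 0.97^(i - warmup)
        u <- units[best_i, ] + stats::rnorm(d, sd = width)
        u <- pmin(pmax(u, 0), 1)
      }
      cfg <- decode_unit(u, space)
      loss <- tryCatch(objective(cfg), error = function(e) {
        warning(sprintf("trial %d failed (%s); recorded with loss 1.0",
                        i, conditionMessage(e)), call. = FALSE)
        1.0
      })
      units[i, ] <- u
      losses[i] <- loss
      configs[[i]] <- cfg
      if (is.na(best_i) || loss < losses[best_i]) best_i <- i
    }
  })
  history <- cbind(data.frame(index = seq_len(n_trials), loss = losses),
                   do.call(rbind, lapply(configs, as.data.frame)))
  best_i <- which.min(losses)
  list(best = list(config = configs[[best_i]], loss = losses[best_i],
                   index = best_i),
       history = history)
}

#' Build a cross-validated accuracy objective for [tune()]
#'
#' @param matrix ExpressionMatrix (typically restricted to selected genes).
#' @param k folds for the inner CV.
#' @param classifier vocabulary passed to [cross_validate()].
#' @param seed inner fold/classifier seed, fixed across trials.
#' @return function(config) -> 1 - mean CV accuracy.
#' @export
make_cv_objective <- function(matrix, k = 8,
                              classifier = "catboost-style", seed = 0) {
  folds <- make_folds(matrix$labels, k, seed = seed)
  function(config) {
    ms <- cross_validate(matrix, genes = NULL, folds = folds,
                         classifier = classifier, params = config,
                         seed = seed)
    1 - ms$summary["accuracy", "mean"]
  }
}
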