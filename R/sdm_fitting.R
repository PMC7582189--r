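#' Sample background (pseudo-absence) points
#'
#' Presence-only learners contrast occurrences with a random sample of the
#' available environment.  Cells are drawn uniformly over the non-nodata
#' extent, without replacement when `n` does not exceed the number of valid
#' cells (with replacement and a warning otherwise); each point sits at its
#' cell centre.
#'
#' @param stack an [env_stack()].
#' @param n number of background points; the default follows the common
#'   choice of 10,000.
#' @param seed integer seed.
#' @return object of class `background_sample`: list with `points` (n x 2
#'   matrix), `n`, `seed`.
#' @export
sample_background <- function(stack, n = 10000, seed) {
  stopifnot(n >= 1)
  ok <- valid_cells(stack)
  if (length(ok) == 0L) stop("stack is fully masked; no valid extent")
  set.seed(seed)
  if (n <= length(ok)) {
    cells <- ok[sample.int(length(ok), n)]
  } else {
    warning("n exceeds the number of valid cells; sampling with replacement")
    cells <- ok[sample.int(length(ok), n, replace = TRUE)]
  }
  structure(list(points = cell_centers(stack, cells), n = n, seed = seed),
            class = "background_sample")
}

#' Random train/test split of presences and background
#'
#' Presences and background points are split independently at the same
#' fraction (stratified), the standard calibration/evaluation protocol:
#' models are trained on the training fraction and scored on the held-out
#' remainder.
#'
#' @param n_presence,n_background group sizes; at least 5 presences are
#'   required for a meaningful held-out evaluation.
#' @param fraction training fraction in (0, 1); default 0.8 (an 80/20 split).
#' @param seed integer seed.
#' @return object of class `train_test_split` with index vectors
#'   `train_presence`, `test_presence`, `train_background`,
#'   `test_background`, and `fraction`.
#' @export
split_train_test <- function(n_presence, n_background, fraction = 0.8, seed) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  if (n_presence < 5)
    stop("need at least 5 presences to hold out a test fraction; ",
         "collect more records or skip evaluation")
  set.seed(seed)
  tp <- sort(sample.int(n_presence, round(fraction * n_presence)))
  tb <- sort(sample.int(n_background, round(fraction * n_background)))
  structure(list(train_presence = tp,
                 test_presence = setdiff(seq_len(n_presence), tp),
                 train_background = tb,
                 test_background = setdiff(seq_len(n_background), tb),
                 fraction = fraction),
            class = "train_test_split")
}

#' Default hyperparameters of the five base learners
#'
#' @return named list of per-method hyperparameter lists.
#' @export
default_hyperparams <- function() {
  list(GLM = list(),
       GAM = list(k = 5),                       # 4-df spline per term
       GBM = list(n_trees = 2000, learning_rate = 0.01, max_depth = 3),
       RF = list(n_trees = 500),
       MAXENT = list(n_hinge_knots = 5, nfolds = 5))
}

#' Fit one presence/background suitability learner
#'
#' Five model classes share one contract: given presence rows and background
#' rows of the same predictor matrix, return a model whose prediction on any
#' feature row is a suitability score in `[0, 1]`, deterministic given the
#' seed.
#'
#' * `GLM` — logistic regression with linear plus quadratic terms.
#' * `GAM` — spline-based logistic additive model ([mgcv::gam()], thin-plate
#'   smooths with `k` basis functions per term).
#' * `GBM` — gradient-boosted trees ([xgboost::xgb.train()], logistic loss).
#' * `RF` — random forest probability votes ([randomForest::randomForest()]).
#' * `MAXENT` — maximum-entropy-style model realized as its penalized
#'   logistic equivalent on background-weighted data: lasso-penalized
#'   logistic regression ([glmnet::cv.glmnet()]) on linear, quadratic and
#'   hinge features, penalty chosen by internal cross-validation.
#'
#' For `GLM`, `GAM` and `MAXENT` the background rows are down-weighted so
#' their total weight equals the total presence weight; this keeps the fitted
#' intercept from being dominated by the presence/background prevalence.
#'
#' @param method one of `"GLM"`, `"GAM"`, `"GBM"`, `"RF"`, `"MAXENT"`.
#' @param presence_matrix,background_matrix numeric matrices with identical
#'   named columns (see [extract_at_points()]).
#' @param hyperparams named list overriding entries of
#'   [default_hyperparams()] for `method`.
#' @param seed integer seed controlling every stochastic element of the fit.
#' @return object of class `fitted_sdm` with `method`, `feature_names`,
#'   `fit` (the underlying model object), and `training_meta`.
#' @export
fit_sdm <- function(method, presence_matrix, background_matrix,
                    hyperparams = list(), seed = 1) {
  method <- match.arg(method, c("GLM", "GAM", "GBM", "RF", "MAXENT"))
  if (!identical(colnames(presence_matrix), colnames(background_matrix)))
    stop("presence and background matrices must share identical columns")
  np <- nrow(presence_matrix); nb <- nrow(background_matrix)
  if (np < 1L || nb < 1L) stop("need at least one presence and one background row")
  X <- rbind(presence_matrix, background_matrix)
  y <- c(rep(1, np), rep(0, nb))
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant predictors left")
  vars <- colnames(X)
  hp <- utils::modifyList(default_hyperparams()[[method]], hyperparams)
  w <- c(rep(1, np), rep(np / nb, nb))
  set.seed(seed)

  fit <- switch(method,
    GLM = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      fml <- stats::as.formula(paste(
        ".y ~", paste(sprintf("`%s` + I(`%s`^2)", vars, vars), collapse = " + ")))
      suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df,
                                  weights = w))
    },
    GAM = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      fml <- stats::as.formula(paste(
        ".y ~", paste(sprintf("s(`%s`, k = %d)", vars, hp$k), collapse = " + ")))
      suppressWarnings(mgcv::gam(fml, family = stats::binomial(), data = df,
                                 weights = w, method = "REML"))
    },
    GBM = {
      d <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$learning_rate,
                      max_depth = hp$max_depth, nthread = 1,
                      seed = seed %% .Machine$integer.max),
        data = d, nrounds = hp$n_trees, verbose = 0)
    },
    RF = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = hp$n_trees),
    MAXENT = {
      knots <- apply(X, 2L, stats::quantile,
                     probs = seq_len(hp$n_hinge_knots) / (hp$n_hinge_knots + 1),
                     names = FALSE)
      FX <- maxent_features(X, knots)
      cv <- glmnet::cv.glmnet(FX, y, family = "binomial", weights = w,
                              nfolds = hp$nfolds, alpha = 1)
      list(cv = cv, knots = knots)
    })

  structure(list(method = method, feature_names = vars, fit = fit,
                 training_meta = list(n_presence = np, n_background = nb,
                                      seed = seed, hyperparams = hp)),
            class = "fitted_sdm")
}

# Linear + quadratic + hinge basis expansion for the MaxEnt-style learner.
maxent_features <- function(X, knots) {
  parts <- list(X, X^2)
  for (j in seq_len(ncol(X))) {
    h <- pmax(outer(X[, j], knots[, j], `-`), 0)
    colnames(h) <- sprintf("%s_h%d", colnames(X)[j], seq_len(ncol(h)))
    parts[[length(parts) + 1L]] <- h
  }
  colnames(parts[[2L]]) <- paste0(colnames(X), "_sq")
  do.call(cbind, parts)
}

#' Predict suitability scores from a fitted learner
#'
#' @param object a [fit_sdm()] result.
#' @param newdata numeric matrix containing (at least) the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of suitability scores in `[0, 1]`.
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss))
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "))
  X <- newdata[, object$feature_names, drop = FALSE]
  p <- switch(object$method,
    GLM = ,
    GAM = as.numeric(stats::predict(object$fit,
                                    newdata = as.data.frame(X),
                                    type = "response")),
    GBM = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(X))),
    RF = as.numeric(stats::predict(object$fit, X, type = "prob")[, "1"]),
    MAXENT = as.numeric(stats::predict(object$fit$cv,
                                       maxent_features(X, object$fit$knots),
                                       s = "lambda.min", type = "response")))
  pmin(pmax(p, 0), 1)
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("fitted_sdm [%s]: %d presences vs %d background, features: %s\n",
              x$method, x$training_meta$n_presence, x$training_meta$n_background,
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Predict a suitability surface over a stack
#'
#' Cellwise model prediction on every valid cell of the stack; nodata cells
#' propagate.  The surface at any cell equals the pointwise prediction on the
#' predictor values extracted at that cell.
#'
#' @param model a [fit_sdm()] result (or any object with a `predict` method
#'   over a feature matrix and a `feature_names` element).
#' @param stack an [env_stack()] holding all of the model's features.
#' @param species_id text label stored on the surface.
#' @return object of class `suitability_surface`: list with `grid` (matrix in
#'   `[0, 1]`, `NA` on nodata), `mask`, `transform`, `species_id`, `method`.
#' @export
predict_surface <- function(model, stack, species_id = "sp") {
  miss <- setdiff(model$feature_names, layer_names(stack))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  m <- extract_all_cells(stack)
  p <- predict(model, m)
  d <- dim(stack)
  g <- matrix(NA_real_, d[1L], d[2L])
  g[attr(m, "cells")] <- p
  suitability_surface(g, stack, species_id = species_id, method = model$method)
}

#' Construct a suitability surface object
#'
#' @param grid numeric matrix in `[0, 1]` (`NA` = nodata).
#' @param stack the [env_stack()] supplying geometry and mask.
#' @param species_id,method text labels (`method` may be `"ensemble"`).
#' @return object of class `suitability_surface`.
#' @export
suitability_surface <- function(grid, stack, species_id = "sp",
                                method = "ensemble") {
  stopifnot(identical(dim(grid), dim(stack)))
  grid[stack$mask] <- NA_real_
  structure(list(grid = grid, mask = stack$mask,
                 transform = stack$transform,
                 species_id = species_id, method = method),
            class = "suitability_surface")
}
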