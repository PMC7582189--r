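#' Area under the ROC curve (Mann–Whitney form)
#'
#' The probability that a randomly chosen presence score exceeds a randomly
#' chosen background score, with ties counted one half.  0.5 means the model
#' ranks no better than random; 1 means perfect discrimination.
#'
#' @param presence_scores,background_scores non-empty numeric vectors of
#'   model scores.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.7), c(0.8, 0.1))  # 3 of 4 pairs concordant -> 0.75
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic at a threshold
#'
#' `TSS = sensitivity + specificity - 1`, where presences scoring at or above
#' the threshold are true positives and background points scoring below it
#' are true negatives.  TSS ranges from -1 to +1; +1 is perfect, 0 is random.
#'
#' @inheritParams auc
#' @param threshold finite cut-off; presences are scored with the closed rule
#'   `score >= threshold`.
#' @return TSS in `[-1, 1]`.
#' @export
tss_at_threshold <- function(presence_scores, background_scores, threshold) {
  stopifnot(is.finite(threshold))
  mean(presence_scores >= threshold) + mean(background_scores < threshold) - 1
}

#' Threshold maximizing sensitivity plus specificity (maxSSS)
#'
#' Scans the midpoints between consecutive distinct observed scores and
#' returns the threshold with the largest TSS; ties break toward the lowest
#' threshold.  This is the usual rule for binarizing a continuous suitability
#' surface into suitable/unsuitable.
#'
#' @inheritParams auc
#' @return list with `threshold` and `tss_max`.
#' @export
max_sss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("score vectors must be non-empty")
  s <- sort(unique(c(presence_scores, background_scores)))
  if (length(s) == 1L)
    return(list(threshold = s, tss_max = 0))
  cand <- (s[-1L] + s[-length(s)]) / 2
  tss <- vapply(cand, tss_at_threshold,
                presence_scores = presence_scores,
                background_scores = background_scores, numeric(1L))
  best <- which.max(tss)  # which.max takes the first (= lowest) on ties
  list(threshold = cand[best], tss_max = tss[best])
}

#' Continuous Boyce index
#'
#' A presence-only calibration metric: windows of width
#' `window_width_fraction` of the landscape score range are slid across that
#' range at `n_windows` evenly spaced positions; each window's
#' predicted-to-expected ratio `F = (share of presence scores inside) /
#' (share of landscape scores inside)` is computed, windows with zero
#' landscape share are dropped, and the index is the Spearman rank
#' correlation between `F` and the window midpoint.  +1 means presence
#' density increases monotonically with predicted suitability (perfect
#' calibration), 0 means no association, -1 a fully inverted model.
#'
#' @param presence_predictions model scores at test presences.
#' @param landscape_predictions model scores over the whole landscape (or a
#'   uniform random sample of it).
#' @param n_windows number of window positions (default 101).
#' @param window_width_fraction window width as a fraction of the landscape
#'   score range, in (0, 1) (default 0.1).
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(presence_predictions, landscape_predictions,
                        n_windows = 101, window_width_fraction = 0.1) {
  if (!length(presence_predictions) || !length(landscape_predictions))
    stop("prediction vectors must be non-empty")
  if (window_width_fraction <= 0 || window_width_fraction >= 1)
    stop("`window_width_fraction` must be in (0, 1)")
  rng <- range(landscape_predictions)
  if (diff(rng) == 0) {
    warning("landscape predictions are constant; Boyce index undefined")
    return(NA_real_)
  }
  w <- window_width_fraction * diff(rng)
  mids <- seq(rng[1L] + w / 2, rng[2L] - w / 2, length.out = n_windows)
  FF <- vapply(mids, function(m) {
    inside_p <- mean(presence_predictions >= m - w / 2 &
                     presence_predictions <= m + w / 2)
    inside_l <- mean(landscape_predictions >= m - w / 2 &
                     landscape_predictions <= m + w / 2)
    if (inside_l == 0) NA_real_ else inside_p / inside_l
  }, numeric(1L))
  keep <- !is.na(FF)
  if (sum(keep) < 3L)
    stop("fewer than 3 usable windows; increase window width or sample size")
  if (stats::sd(FF[keep]) == 0) return(0)
  suppressWarnings(stats::cor(FF[keep], mids[keep], method = "spearman"))
}

#' Permutation variable importance
#'
#' For each variable, predictions on the original matrix are compared with
#' predictions on a copy in which that single column has been randomly
#' permuted; importance is `1 - |Pearson correlation|` between the two
#' prediction vectors, averaged over `n_permutations` permutations.  A
#' variable the model ignores scores 0; a variable the predictions hinge on
#' scores near 1.
#'
#' @param model a [fit_sdm()] result.
#' @param m numeric matrix covering the model's features (typically presences
#'   plus a background sample).
#' @param n_permutations permutations per variable (default 10).
#' @param seed integer seed.
#' @return object of class `importance_table`: data.frame with columns
#'   `variable`, `importance` (mean over permutations, in `[0, 1]`), `sd`;
#'   attributes `n_permutations` and `seed`.
#' @export
variable_importance <- function(model, m, n_permutations = 10, seed = 1) {
  vars <- model$feature_names
  miss <- setdiff(vars, colnames(m))
  if (length(miss)) stop("matrix is missing feature(s): ",
                         paste(miss, collapse = ", "))
  base <- predict(model, m)
  base_const <- stats::sd(base) == 0
  if (base_const)
    warning("model predictions are constant; importances set to 0")
  set.seed(seed)
  res <- lapply(vars, function(v) {
    imp <- vapply(seq_len(n_permutations), function(i) {
      mm <- m
      mm[, v] <- mm[sample.int(nrow(mm)), v]
      p <- predict(model, mm)
      if (base_const || stats::sd(p) == 0) {
        if (all(p == base)) 0 else 1
      } else 1 - abs(stats::cor(base, p))
    }, numeric(1L))
    c(mean(imp), stats::sd(imp))
  })
  out <- data.frame(variable = vars,
                    importance = vapply(res, `[`, numeric(1L), 1L),
                    sd = vapply(res, `[`, numeric(1L), 2L))
  out$importance <- pmin(pmax(out$importance, 0), 1)
  structure(out, n_permutations = n_permutations, seed = seed,
            class = c("importance_table", "data.frame"))
}

#' Evaluate a fitted model on the held-out split
#'
#' Computes AUC, the maximized TSS with its threshold, and the continuous
#' Boyce index on the test partitions of an 80/20 (or other) split.  The
#' Boyce reference distribution defaults to predictions on the full
#' background matrix, a uniform sample of the landscape.
#'
#' @param model a [fit_sdm()] result.
#' @param split a [split_train_test()] result.
#' @param presence_matrix,background_matrix the full predictor matrices the
#'   split indexes into.
#' @param landscape_scores optional numeric vector of model scores over the
#'   landscape used as the Boyce reference; defaults to predictions on all
#'   background rows.
#' @return object of class `evaluation_report`: list with `auc`, `tss_max`,
#'   `tss_threshold`, `boyce`, `max_sss_threshold`, `n_test_presence`,
#'   `n_test_background`.
#' @export
evaluate_model <- function(model, split, presence_matrix, background_matrix,
                           landscape_scores = NULL) {
  ip <- split$test_presence; ib <- split$test_background
  if (!length(ip) || !length(ib)) stop("test partitions must be non-empty")
  sp <- predict(model, presence_matrix[ip, , drop = FALSE])
  sb <- predict(model, background_matrix[ib, , drop = FALSE])
  if (is.null(landscape_scores))
    landscape_scores <- predict(model, background_matrix)
  mx <- max_sss_threshold(sp, sb)
  boyce <- tryCatch(boyce_index(sp, landscape_scores),
                    error = function(e) NA_real_)
  structure(list(auc = auc(sp, sb),
                 tss_max = mx$tss_max,
                 tss_threshold = mx$threshold,
                 boyce = boyce,
                 max_sss_threshold = mx$threshold,
                 n_test_presence = length(ip),
                 n_test_background = length(ib)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation: AUC %.3f | maxTSS %.3f @ %.3f | Boyce %s | test %d pres / %d bg\n",
    x$auc, x$tss_max, x$tss_threshold,
    ifelse(is.na(x$boyce), "NA", sprintf("%.3f", x$boyce)),
    x$n_test_presence, x$n_test_background))
  invisible(x)
}
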