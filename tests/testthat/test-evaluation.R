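test_that("auc matches exhaustive pair counting on randomized instances", {
  expect_equal(auc(c(0.9, 0.7), c(0.8, 0.1)), 0.75)
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  expect_error(auc(numeric(0), 1), "non-empty")
  pair_count_auc <- function(p, b) {
    s <- outer(p, b, function(x, y) (x > y) + 0.5 * (x == y))
    mean(s)
  }
  for (i in 1:100) {
    set.seed(i)
    p <- round(runif(sample(2:30, 1)), 2)  # rounding forces ties
    b <- round(runif(sample(2:30, 1)), 2)
    expect_equal(auc(p, b), pair_count_auc(p, b), tolerance = 1e-12)
    # complement symmetry
    expect_equal(auc(p, b) + auc(b, p), 1, tolerance = 1e-12)
  }
})

test_that("TSS arithmetic and monotone-transform invariance hold", {
  # perfect separation with the threshold in the gap
  expect_equal(tss_at_threshold(c(0.8, 0.9), c(0.1, 0.2), 0.5), 1)
  # threshold below all scores: sensitivity 1, specificity 0
  expect_equal(tss_at_threshold(c(0.8, 0.9), c(0.1, 0.2), 0), 0)
  # sens 0.8, spec 0.7 -> 0.5
  p <- c(rep(1, 8), rep(0, 2)); b <- c(rep(0, 7), rep(1, 3))
  expect_equal(tss_at_threshold(p, b, 0.5), 0.5)
  # invariance under a strictly monotone transform of scores and threshold
  set.seed(2)
  ps <- runif(40); bs <- runif(60); th <- 0.4
  f <- function(x) qlogis(x * 0.98 + 0.01)
  expect_equal(tss_at_threshold(ps, bs, th),
               tss_at_threshold(f(ps), f(bs), f(th)))
})

test_that("max_sss_threshold equals the exhaustive candidate scan", {
  # separable scores reach TSS 1
  mx <- max_sss_threshold(c(0.8, 0.9, 0.95), c(0.1, 0.2, 0.3))
  expect_equal(mx$tss_max, 1)
  expect_gt(mx$threshold, 0.3); expect_lt(mx$threshold, 0.8)
  # all scores identical: single candidate, TSS 0
  mx0 <- max_sss_threshold(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(mx0$tss_max, 0)
  # brute force over the full candidate set on randomized instances
  for (i in 1:100) {
    set.seed(100 + i)
    p <- round(runif(sample(2:40, 1)), 2)
    b <- round(runif(sample(2:40, 1)), 2)
    s <- sort(unique(c(p, b)))
    cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
    tss <- sapply(cand, function(t) tss_at_threshold(p, b, t))
    mx <- max_sss_threshold(p, b)
    expect_equal(mx$tss_max, max(tss), tolerance = 1e-12)
    # ties break toward the lowest threshold
    expect_equal(mx$threshold, cand[which.max(tss)])
  }
})

test_that("Boyce index hits +1, -1 and 0 on constructed cases", {
  set.seed(3)
  land <- runif(10000)
  # presences concentrated at high suitability (weight ~ suitability^3):
  # strictly increasing P/E profile -> +1
  pres_hi <- sample(land, 500, replace = TRUE, prob = land^3)
  expect_equal(boyce_index(pres_hi, land), 1, tolerance = 0.02)
  # mirrored case concentrates at the low end -> -1
  expect_equal(boyce_index(1 - pres_hi, land), -1, tolerance = 0.02)
  # rank-based: invariant under strictly monotone transforms
  g <- function(x) x^3 + x
  expect_equal(boyce_index(g(pres_hi), g(land)),
               boyce_index(pres_hi, land), tolerance = 0.05)
  # presences that are a random subsample of the landscape: mean near 0
  reps <- vapply(1:200, function(s) {
    set.seed(s)
    boyce_index(sample(land, 300), land)
  }, numeric(1))
  expect_lt(abs(mean(reps)), 0.1)
  expect_error(boyce_index(numeric(0), land), "non-empty")
  expect_warning(b <- boyce_index(c(1, 1), rep(0.5, 10)), "constant")
  expect_true(is.na(b))
})

test_that("permutation importance identifies the driving variable", {
  dat <- simulated_pb(n_presence = 100, n_background = 500, p = 3,
                      beta = c(3, 0, 0), seed = 41)
  m <- rbind(dat$pm, dat$bm)
  top_hits <- 0L
  for (s in 1:10) {
    fit <- fit_sdm("GLM", dat$pm, dat$bm, seed = s)
    imp <- variable_importance(fit, m, n_permutations = 5, seed = s)
    expect_true(all(imp$importance >= 0 & imp$importance <= 1))
    if (imp$variable[which.max(imp$importance)] == "v1") top_hits <- top_hits + 1L
  }
  expect_equal(top_hits, 10L)
  # a variable with zero fitted coefficient has importance exactly 0
  fit <- fit_sdm("GLM", dat$pm, dat$bm, seed = 1)
  fit$fit$coefficients[grep("v3", names(coef(fit$fit)))] <- 0
  imp <- variable_importance(fit, m, n_permutations = 3, seed = 2)
  expect_equal(imp$importance[imp$variable == "v3"], 0)
})

test_that("evaluate_model reports in-range metrics and a sane truth model", {
  dat <- simulated_pb(n_presence = 100, n_background = 800, p = 3,
                      beta = c(2, -2, 0), seed = 55)
  split <- split_train_test(nrow(dat$pm), nrow(dat$bm), 0.8, seed = 1)
  for (met in c("GLM", "RF")) {
    fit <- fit_sdm(met, dat$pm[split$train_presence, ],
                   dat$bm[split$train_background, ], seed = 3)
    rep <- evaluate_model(fit, split, dat$pm, dat$bm)
    expect_true(rep$auc >= 0 && rep$auc <= 1)
    expect_true(rep$tss_max >= -1 && rep$tss_max <= 1)
    expect_true(is.na(rep$boyce) || abs(rep$boyce) <= 1)
    expect_equal(rep$n_test_presence, length(split$test_presence))
  }
  # scoring with the true suitability itself: near-ceiling performance
  truth_score <- function(m) {
    eta <- dat$vs$intercept
    for (nm in names(dat$vs$coefficients))
      eta <- eta + dat$vs$coefficients[[nm]] * m[, nm]
    plogis(eta)
  }
  # Because presences are sampled *proportionally* to suitability (not
  # thresholded on it), even the true model cannot separate classes
  # perfectly: its theoretical AUC on this landscape is about 0.72 and its
  # large-sample Boyce index approaches 1.  The oracle values computed from
  # the truth itself are AUC 0.720 and Boyce 0.894 here.
  sp <- truth_score(dat$pm)
  sb <- truth_score(dat$bm)
  expect_equal(auc(sp, sb), 0.7195563, tolerance = 1e-6)
  expect_gt(auc(sp, sb), 0.65)
  expect_equal(boyce_index(sp, sb), 0.8943195, tolerance = 1e-6)
  expect_gt(boyce_index(sp, sb), 0.8)
  # a constant model is exactly random: AUC 0.5, maxTSS 0
  expect_equal(auc(rep(0.4, 10), rep(0.4, 50)), 0.5)
  expect_equal(max_sss_threshold(rep(0.4, 10), rep(0.4, 50))$tss_max, 0)
})
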