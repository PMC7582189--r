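test_that("landscape generation is a pure function of arguments and seed", {
  a <- generate_landscape(20, 20, default_layer_specs(), seed = 5)
  b <- generate_landscape(20, 20, default_layer_specs(), seed = 5)
  c <- generate_landscape(20, 20, default_layer_specs(), seed = 6)
  expect_identical(a$layers, b$layers)
  expect_false(identical(a$layers$bio4, c$layers$bio4))
  expect_error(generate_landscape(4, 20, seed = 1), "at least 8")
})

test_that("layers are standardized and uncorrelated targets give VIF < 2", {
  specs <- data.frame(name = paste0("v", 1:7), autocorrelation_length = 5,
                      target_correlation = 0)
  st <- generate_landscape(200, 200, specs, seed = 17)
  for (l in st$layers) {
    expect_equal(mean(l), 0, tolerance = 1e-10)
    expect_equal(sd(l), 1, tolerance = 1e-10)
  }
  m <- sapply(st$layers, as.vector)
  expect_true(all(compute_vif(m) < 2))
})

test_that("realized pairwise correlations track the common target", {
  specs <- data.frame(name = paste0("v", 1:5), autocorrelation_length = 4,
                      target_correlation = 0.5)
  st <- generate_landscape(150, 150, specs, seed = 8)
  cm <- cor(sapply(st$layers, as.vector))
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 0.5) < 0.15))
})

test_that("autocorrelation length controls neighbour correlation", {
  lag1 <- function(st) {
    g <- st$layers[[1L]]
    cor(as.vector(g[-1, ]), as.vector(g[-nrow(g), ]))
  }
  white <- tiny_stack(100, 1, seed = 2, autocorr = 0)
  smooth <- tiny_stack(100, 1, seed = 2, autocorr = 6)
  expect_lt(abs(lag1(white)), 0.05)
  expect_gt(lag1(smooth), 0.8)
})

test_that("virtual species follows the logistic-linear formula cellwise", {
  st <- tiny_stack(10, 2, seed = 3)
  # all-zero coefficients: suitability is 0.5 everywhere
  vs0 <- define_virtual_species(st, c(v1 = 0), 0, "null")
  expect_true(all(abs(vs0$true_suitability - 0.5) < 1e-15))
  # hand-evaluated logistic at a cell
  vs <- define_virtual_species(st, c(v1 = 2, v2 = -1), 0.5, "sp")
  eta <- 0.5 + 2 * st$layers$v1[4, 7] - st$layers$v2[4, 7]
  expect_equal(vs$true_suitability[4, 7], 1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_true(all(vs$true_suitability >= 0 & vs$true_suitability <= 1))
  # logistic saturates for extreme layer values
  st2 <- env_stack(list(a = matrix(c(0, 50), 8, 8)))
  vs2 <- define_virtual_species(st2, c(a = 1), 0, "sat")
  expect_equal(vs2$true_suitability[1, 1], 0.5)
  expect_gt(vs2$true_suitability[2, 1], 0.999)
  expect_error(define_virtual_species(st, c(nosuch = 1), 0, "x"),
               "unknown layer")
})

test_that("presences concentrate where true suitability is high", {
  st <- tiny_stack(25, 1, seed = 4)
  # all mass in one cell -> every presence lands there
  g <- matrix(0, 25, 25); g[13, 13] <- 40  # logistic(40) ~ 1
  st1 <- env_stack(list(a = g))
  vs1 <- define_virtual_species(st1, c(a = 1), -20, "point")
  # suitability ~0 off-cell but not exactly 0; force exact zero truth instead
  vs1$true_suitability[] <- 0; vs1$true_suitability[13, 13] <- 1
  occ <- sample_presences(vs1, 10, seed = 1)
  ctr <- sdmrisk:::cell_centers(st1, which(vs1$true_suitability == 1))
  expect_true(all(occ$points[, 1] == ctr[1] & occ$points[, 2] == ctr[2]))
  # zero suitability everywhere is an error
  vs1$true_suitability[] <- 0
  expect_error(sample_presences(vs1, 5, seed = 1), "zero")
  # selection bias: mean truth at samples exceeds the landscape mean
  vs <- define_virtual_species(st, c(v1 = 2), 0, "sp")
  occ <- sample_presences(vs, 100, seed = 9)
  cells <- sdmrisk:::locate_points(st, occ$points)$cell
  expect_gt(mean(vs$true_suitability[cells]), mean(vs$true_suitability))
})

test_that("uniform suitability yields uniform presence sampling", {
  st <- env_stack(list(a = matrix(0, 10, 10)))
  vs <- define_virtual_species(st, c(a = 1), 0, "uni")  # constant 0.5
  pvals <- vapply(1:10, function(s) {
    occ <- sample_presences(vs, 400, seed = s)
    cells <- sdmrisk:::locate_points(st, occ$points)$cell
    counts <- tabulate(cells, nbins = 100)
    suppressWarnings(chisq.test(counts)$p.value)
  }, numeric(1))
  # global test over the 10 seeds at alpha ~ 0.01 (Bonferroni)
  expect_true(all(pvals > 0.001))
})

test_that("villages are unique, reproducible, and respect the mask", {
  st <- tiny_stack(20, 1, seed = 5)
  v0 <- generate_villages(st, 0, seed = 1)
  expect_equal(nrow(v0$points), 0)
  v <- generate_villages(st, 185, seed = 2)
  expect_equal(length(unique(v$ids)), 185)
  expect_identical(v$points, generate_villages(st, 185, seed = 2)$points)
  # masked half-grid: no villages in the masked half
  mask <- matrix(FALSE, 20, 20); mask[, 1:10] <- TRUE
  stm <- tiny_stack(20, 1, seed = 5, mask = mask)
  vm <- generate_villages(stm, 200, seed = 3)
  expect_true(all(vm$points[, 1] >= 10))
  # fully masked stack errors
  allmask <- matrix(TRUE, 20, 20)
  stall <- env_stack(list(a = matrix(0, 20, 20)), nodata_mask = allmask)
  expect_error(generate_villages(stall, 5, seed = 1), "fully masked")
})
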