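# Shared fixtures, generated in code at test time.

# Small landscape with uncorrelated white-noise layers (fast default).
tiny_stack <- function(n = 30, p = 3, seed = 42, autocorr = 0, corr = 0,
                       mask = NULL) {
  specs <- data.frame(name = paste0("v", seq_len(p)),
                      autocorrelation_length = autocorr,
                      target_correlation = corr,
                      stringsAsFactors = FALSE)
  generate_landscape(n, n, specs, seed = seed, nodata_mask = mask)
}

# Matrix with named columns from raw vectors.
named_matrix <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

# Presence/background matrices simulated from a logistic-linear truth over
# white-noise predictors; returns the pieces needed for fitting tests.
simulated_pb <- function(n_presence = 100, n_background = 1000, p = 3,
                         beta = c(2, -2, 0), intercept = 0, seed = 1) {
  st <- tiny_stack(50, p, seed = seed)
  coefs <- stats::setNames(beta, layer_names(st))[beta != 0]
  vs <- define_virtual_species(st, coefs, intercept, "sim")
  occ <- sample_presences(vs, n_presence, seed = seed + 1)
  bg <- sample_background(st, n_background, seed = seed + 2)
  list(stack = st, vs = vs,
       pm = extract_at_points(st, occ),
       bm = extract_at_points(st, bg$points))
}

# Plain suitability surface over a constant-value grid.
flat_surface <- function(value, n = 4, species_id = "sp", method = "m") {
  st <- tiny_stack(max(n, 8), 1, seed = 1)
  g <- matrix(value, max(n, 8), max(n, 8))
  suitability_surface(g, st, species_id = species_id, method = method)
}
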