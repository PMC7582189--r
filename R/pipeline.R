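#' Default pipeline configuration
#'
#' The default run simulates a 150 x 150 equal-area landscape with the seven
#' default predictor layers, four virtual snake species (each driven by two
#' predictors with distinct effect sizes, occurrence counts 89, 68, 54, 37 —
#' the typical record counts for wide-ranging venomous snakes), 10,000
#' background points per species, an 80/20 calibration split, all five
#' learners, and 1,850 villages scattered uniformly over the extent.
#'
#' @param seed master seed; every stage seed is derived from it
#'   deterministically (see [stage_seed()]).
#' @return named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    grid = c(150L, 150L),
    cell_size_km = 1,
    layer_specs = default_layer_specs(),
    species = list(
      list(id = "species_A", coefficients = c(bio4 = 2, bio12 = -1),
           intercept = -0.5, n_presence = 89L),
      list(id = "species_B", coefficients = c(bio12 = 2, bio17 = 1),
           intercept = -0.5, n_presence = 68L),
      list(id = "species_C", coefficients = c(bio15 = -2, ndvi = 1),
           intercept = -0.5, n_presence = 54L),
      list(id = "species_D", coefficients = c(hfp = 2, sd_elev = -1),
           intercept = -0.5, n_presence = 37L)),
    methods = c("GLM", "GAM", "GBM", "RF", "MAXENT"),
    n_background = 10000L,
    train_fraction = 0.8,
    vif_threshold = 5,
    vif_sample_cells = 10000L,
    n_villages = 1850L,
    n_permutations = 10L,
    importance_background_sample = 1000L,
    ensemble_weighting = "equal",   # or "tss"
    write_rescaled_risk = TRUE,
    seed = seed)
}

#' Deterministic per-stage seed
#'
#' Hashes the master seed together with the stage name and species label so
#' that adding or reordering species never perturbs another species' random
#' draws.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @param species species label (empty for global stages).
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master, stage, species = "") {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(paste(stage, species, sep = ":")))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full risk-mapping pipeline
#'
#' Orchestrates simulate -> screen -> fit -> evaluate -> ensemble -> risk ->
#' exposure from one configuration, writing every artifact under `outdir`:
#' per species the five method surfaces, the ensemble surface, the binary
#' (maxSSS) map, evaluation and importance tables; plus the multiplicative
#' risk surface, the exposure table, and a JSON run manifest.  The run is a
#' pure function of the configuration: a rerun with the same master seed
#' reproduces every CSV/JSON byte for byte.
#'
#' @param config list as returned by [default_config()] (entries may be
#'   overridden).
#' @param outdir output directory, created if missing.
#' @return invisibly, a list with the in-memory results: `stack`,
#'   `vif_report`, `species` (per-species fits, reports, surfaces,
#'   thresholds), `risk`, `exposure`, `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  cfg <- utils::modifyList(default_config(), config)
  # list-valued keys are replaced wholesale, not merged element-wise
  for (key in intersect(c("species", "layer_specs"), names(config)))
    cfg[[key]] <- config[[key]]
  if (length(cfg$species) < 2L)
    stop("stage 'risk' needs at least 2 species; configure 2 or more")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ms <- cfg$seed

  stack <- with_stage("simulate", generate_landscape(
    cfg$grid[1L], cfg$grid[2L], cfg$layer_specs,
    seed = stage_seed(ms, "landscape"), cell_size = cfg$cell_size_km))
  villages <- with_stage("simulate", generate_villages(
    stack, cfg$n_villages, seed = stage_seed(ms, "villages")))
  write_points_csv(villages, file.path(outdir, "villages.csv"))

  screen <- with_stage("screen", {
    ok <- valid_cells(stack)
    set.seed(stage_seed(ms, "vif_cells"))
    cells <- ok[sample.int(length(ok), min(cfg$vif_sample_cells, length(ok)))]
    m <- vapply(stack$layers, function(l) l[cells], numeric(length(cells)))
    vif_screen(m, threshold = cfg$vif_threshold)
  })
  write_vif_report(screen, file.path(outdir, "vif_report.json"),
                   file.path(outdir, "vif_report.csv"))
  vars <- screen$retained

  eval_rows <- list(); imp_rows <- list()
  species_out <- list(); ensembles <- list(); exposures <- list()
  cell_area <- cfg$cell_size_km^2

  for (sp in cfg$species) {
    sid <- sp$id
    res <- with_stage(paste0("fit:", sid), {
      vs <- define_virtual_species(stack, sp$coefficients, sp$intercept, sid)
      occ <- sample_presences(vs, sp$n_presence,
                              seed = stage_seed(ms, "presences", sid))
      bg <- sample_background(stack, cfg$n_background,
                              seed = stage_seed(ms, "background", sid))
      pm0 <- extract_at_points(stack, occ, "occurrences")
      bm0 <- extract_at_points(stack, bg$points, "background")
      pm <- pm0[, vars, drop = FALSE]; attr(pm, "cells") <- attr(pm0, "cells")
      bm <- bm0[, vars, drop = FALSE]; attr(bm, "cells") <- attr(bm0, "cells")
      split <- split_train_test(nrow(pm), nrow(bm), cfg$train_fraction,
                                seed = stage_seed(ms, "split", sid))
      write_points_csv(occ, file.path(outdir, paste0(sid, "_occurrences.csv")))

      set.seed(stage_seed(ms, "imp_sample", sid))
      imp_m <- rbind(pm, bm[sample.int(nrow(bm),
                       min(cfg$importance_background_sample, nrow(bm))), ,
                       drop = FALSE])

      fits <- list(); reports <- list(); surfaces <- list(); imps <- list()
      for (met in cfg$methods) {
        fit <- fit_sdm(met, pm[split$train_presence, , drop = FALSE],
                       bm[split$train_background, , drop = FALSE],
                       seed = stage_seed(ms, paste0("fit_", met), sid))
        reports[[met]] <- evaluate_model(fit, split, pm, bm)
        imps[[met]] <- variable_importance(fit, imp_m, cfg$n_permutations,
                                           seed = stage_seed(ms, paste0("imp_", met), sid))
        surf <- predict_surface(fit, stack, species_id = sid)
        write_ascii_grid(surf$grid, stack$transform,
                         file.path(outdir, sprintf("%s_%s.asc", sid, met)))
        fits[[met]] <- fit; surfaces[[met]] <- surf
      }
      list(vs = vs, occ = occ, bg = bg, pm = pm, bm = bm, split = split,
           fits = fits, reports = reports, surfaces = surfaces,
           importances = imps)
    })

    ens <- with_stage(paste0("ensemble:", sid), {
      w <- if (identical(cfg$ensemble_weighting, "tss"))
        vapply(res$reports, function(r) max(r$tss_max, 1e-6), numeric(1L))
      else NULL
      ensemble_mean(unname(res$surfaces), weights = w, species_id = sid)
    })
    write_ascii_grid(ens$grid, stack$transform,
                     file.path(outdir, sprintf("%s_ensemble.asc", sid)))

    expo <- with_stage(paste0("exposure:", sid), {
      cells_p <- attr(res$pm, "cells"); cells_b <- attr(res$bm, "cells")
      sp_scores <- ens$grid[cells_p[res$split$test_presence]]
      bg_scores <- ens$grid[cells_b[res$split$test_background]]
      mx <- max_sss_threshold(sp_scores, bg_scores)
      ens_report <- list(
        auc = auc(sp_scores, bg_scores), tss_max = mx$tss_max,
        tss_threshold = mx$threshold,
        boyce = tryCatch(boyce_index(sp_scores, ens$grid[valid_cells(stack)]),
                         error = function(e) NA_real_),
        max_sss_threshold = mx$threshold,
        n_test_presence = length(sp_scores),
        n_test_background = length(bg_scores))
      class(ens_report) <- "evaluation_report"
      t_suit <- min(max(mx$threshold, 1e-6), 1 - 2e-6)
      t_high <- min(max((t_suit + max(ens$grid, na.rm = TRUE)) / 2,
                        t_suit + 1e-9), 1 - 1e-6)
      cmap <- classify_risk(ens, t_suit, t_high)
      bin <- binarize(ens, t_suit)
      write_ascii_grid(bin + 0, stack$transform,
                       file.path(outdir, sprintf("%s_binary.asc", sid)))
      list(ens_report = ens_report, class_map = cmap, binary = bin,
           t_suitable = t_suit, t_high = t_high,
           villages = villages_at_risk(villages, cmap),
           area_km2 = suitable_area(bin, cell_area))
    })

    for (met in cfg$methods) {
      r <- res$reports[[met]]
      eval_rows[[length(eval_rows) + 1L]] <- data.frame(
        species = sid, method = met,
        metric = c("AUC", "TSS_max", "TSS_threshold", "Boyce"),
        value = c(r$auc, r$tss_max, r$tss_threshold, r$boyce))
      i <- res$importances[[met]]
      imp_rows[[length(imp_rows) + 1L]] <- data.frame(
        species = sid, method = met, variable = i$variable,
        importance = i$importance, sd = i$sd)
    }
    r <- expo$ens_report
    eval_rows[[length(eval_rows) + 1L]] <- data.frame(
      species = sid, method = "ensemble",
      metric = c("AUC", "TSS_max", "TSS_threshold", "Boyce"),
      value = c(r$auc, r$tss_max, r$tss_threshold, r$boyce))

    species_out[[sid]] <- c(res, expo)
    ensembles[[sid]] <- ens
    exposures[[sid]] <- list(villages = expo$villages, area_km2 = expo$area_km2)
  }

  risk <- with_stage("risk", risk_product(unname(ensembles)))
  write_ascii_grid(risk$grid, stack$transform, file.path(outdir, "risk.asc"))
  if (isTRUE(cfg$write_rescaled_risk)) {
    g <- risk$grid
    rng <- range(g, na.rm = TRUE)
    if (diff(rng) > 0) g <- (g - rng[1L]) / diff(rng)
    write_ascii_grid(g, stack$transform,
                     file.path(outdir, "risk_rescaled.asc"))
  }

  expo_tab <- exposure_table(exposures)
  utils::write.csv(expo_tab, file.path(outdir, "exposure.csv"),
                   row.names = FALSE, quote = FALSE)
  evals <- do.call(rbind, eval_rows)
  utils::write.csv(evals, file.path(outdir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE)
  imps <- do.call(rbind, imp_rows)
  utils::write.csv(imps, file.path(outdir, "importance.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdmrisk")),
    master_seed = ms,
    config = cfg[setdiff(names(cfg), c("layer_specs", "species"))],
    layer_specs = cfg$layer_specs,
    species = lapply(cfg$species, function(s)
      list(id = s$id, coefficients = as.list(s$coefficients),
           intercept = s$intercept, n_presence = s$n_presence)),
    thresholds = lapply(species_out, function(s)
      list(t_suitable = s$t_suitable, t_high = s$t_high)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(stack = stack, villages = villages, vif_report = screen,
                 species = species_out, ensembles = ensembles, risk = risk,
                 exposure = expo_tab, evaluation = evals, importance = imps,
                 outdir = outdir))
}
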