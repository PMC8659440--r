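# End-to-end experiment: simulate -> pretreatment comparison -> wavelength
# selection -> PCA -> PLS/ELM/SVR -> evaluation (-> maps).

#' Build and validate an experiment configuration
#'
#' Plain-list configuration that round-trips through YAML without loss. The
#' defaults describe the package's standard desk-scale experiment: the 18
#' sample x 10 replicate synthetic fermentation data set on the 401-band
#' 400-960 nm grid, a 3:1 Kennard-Stone split, the seven pretreatments
#' compared by full-band PLS Rp, per-component selectors following the usual
#' pairing (SPA for total catechins, VCPA-GA for EGC/ECG, VCPA-IRIV for
#' C/EC/EGCG), and all three model families.
#'
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @param replicates spectra per chemistry sample (default 10 -> 180 spectra).
#' @param components components to model.
#' @param pretreatments pretreatments to compare.
#' @param selectors named list: per-component list(algorithm = ..., params).
#' @param models subset of c("pls", "elm", "svr").
#' @param split_fraction calibration fraction of the Kennard-Stone split.
#' @param folds CV folds for RMSECV and selector fitness.
#' @param max_pcs PCA score cap fed to the models.
#' @param nonlinear turn on the generator's saturating content-absorbance
#'   link.
#' @param render_maps also render a pixel map for `map_component`.
#' @param map_component component mapped when `render_maps` is TRUE.
#' @param out_dir optional output directory for report files.
#' @return validated config (class `experiment_config`, a plain list).
#' @export
experiment_config <- function(seed = 1,
                              replicates = 10,
                              components = catechin_components(),
                              pretreatments = c("smooth", "snv", "msc", "d2",
                                                "center", "zscore", "minmax"),
                              selectors = default_selectors(),
                              models = c("pls", "elm", "svr"),
                              split_fraction = 0.75,
                              folds = 5,
                              max_pcs = 15,
                              nonlinear = FALSE,
                              render_maps = FALSE,
                              map_component = "ec",
                              out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), replicates = replicates,
              components = components, pretreatments = pretreatments,
              selectors = selectors, models = models,
              split_fraction = split_fraction, folds = folds,
              max_pcs = max_pcs, nonlinear = nonlinear,
              render_maps = render_maps, map_component = map_component,
              out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = c("experiment_config", "list"))
}

#' @rdname experiment_config
#' @export
default_selectors <- function() {
  desk_vcpa <- list(n_bms = 100, edf_loops = 6, final_size = 40)
  list(
    total = list(algorithm = "spa", params = list(kmin = 5, kmax = 20)),
    egc   = list(algorithm = "vcpa-ga", params = desk_vcpa),
    c     = list(algorithm = "vcpa-iriv", params = desk_vcpa),
    ec    = list(algorithm = "vcpa-iriv", params = desk_vcpa),
    egcg  = list(algorithm = "vcpa-iriv", params = desk_vcpa),
    ecg   = list(algorithm = "vcpa-ga", params = desk_vcpa)
  )
}

validate_config <- function(cfg) {
  if (length(cfg$models) == 0) {
    stop("config lists no models.", call. = FALSE)
  }
  bad <- setdiff(cfg$models, c("pls", "elm", "svr"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(cfg$components, catechin_components())
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  missing_sel <- setdiff(cfg$components, names(cfg$selectors))
  if (length(missing_sel)) {
    stop("no selector configured for: ", paste(missing_sel, collapse = ", "),
         call. = FALSE)
  }
  algs <- vapply(cfg$selectors, `[[`, "", "algorithm")
  bad <- setdiff(algs, c("spa", "sfla", "vcpa", "vcpa-ga", "vcpa-iriv"))
  if (length(bad)) stop("unknown selector algorithm(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  known_pre <- c("none", "smooth", "snv", "msc", "d2", "center", "zscore",
                 "minmax")
  bad <- setdiff(cfg$pretreatments, known_pre)
  if (length(bad)) stop("unknown pretreatment(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    stop("`split_fraction` must be in (0, 1).", call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read an experiment config as YAML
#' @param cfg an `experiment_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}

#' Compare spectral pretreatments by full-band PLS
#'
#' Fits a PLS model per pretreatment (latent variables chosen by minimal
#' RMSECV) on absorbance spectra and ranks the pretreatments by the
#' prediction-set correlation Rp; the argmax row is marked selected. A
#' failing pretreatment yields a row flagged `failed` and the comparison
#' continues.
#'
#' @param spectra reflectance `spectra_set`.
#' @param chem chemistry tibble with `sample_id` and the component column.
#' @param component component name (e.g. "ec").
#' @param split optional `cal_split`; default Kennard-Stone 3:1 on absorbance.
#' @param folds CV folds for RMSECV.
#' @param pretreatments at least two method names.
#' @param max_pcs latent-variable cap.
#' @param seed fold-shuffle seed.
#' @param quantity model on "absorbance" (default) or raw "reflectance".
#' @return tibble: component, method, pcs, rc, rmsecv, rp, rmsep, failed,
#'   selected.
#' @export
compare_pretreatments <- function(spectra, chem, component, split = NULL,
                                  folds = 5,
                                  pretreatments = c("smooth", "snv", "msc",
                                                    "d2", "center", "zscore",
                                                    "minmax"),
                                  max_pcs = 15, seed = 1,
                                  quantity = c("absorbance", "reflectance")) {
  quantity <- match.arg(quantity)
  if (length(pretreatments) < 2) {
    stop("configure at least two pretreatments.", call. = FALSE)
  }
  y_all <- component_response(spectra, chem, component)
  raw <- spectra$values
  if (is.null(split)) {
    split <- kennard_stone(-log10(raw), cal_fraction = 0.75)
  }
  cal <- split$calibration; prd <- split$prediction
  prefix <- if (quantity == "absorbance") "absorbance" else character()
  rows <- purrr::map(pretreatments, function(m) {
    tryCatch({
      fitted <- fit_preproc_chain(raw[cal, , drop = FALSE], c(prefix, m))
      Xc <- fitted$cal
      Xp <- apply_preproc_chain(raw[prd, , drop = FALSE], fitted$chain)
      cv <- choose_pcs_by_rmsecv(Xc, y_all[cal], "pls", folds = folds,
                                 seed = seed, max_pcs = max_pcs)
      model <- pls_train(Xc, y_all[cal], n_lv = cv$best_pcs)
      ev <- evaluate_model(model, Xc, y_all[cal], Xp, y_all[prd],
                           rmsecv = cv$rmsecv, pcs = cv$best_pcs)
      dplyr::mutate(ev, component = component, method = m, failed = FALSE,
                    .before = 1)
    }, error = function(e) {
      tibble::tibble(component = component, method = m, failed = TRUE,
                     pcs = NA_integer_, rc = NA_real_, rmsecv = NA_real_,
                     rp = NA_real_, rmsep = NA_real_, rpd = NA_real_,
                     grade = NA_character_)
    })
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- !out$failed & !is.na(out$rp) &
    out$rp == max(out$rp, na.rm = TRUE)
  dplyr::select(out, "component", "method", "pcs", "rc", "rmsecv", "rp",
                "rmsep", "failed", "selected")
}

# match per-spectrum response values by sample_id
component_response <- function(spectra, chem, component) {
  if (!component %in% names(chem)) {
    stop("component `", component, "` not found in the chemistry table.",
         call. = FALSE)
  }
  y <- chem[[component]][match(spectra$meta$sample_id, chem$sample_id)]
  if (anyNA(y)) stop("spectra metadata and chemistry table do not match.",
                     call. = FALSE)
  y
}

run_selector <- function(sel_cfg, Xcal, ycal, wavelengths_nm, fitness, seed) {
  params <- sel_cfg$params %||% list()
  alg <- sel_cfg$algorithm
  if (alg == "spa") {
    do.call(spa_select, c(list(Xcal = Xcal, ycal = ycal,
                               wavelengths_nm = wavelengths_nm), params))
  } else if (alg == "sfla") {
    do.call(sfla_select, c(list(Xcal = Xcal, ycal = ycal, fitness = fitness,
                                seed = seed,
                                wavelengths_nm = wavelengths_nm), params))
  } else if (alg == "vcpa") {
    do.call(vcpa_select, c(list(Xcal = Xcal, ycal = ycal, fitness = fitness,
                                seed = seed,
                                wavelengths_nm = wavelengths_nm), params))
  } else if (alg %in% c("vcpa-ga", "vcpa-iriv")) {
    refine_params <- params$refine %||% list()
    vc <- do.call(vcpa_select,
                  c(list(Xcal = Xcal, ycal = ycal, fitness = fitness,
                         seed = seed, wavelengths_nm = wavelengths_nm),
                    params[setdiff(names(params), "refine")]))
    refine_subset(Xcal, ycal, vc$survivors,
                  mode = if (alg == "vcpa-ga") "GA" else "IRIV",
                  fitness = fitness, params = refine_params, seed = seed,
                  wavelengths_nm = wavelengths_nm)
  } else {
    stop("unknown selector: ", alg, call. = FALSE)
  }
}

#' Run the full fermentation-monitoring experiment
#'
#' Simulates the default fermentation chemistry and spectra, partitions the
#' samples with Kennard-Stone, compares pretreatments per component (winner
#' feeds the selectors), screens characteristic wavelengths, compresses with
#' PCA, fits the configured models with RMSECV-chosen component counts, and
#' evaluates each on the prediction set. Deterministic for a fixed config.
#' When `cfg$out_dir` is set, writes report_pretreatment.csv,
#' report_models.csv, per-component selection JSON, config.yaml, run.log and
#' (optionally) maps.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `experiment_report`: list with `pretreatment`
#'   and `models` tibbles, `selections`, `chem`, `split`, and `provenance`.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  validate_config(cfg)
  t0 <- Sys.time()
  log_lines <- character()
  log_add <- function(...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  grid <- default_grid()
  lib <- component_library(grid)
  params <- kinetic_params()
  chem <- simulate_kinetics(params)
  spectra <- simulate_spectra(chem, lib, noise_model(seed = cfg$seed),
                              replicates = cfg$replicates,
                              nonlinear = cfg$nonlinear)
  log_add("simulated %d spectra on %d bands", nrow(spectra$values),
          length(grid))

  raw <- spectra$values
  split <- kennard_stone(-log10(raw), cal_fraction = cfg$split_fraction)
  cal <- split$calibration; prd <- split$prediction
  log_add("Kennard-Stone split: %d calibration / %d prediction",
          length(cal), length(prd))

  pre_rows <- list(); model_rows <- list(); selections <- list()
  artifacts <- list()
  for (comp in cfg$components) {
    y <- component_response(spectra, chem, comp)
    pre <- compare_pretreatments(spectra, chem, comp, split = split,
                                 folds = cfg$folds,
                                 pretreatments = cfg$pretreatments,
                                 max_pcs = cfg$max_pcs, seed = cfg$seed + 1L)
    winner <- pre$method[which(pre$selected)][1]
    pre_rows[[comp]] <- pre
    log_add("%s: pretreatment winner = %s", comp, winner)

    fitted <- fit_preproc_chain(raw[cal, , drop = FALSE],
                                c("absorbance", winner))
    Xc <- fitted$cal
    Xp <- apply_preproc_chain(raw[prd, , drop = FALSE], fitted$chain)

    fitness <- subset_fitness(Xc, y[cal], folds = cfg$folds,
                              seed = cfg$seed + 2L)
    sel <- run_selector(cfg$selectors[[comp]], Xc, y[cal],
                        as.numeric(grid), fitness, seed = cfg$seed + 3L)
    selections[[comp]] <- sel
    log_add("%s: %s kept %d bands (reduction %.1f%%)", comp, sel$algorithm,
            length(sel$indices), 100 * sel$reduction_ratio)

    max_pcs <- min(cfg$max_pcs, length(sel$indices), length(cal) - 1)
    red <- pca_reduce(Xc, Xp, sel$indices, max_pcs)

    comp_best <- NULL
    for (mk in cfg$models) {
      cv <- choose_pcs_by_rmsecv(red$cal_scores, y[cal], mk,
                                 folds = cfg$folds, seed = cfg$seed + 4L)
      ncs <- cv$best_pcs
      Sc <- red$cal_scores[, seq_len(ncs), drop = FALSE]
      Sp <- red$pred_scores[, seq_len(ncs), drop = FALSE]
      fit <- switch(mk,
        pls = pls_train(Sc, y[cal], n_lv = ncs),
        elm = elm_train(Sc, y[cal], seed = cfg$seed + 5L),
        svr = svr_train_tuned(Sc, y[cal], c_grid = 2^seq(-2, 6, by = 1),
                              g_grid = 2^seq(-7, 1, by = 1),
                              folds = cfg$folds, seed = cfg$seed + 6L)$model
      )
      ev <- evaluate_model(fit, Sc, y[cal], Sp, y[prd],
                           rmsecv = cv$rmsecv, pcs = ncs)
      row <- dplyr::mutate(
        ev,
        component = comp,
        method = paste0(toupper(sel$algorithm), "-", toupper(mk)),
        variable_number = length(sel$indices),
        reduction_ratio = sel$reduction_ratio,
        dynamic_range = diff(range(chem[[comp]])),
        .before = 1
      )
      model_rows[[paste(comp, mk)]] <- row
      if (is.null(comp_best) || row$rp > comp_best$row$rp) {
        comp_best <- list(row = row, fit = fit, pcs = ncs)
      }
      log_add("%s / %s: PCs = %d, Rp = %.3f, RPD = %.2f", comp, mk, ncs,
              row$rp, row$rpd)
    }
    pca_best <- red$model
    pca_best$rotation <- pca_best$rotation[, seq_len(comp_best$pcs), drop = FALSE]
    pca_best$n_components <- comp_best$pcs
    artifacts[[comp]] <- list(chain = fitted$chain, selection = sel,
                              pca = pca_best, pca_full = red$model,
                              best = comp_best)
  }

  report <- structure(
    list(
      pretreatment = dplyr::bind_rows(pre_rows),
      models = dplyr::bind_rows(model_rows),
      selections = selections,
      chem = chem,
      split = split,
      artifacts = artifacts,
      provenance = list(
        seed = cfg$seed,
        package_version = as.character(utils::packageVersion("teaspec")),
        config_hash = rlang::hash(unclass(cfg)),
        n_spectra = nrow(raw), n_bands = ncol(raw)
      )
    ),
    class = "experiment_report"
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(report$pretreatment,
                     file.path(cfg$out_dir, "report_pretreatment.csv"))
    readr::write_csv(report$models,
                     file.path(cfg$out_dir, "report_models.csv"))
    for (comp in names(selections)) {
      write_selection_json(selections[[comp]],
                           file.path(cfg$out_dir,
                                     sprintf("selection_%s.json", comp)))
    }
    write_config(cfg, file.path(cfg$out_dir, "config.yaml"))
    if (isTRUE(cfg$render_maps) && cfg$map_component %in% names(artifacts)) {
      map_dir <- file.path(cfg$out_dir, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      art <- artifacts[[cfg$map_component]]
      row2h <- chem[chem$time_h == 2 & chem$layer == "middle", ]
      sim <- simulate_cube(row2h, lib, noise_model(seed = cfg$seed + 7L),
                           height = 64, width = 64, params = params)
      mask <- background_mask(sim$cube)
      pm <- predict_map(sim$cube, mask, art$chain, art$selection, art$pca,
                        art$best$fit, component = cfg$map_component)
      render_map(pm, file.path(map_dir,
                               sprintf("map_%s.png", cfg$map_component)))
      log_add("rendered map for %s", cfg$map_component)
    }
    log_add("report written to %s", cfg$out_dir)
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  seed %d, %d spectra x %d bands\n", x$provenance$seed,
              x$provenance$n_spectra, x$provenance$n_bands))
  cat("  model table:\n")
  print(dplyr::select(x$models, "component", "method", "variable_number",
                      "pcs", "rc", "rmsecv", "rp", "rmsep", "rpd"), n = 30)
  invisible(x)
}

#' @export
glance.experiment_report <- function(x, ...) {
  x$models |>
    dplyr::group_by(.data$component) |>
    dplyr::slice_max(.data$rp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("component", "method", "pcs", "rp", "rmsep", "rpd", "grade")
}
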