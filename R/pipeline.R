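# End-to-end orchestration: simulate (or load) inputs, derive predictors,
# class yields, fit/evaluate one model per crop, project scenarios, and
# aggregate multi-crop scores, with a manifest recording seeds and hashes.

default_response <- function(driver) {
  scale <- switch(driver,
    rain_growing_season = 200, rain_mar_sep = 400, rain_sowing_month = 100,
    rain_cv = 20, dtr_mar_sep = 2.5, tmean_growing_season = 8,
    tmean_mar_sep = 8, soil_organic_carbon = 10,
    stop(sprintf("unknown driver '%s'", driver)))
  function(x) pmax(0, x / scale)
}

#' Default pipeline configuration
#'
#' A complete synthetic-world configuration: an 11-year daily weather grid
#' calibrated to the national baseline climate, 40 districts, four crops
#' whose yields are driven by different predictors, a 70/30 stratified
#' split, a compact tuning grid, and the bundled national GCM delta table.
#' Every entry can be overridden; the tuning grid in particular can be
#' replaced with [default_tuning_grid()] for a full search.
#'
#' @param nlat,nlon grid dimensions.
#' @param years simulated years.
#' @param seed root seed for every stage.
#' @return nested configuration list for [run_pipeline()].
#' @export
default_config <- function(nlat = 25, nlon = 25, years = 11, seed = 1) {
  list(
    seed = seed,
    grid = list(nlat = nlat, nlon = nlon, years = years, start_year = 2006),
    region = list(n_districts = 40, mask_frac = 1),
    yields_csv = NULL,  # path to a district,crop,year,yield_t_ha CSV; NULL = simulate
    crops = list(
      maize = list(driver = "rain_mar_sep", noise_sd = 0.25),
      sorghum = list(driver = "dtr_mar_sep", noise_sd = 0.25),
      cassava = list(driver = "rain_growing_season", noise_sd = 0.25),
      groundnut = list(driver = "rain_sowing_month", noise_sd = 0.25)
    ),
    split = list(fraction = 0.7),
    tuning = list(
      grid = expand.grid(nrounds = c(50L, 100L), max_depth = c(2L, 4L),
                         eta = c(0.1, 0.3), KEEP.OUT.ATTRS = FALSE),
      nfolds = 3
    ),
    deltas = ghana_climate_deltas(),
    cell_area = list(mode = "equal", cell_km2 = (111.32 * 0.05)^2)
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full suitability pipeline
#'
#' Composes all stages: weather/region simulation (or yield-table input),
#' predictor derivation, percentile classing, per-crop model fitting and
#' evaluation, gain importance, scenario projection under the configured
#' GCM deltas, multi-crop scoring, and area-change accounting. All
#' artifacts are written as plain CSV (plus the serialized models) under
#' `out_dir`, and a JSON manifest records the configuration, seeds and an
#' MD5 hash of every artifact.
#'
#' Per-crop area changes average the per-GCM change tables (multi-model
#' mean change); multi-crop maps under each scenario use the multi-model
#' mean delta, so each scenario yields one future map per crop.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`region`, `vars`,
#'   per-crop fits and maps, delta summary, multi-crop tables, manifest
#'   path).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("agrisuit_"),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }

  say("stage simulate: %dx%d grid, %d years",
      config$grid$nlat, config$grid$nlon, config$grid$years)
  weather <- stage("simulate", generate_weather(
    config$grid$nlat, config$grid$nlon, config$grid$years,
    config$grid$start_year, seed = seed))
  region <- stage("simulate", generate_region(
    config$grid$nlat, config$grid$nlon, config$region$n_districts,
    mask_frac = config$region$mask_frac, seed = seed))

  say("stage derive-vars")
  vars <- stage("derive-vars", assemble_variables(weather, region))
  keep(write_vars_csv(vars, file.path(out_dir, "vars_baseline.csv")))

  say("stage yields")
  yields <- stage("yields", {
    if (!is.null(config$yields_csv)) read_yield_csv(config$yields_csv)
    else do.call(rbind, lapply(names(config$crops), function(cr) {
      cfg <- config$crops[[cr]]
      generate_yields(weather, region,
                      truth_spec(cfg$driver, default_response(cfg$driver),
                                 cfg$noise_sd),
                      crop = cr, seed = derive_seed(seed, cr))
    }))
  })
  keep(write_yield_csv(yields, file.path(out_dir, "yields.csv")))

  dsum <- stage("scenarios", summarize_deltas(config$deltas))
  write.csv(dsum, keep(file.path(out_dir, "delta_summary.csv")),
            row.names = FALSE)
  scen_ids <- unique(config$deltas$scenario)
  areas <- cell_areas(region$lat, region$lon, config$cell_area$mode,
                      config$cell_area$cell_km2)

  crops_out <- list()
  current_maps <- list()
  future_maps <- setNames(vector("list", length(scen_ids)), scen_ids)
  for (s in scen_ids) future_maps[[s]] <- list()

  for (cr in names(config$crops)) {
    say("stage classify+train: %s", cr)
    cdir <- file.path(out_dir, cr)
    dir.create(cdir, showWarnings = FALSE)
    cls <- stage("classify", class_districts(yields, cr))
    write.csv(data.frame(q25 = cls$thresholds$q25, q50 = cls$thresholds$q50,
                         q75 = cls$thresholds$q75),
              keep(file.path(cdir, "thresholds.csv")), row.names = FALSE)
    labels <- stage("classify", rasterize_labels(cls$classes, region))
    keep(write_grid_csv(labels, region$lat, region$lon,
                        file.path(cdir, "labels.csv")))

    samples <- stage("train", build_samples(vars, labels))
    parts <- stage("train", split_samples(samples, config$split$fraction,
                                          seed = derive_seed(seed, cr)))
    model <- stage("train", tune_and_fit(
      parts$fit, config$tuning$grid, config$tuning$nfolds,
      seed = derive_seed(seed, cr)))
    keep(write_model(model, file.path(cdir, "model.rds")))

    say("stage evaluate: %s", cr)
    pred <- predict(model, parts$test)
    prob <- predict(model, parts$test, type = "prob")
    rep <- stage("evaluate", metrics_report(
      droplevels(factor(as.character(parts$test$class),
                        levels = suitability_levels())), pred, prob))
    write.csv(cbind(crop = cr, rep$overall),
              keep(file.path(cdir, "metrics_overall.csv")), row.names = FALSE)
    write.csv(rep$per_class, keep(file.path(cdir, "metrics_per_class.csv")),
              row.names = FALSE)

    imp <- stage("importance", gain_importance(model))
    write.csv(imp, keep(file.path(cdir, "importance.csv")), row.names = FALSE)
    grp <- rbind(
      cbind(grouping = "cv_in_rainfall",
            group_contributions(imp, variable_groups(TRUE))),
      cbind(grouping = "cv_separate",
            group_contributions(imp, variable_groups(FALSE))))
    write.csv(grp, keep(file.path(cdir, "importance_groups.csv")),
              row.names = FALSE)

    cur_map <- stage("project", predict_map(model, vars))
    current_maps[[cr]] <- cur_map
    keep(write_grid_csv(cur_map$rank, region$lat, region$lon,
                        file.path(cdir, "map_current.csv")))
    cur_area <- area_table(cur_map, areas)

    for (s in scen_ids) {
      say("stage project: %s %s", cr, s)
      gcm_tabs <- list()
      for (g in unique(config$deltas$model)) {
        d <- config$deltas[config$deltas$scenario == s &
                             config$deltas$model == g, ]
        fmap <- stage("project", predict_map(model, apply_delta(vars, d)))
        gcm_tabs[[g]] <- area_table(fmap, areas)
      }
      chg <- stage("project", change_table(cur_area, gcm_tabs))
      write.csv(chg, keep(file.path(cdir, sprintf("area_change_%s.csv",
                                                  gsub("[^A-Za-z0-9.]", "_", s)))),
                row.names = FALSE)
      mean_d <- setNames(dsum$mean_delta[dsum$scenario == s],
                         dsum$variable[dsum$scenario == s])
      smap <- stage("project", predict_map(model, apply_delta(vars, mean_d)))
      future_maps[[s]][[cr]] <- smap
      keep(write_grid_csv(smap$rank, region$lat, region$lon,
                          file.path(cdir, sprintf("map_%s.csv",
                                                  gsub("[^A-Za-z0-9.]", "_", s)))))
    }
    crops_out[[cr]] <- list(classes = cls, model = model, map = cur_map)
  }

  say("stage multicrop")
  mdir <- file.path(out_dir, "multicrop")
  dir.create(mdir, showWarnings = FALSE)
  multicrop <- stage("multicrop", {
    out <- list()
    for (s in c("current", scen_ids)) {
      maps <- if (s == "current") current_maps else future_maps[[s]]
      tag <- gsub("[^A-Za-z0-9.]", "_", s)
      score <- combined_score(maps)
      keep(write_grid_csv(score, region$lat, region$lon,
                          file.path(mdir, sprintf("combined_score_%s.csv", tag))))
      counts <- count_by_class(maps)
      lvl_tabs <- do.call(rbind, lapply(suitability_levels(), function(lv) {
        cnt <- counts[, , lv]
        tab <- area_table(
          matrix(ifelse(is.na(cnt), NA, paste0(pmin(cnt, 4), "_crops")),
                 nrow(cnt), ncol(cnt)),
          areas, categories = paste0(0:4, "_crops"))
        cbind(level = lv, scenario = s, tab)
      }))
      write.csv(lvl_tabs, keep(file.path(mdir, sprintf("crop_counts_%s.csv", tag))),
                row.names = FALSE)
      pair_tabs <- list()
      crs <- names(maps)
      for (i in seq_along(crs)) for (j in seq_along(crs)) if (i < j) {
        ps <- pair_score(maps[[crs[i]]], maps[[crs[j]]])
        pair_tabs[[paste(crs[i], crs[j], sep = "_")]] <-
          cbind(pair = paste(crs[i], crs[j], sep = "-"), scenario = s,
                area_table(ps$category, areas,
                           categories = pair_category_levels()))
      }
      write.csv(do.call(rbind, pair_tabs),
                keep(file.path(mdir, sprintf("pair_areas_%s.csv", tag))),
                row.names = FALSE)
      out[[s]] <- list(score = score, counts = counts)
    }
    out
  })

  say("stage manifest")
  manifest <- list(
    package_version = as.character(utils::packageVersion("agrisuit")),
    seed = seed,
    config_hash = unname(tools::md5sum(
      local({
        p <- file.path(out_dir, "config.json")
        jsonlite::write_json(config[setdiff(names(config), "tuning")], p,
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        keep(p)
      }))),
    artifacts = lapply(unname(files), function(p) {
      list(path = sub(paste0("^", out_dir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  say("done: %s", out_dir)

  invisible(list(region = region, vars = vars, yields = yields,
                 crops = crops_out, delta_summary = dsum,
                 current_maps = current_maps, future_maps = future_maps,
                 multicrop = multicrop, out_dir = out_dir,
                 manifest = mpath))
}
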