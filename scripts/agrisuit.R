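#!/usr/bin/env Rscript
# Thin command-line wrapper over the agrisuit package.
#
#   Rscript scripts/agrisuit.R run      --seed 1 --out rundir [--config cfg.yaml]
#   Rscript scripts/agrisuit.R simulate --seed 1 --out outdir [--nlat 25 --nlon 25 --years 11]
#
# 'run' executes the full pipeline (simulate, derive-vars, classify, train,
# evaluate, importance, project, multicrop); 'simulate' writes only the
# synthetic inputs. A YAML config, if given, overrides matching entries of
# default_config().

suppressPackageStartupMessages({
  library(optparse)
  library(agrisuit)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "simulate")) {
  stop("usage: agrisuit.R <run|simulate> --seed <int> --out <dir> [options]")
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "agrisuit_out"),
  make_option("--config", type = "character", default = NULL),
  make_option("--nlat", type = "integer", default = 25L),
  make_option("--nlon", type = "integer", default = 25L),
  make_option("--years", type = "integer", default = 11L)
)), args = args[-1])

cfg <- default_config(nlat = opts$nlat, nlon = opts$nlon, years = opts$years,
                      seed = opts$seed)
if (!is.null(opts$config)) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for --config")
  cfg <- utils::modifyList(cfg, yaml::read_yaml(opts$config))
}

if (cmd == "simulate") {
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  w <- generate_weather(cfg$grid$nlat, cfg$grid$nlon, cfg$grid$years,
                        cfg$grid$start_year, seed = cfg$seed)
  r <- generate_region(cfg$grid$nlat, cfg$grid$nlon, cfg$region$n_districts,
                       mask_frac = cfg$region$mask_frac, seed = cfg$seed)
  v <- assemble_variables(w, r)
  write_vars_csv(v, file.path(opts$out, "vars_baseline.csv"))
  write_grid_csv(r$soil_carbon, r$lat, r$lon, file.path(opts$out, "soil.csv"))
  write_grid_csv(r$districts, r$lat, r$lon, file.path(opts$out, "districts.csv"))
  yields <- do.call(rbind, lapply(names(cfg$crops), function(cr) {
    generate_yields(w, r, truth_spec(cfg$crops[[cr]]$driver,
                                     noise_sd = cfg$crops[[cr]]$noise_sd),
                    crop = cr, seed = cfg$seed)
  }))
  write_yield_csv(yields, file.path(opts$out, "yields.csv"))
  message("simulated inputs written to ", opts$out)
} else {
  run_pipeline(cfg, opts$out)
}
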