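#' Default pipeline configuration
#'
#' All tunables of the analysis in one structure, each at its standard
#' value: GLCM window 45 px with 32 gray levels, 180-px (562.5 m)
#' classification cells, the published boosting hyperparameters, 50 m
#' plots resampled by 10 to 500 m carbon blocks, the 5-year disturbance
#' age cutoff, and 10,000 Monte Carlo iterations.  `scaled` substitutes
#' the desk-scale synthetic-study settings (11-px window, 16 levels,
#' 48-px cells, 2,000 iterations, 10 ensemble partitions) used by the
#' bundled three-site fixture.
#'
#' @param scaled use the desk-scale synthetic-study settings.
#' @param seed master seed recorded in the config.
#' @return nested named list of parameters.
#' @export
default_run_config <- function(scaled = FALSE, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    sites = "multisite_fixture",
    extent_px = if (scaled) 960L else 7200L,
    glcm = list(window = if (scaled) 11L else 45L,
                levels = if (scaled) 16L else 32L),
    cell_px = if (scaled) 48L else 180L,
    max_age_years = 5L,
    training = list(n_partitions = if (scaled) 10L else 100L),
    acd = list(plot_m = 50, resample_factor = 10L),
    montecarlo = list(n_iter = if (scaled) 2000L else 10000L))
  cfg
}

pipeline_stages <- function() {
  c("simulate-data", "evi", "texture", "features", "train", "assess",
    "acd", "montecarlo")
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p)
  else list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            stages = list())
}

record_stage <- function(out_dir, stage, config, seed, outputs,
                         extra = NULL) {
  man <- read_manifest(out_dir)
  sums <- as.list(tools::md5sum(outputs))
  names(sums) <- basename(outputs)
  entry <- list(config = config, seed = seed, outputs = sums)
  if (!is.null(extra)) entry <- c(entry, extra)
  man$stages[[stage]] <- entry
  jsonlite::write_json(man, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(man)
}

require_inputs <- function(out_dir, files, prior_stage) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing))
    stop("missing input artifact(s) ", paste(missing, collapse = ", "),
         "; run stage '", prior_stage, "' first")
  invisible(TRUE)
}

site_ids_from <- function(out_dir, pattern) {
  fs <- list.files(out_dir, pattern = pattern)
  unique(sub(pattern, "\\1", fs))
}

#' Run one pipeline stage
#'
#' Stages, in order: `simulate-data` (synthetic sites to rasters and
#' polygons), `evi` (EVI from blue/red/NIR band rasters, for real
#' imagery; the synthetic stage already emits EVI), `texture`
#' (moving-window GLCM bands), `features` (aggregation to the
#' classification grid, labels, age filter, per-site standardization),
#' `train` (partition ensemble), `assess` (confusion matrix and accuracy
#' report), `acd` (block-median resampling and site-class
#' distributions with substitution), `montecarlo` (both uncertainty
#' modes and their comparison), or `full-run` for everything runnable in
#' sequence.  Every stage records its outputs and md5 checksums in
#' `manifest.json` under `out_dir`.
#'
#' @param stage stage name.
#' @param config configuration list, see [default_run_config()].
#' @param out_dir artifact directory (created if needed).
#' @param seed master seed; stage-specific seeds derive from it.
#' @return invisibly, a named list of the stage's main in-memory results.
#' @export
run_stage <- function(stage, config = default_run_config(scaled = TRUE),
                      out_dir = "degratex-run", seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(stage, "full-run")) {
    res <- list()
    for (s in setdiff(pipeline_stages(), "evi"))  # synthetic flow emits EVI
      res[[s]] <- run_stage(s, config, out_dir, seed)
    return(invisible(res))
  }
  switch(stage,
    "simulate-data" = stage_simulate(config, out_dir, seed),
    "evi" = stage_evi(config, out_dir, seed),
    "texture" = stage_texture(config, out_dir, seed),
    "features" = stage_features(config, out_dir, seed),
    "train" = stage_train(config, out_dir, seed),
    "assess" = stage_assess(config, out_dir, seed),
    "acd" = stage_acd(config, out_dir, seed),
    "montecarlo" = stage_montecarlo(config, out_dir, seed),
    stop("unknown stage '", stage, "'; stages: ",
         paste(c(pipeline_stages(), "full-run"), collapse = ", ")))
}

stage_simulate <- function(config, out_dir, seed) {
  sites <- make_multisite_fixture(seed = seed,
                                  extent_px = config$extent_px,
                                  glcm_window = config$glcm$window)
  outputs <- character(0)
  meta <- list()
  for (land in sites) {
    id <- land$config$site_id
    fs <- c(evi = file.path(out_dir, sprintf("evi_%s.asc", id)),
            cls = file.path(out_dir, sprintf("class_%s.asc", id)),
            yr = file.path(out_dir, sprintf("year_%s.asc", id)),
            acd = file.path(out_dir, sprintf("acd50_%s.asc", id)),
            pol = file.path(out_dir, sprintf("polygons_%s.geojson", id)))
    write_raster_asc(land$evi, fs[["evi"]])
    write_raster_asc(land$class_map, fs[["cls"]])
    write_raster_asc(land$year_map, fs[["yr"]])
    write_raster_asc(land$acd_plots, fs[["acd"]])
    write_polygons_geojson(land$polygons, fs[["pol"]])
    outputs <- c(outputs, fs)
    meta[[id]] <- list(image_year = land$config$image_year)
  }
  record_stage(out_dir, "simulate-data", config, seed, outputs,
               list(sites = meta))
  invisible(list(sites = sites))
}

stage_evi <- function(config, out_dir, seed) {
  ids <- site_ids_from(out_dir, "^blue_(.+)\\.asc$")
  if (!length(ids))
    stop("missing input artifact(s) blue_<site>.asc/red_<site>.asc/",
         "nir_<site>.asc; provide band rasters or run stage ",
         "'simulate-data' first (it emits EVI directly)")
  outputs <- character(0)
  for (id in ids) {
    require_inputs(out_dir, sprintf(c("red_%s.asc", "nir_%s.asc"), id),
                   "import")
    evi <- compute_evi(
      read_raster_asc(file.path(out_dir, sprintf("blue_%s.asc", id))),
      read_raster_asc(file.path(out_dir, sprintf("red_%s.asc", id))),
      read_raster_asc(file.path(out_dir, sprintf("nir_%s.asc", id))))
    f <- file.path(out_dir, sprintf("evi_%s.asc", id))
    write_raster_asc(evi, f)
    outputs <- c(outputs, f)
  }
  record_stage(out_dir, "evi", config, seed, outputs)
  invisible(list(sites = ids))
}

stage_texture <- function(config, out_dir, seed) {
  ids <- site_ids_from(out_dir, "^evi_(.+)\\.asc$")
  if (!length(ids))
    stop("missing input artifact(s) evi_<site>.asc; run stage ",
         "'simulate-data' (or 'evi') first")
  gc_cfg <- glcm_config(window = config$glcm$window,
                        levels = config$glcm$levels)
  outputs <- character(0)
  for (id in ids) {
    evi <- read_raster_asc(file.path(out_dir, sprintf("evi_%s.asc", id)))
    bands <- windowed_glcm(evi, gc_cfg)
    for (bn in names(bands)) {
      f <- file.path(out_dir, sprintf("glcm_%s_%s.asc", id, bn))
      write_raster_asc(bands[[bn]], f)
      outputs <- c(outputs, f)
    }
  }
  record_stage(out_dir, "texture", config, seed, outputs)
  invisible(list(sites = ids))
}

stage_features <- function(config, out_dir, seed) {
  ids <- site_ids_from(out_dir, "^glcm_(.+)_entropy\\.asc$")
  if (!length(ids))
    stop("missing input artifact(s) glcm_<site>_<metric>.asc; run stage ",
         "'texture' first")
  man <- read_manifest(out_dir)
  tabs <- list()
  for (id in ids) {
    require_inputs(out_dir, sprintf(c("class_%s.asc", "year_%s.asc"), id),
                   "simulate-data")
    bands <- lapply(glcm_metric_names(), function(bn)
      read_raster_asc(file.path(out_dir,
                                sprintf("glcm_%s_%s.asc", id, bn))))
    names(bands) <- glcm_metric_names()
    cls <- read_raster_asc(file.path(out_dir, sprintf("class_%s.asc", id)))
    yr <- read_raster_asc(file.path(out_dir, sprintf("year_%s.asc", id)))
    tab <- build_feature_table(id, bands, cls, yr,
                               cell_px = config$cell_px)
    iy <- man$stages[["simulate-data"]]$sites[[id]]$image_year
    if (is.null(iy))
      stop("image year for site ", id, " not found in the manifest; ",
           "run stage 'simulate-data' first")
    tabs[[id]] <- filter_recent(tab, iy, config$max_age_years)
  }
  cells <- do.call(rbind, tabs)
  cells <- standardize_per_site(cells)
  f <- file.path(out_dir, "features.csv")
  utils::write.csv(cells, f, row.names = FALSE)
  record_stage(out_dir, "features", config, seed, f)
  invisible(list(cells = cells))
}

stage_train <- function(config, out_dir, seed) {
  require_inputs(out_dir, "features.csv", "features")
  cells <- utils::read.csv(file.path(out_dir, "features.csv"))
  spec <- training_spec(n_partitions = config$training$n_partitions,
                        seed = seed)
  ens <- fit_ensemble(cells, spec)
  f_acc <- file.path(out_dir, "accuracies.csv")
  f_prob <- file.path(out_dir, "probs.csv")
  utils::write.csv(data.frame(partition =
                                seq_along(ens$accuracies),
                              accuracy = ens$accuracies),
                   f_acc, row.names = FALSE)
  utils::write.csv(ens$probs, f_prob, row.names = FALSE)
  record_stage(out_dir, "train", config, seed, c(f_acc, f_prob),
               list(accuracy = list(mean = unname(ens$summary["mean"]),
                                    sd = unname(ens$summary["sd"]))))
  invisible(list(ensemble = ens))
}

stage_assess <- function(config, out_dir, seed) {
  require_inputs(out_dir, "probs.csv", "train")
  probs <- utils::read.csv(file.path(out_dir, "probs.csv"))
  cm <- confusion_matrix(hard_class(as.matrix(probs[, DCLASSES])),
                         probs$ref_class)
  f_cm <- file.path(out_dir, "confusion.csv")
  f_rep <- file.path(out_dir, "accuracy_report.txt")
  utils::write.csv(as.data.frame(unclass(cm)), f_cm)
  lines <- utils::capture.output(accuracy_report(cm))
  writeLines(lines, f_rep)
  record_stage(out_dir, "assess", config, seed, c(f_cm, f_rep))
  invisible(list(confusion = cm, metrics = accuracy_metrics(cm)))
}

stage_acd <- function(config, out_dir, seed) {
  ids <- site_ids_from(out_dir, "^acd50_(.+)\\.asc$")
  if (!length(ids))
    stop("missing input artifact(s) acd50_<site>.asc; run stage ",
         "'simulate-data' first")
  per_site <- lapply(ids, function(id) {
    acd50 <- read_raster_asc(file.path(out_dir,
                                       sprintf("acd50_%s.asc", id)))
    cls <- read_raster_asc(file.path(out_dir, sprintf("class_%s.asc", id)))
    acd500 <- resample_acd(acd50, config$acd$resample_factor)
    plot_px <- max(1L, round(config$acd$plot_m / cls$pixel_size))
    cls500 <- block_majority(cls, plot_px * config$acd$resample_factor)
    build_distributions(acd500, cls500, id)
  })
  dists <- apply_substitution(combine_distributions(per_site))
  f_d <- file.path(out_dir, "acd_distributions.csv")
  f_s <- file.path(out_dir, "acd_summary.csv")
  utils::write.csv(as.data.frame(dists), f_d, row.names = FALSE)
  utils::write.csv(summarize_distributions(dists), f_s, row.names = FALSE)
  subs <- attr(dists, "substitutions")
  record_stage(out_dir, "acd", config, seed, c(f_d, f_s),
               list(substitutions = if (is.null(subs)) list()
                    else subs))
  invisible(list(dists = dists))
}

stage_montecarlo <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("probs.csv", "acd_distributions.csv"),
                 "train / acd")
  probs <- utils::read.csv(file.path(out_dir, "probs.csv"))
  dists <- utils::read.csv(file.path(out_dir, "acd_distributions.csv"))
  n_iter <- config$montecarlo$n_iter
  sim_a <- simulate_acd(probs, dists, "acd_only", n_iter, seed)
  sim_b <- simulate_acd(probs, dists, "acd_plus_class", n_iter, seed + 1L)
  cmp <- compare_simulations(sim_a, sim_b)
  f_sum <- file.path(out_dir, "mc_summary.csv")
  f_cmp <- file.path(out_dir, "mc_comparison.csv")
  f_it <- file.path(out_dir, "mc_iterations.csv")
  utils::write.csv(rbind(summary(sim_a), summary(sim_b)), f_sum,
                   row.names = FALSE)
  utils::write.csv(cmp, f_cmp, row.names = FALSE)
  its <- do.call(rbind, lapply(list(sim_a, sim_b), function(s)
    do.call(rbind, lapply(s$sites, function(x)
      data.frame(site_id = x$site_id, mode = s$mode,
                 iteration = seq_along(x$iterations),
                 mean_acd = x$iterations)))))
  utils::write.csv(its, f_it, row.names = FALSE)
  record_stage(out_dir, "montecarlo", config, seed,
               c(f_sum, f_cmp, f_it))
  invisible(list(acd_only = sim_a, acd_plus_class = sim_b,
                 comparison = cmp))
}
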