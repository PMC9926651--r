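## Shared fixtures, built in code at test time.

## small three-class landscape (480 px, 80-px patch quantum) for module
## tests; the full-size three-site fixture is only built where a test
## needs the whole pipeline
mini_landscape <- function(seed = 42L,
                           frac = c(intact = 0.5, logged = 0.3,
                                    burned = 0.2)) {
  cfg <- site_config("mini", extent = c(480L, 480L), image_year = 2018L,
                     class_fraction = frac, seed = seed)
  generate_landscape(cfg, glcm_window = 9L, patch_quantum_px = 80L,
                     polys_per_band = 2L)
}

## well-separated three-class feature table for classifier tests:
## class means 4 SD apart on 5 features, unit noise
separable_cells <- function(n_per_class = 100L, seed = 7L,
                            n_features = 5L) {
  set.seed(seed)
  classes <- c("intact", "logged", "burned")
  centers <- matrix(c(0, 4, 8), 3L, n_features)
  rows <- lapply(seq_along(classes), function(k) {
    x <- matrix(stats::rnorm(n_per_class * n_features,
                             mean = centers[k, 1L]),
                n_per_class, n_features)
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(n_features))
    df$site_id <- "siteA"
    df$cell_row <- (k - 1L) * n_per_class + seq_len(n_per_class)
    df$cell_col <- 1L
    df$ref_class <- classes[k]
    df$purity <- stats::runif(n_per_class, 0.55, 1)
    df
  })
  do.call(rbind, rows)
}

## memoized full three-site pipeline run shared by the acceptance tests
.pipeline_cache <- new.env(parent = emptyenv())
full_pipeline_run <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    out_dir <- file.path(tempdir(), paste0("degratex-accept-", seed))
    cfg <- default_run_config(scaled = TRUE, seed = seed)
    .pipeline_cache[[key]] <- run_stage("full-run", cfg,
                                        out_dir = out_dir, seed = seed)
  }
  .pipeline_cache[[key]]
}
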