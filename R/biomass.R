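#' Block-median resampling of plot ACD
#'
#' Aggregates the 50 m plot-level aboveground carbon density raster to
#' 500 m (25 ha) cells, each output value the median of its
#' `factor x factor` unmasked plot values; cells with fewer than 50%
#' valid plots become nodata.
#'
#' @param plot_raster ACD raster at plot resolution (`dgx_raster`).
#' @param factor resampling factor (default 10, 50 m -> 500 m).
#' @param min_valid_frac minimum valid-plot fraction per cell.
#' @return `dgx_raster` at the coarse resolution.
#' @export
resample_acd <- function(plot_raster, factor = 10L, min_valid_frac = 0.5) {
  stopifnot(is_raster(plot_raster), factor >= 1L)
  block_stat(plot_raster, factor, stats::median,
             min_valid_frac = min_valid_frac)
}

#' Site-by-class empirical ACD distributions
#'
#' Pools the resampled 500 m ACD values by degradation class (no
#' distinction by time since disturbance).  Classes present in the class
#' map but without any valid ACD cell yield empty distributions flagged
#' for substitution rather than being dropped.
#'
#' @param resampled 500 m ACD raster for one site.
#' @param class_map class raster aligned to the same 500 m grid
#'   (0 intact, 1 logged, 2 burned), e.g. from majority aggregation.
#' @param site_id site label.
#' @param classes classes to report (default all three).
#' @return data frame of class `acd_distributions` with one row per
#'   site-class value; empty classes appear with `NA` values and
#'   `needs_substitution = TRUE` attribute rows tracked in
#'   `attr(, "empty")`.
#' @export
build_distributions <- function(resampled, class_map, site_id,
                                classes = DCLASSES) {
  stopifnot(is_raster(resampled), is_raster(class_map))
  stopifnot_same_grid(resampled, class_map)
  cls <- class_map$values
  acd <- resampled$values
  out <- list()
  empty <- character(0)
  for (k in seq_along(classes)) {
    code <- match(classes[k], DCLASSES) - 1L
    vals <- acd[!is.na(cls) & cls == code & !is.na(acd)]
    if (length(vals) == 0L) {  # class absent or without valid carbon data
      empty <- c(empty, classes[k])
      next
    }
    out[[length(out) + 1L]] <- data.frame(site_id = site_id,
                                          dclass = classes[k],
                                          acd = vals)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(site_id = character(0), dclass = character(0),
                         acd = numeric(0))
  ## classes with reference presence at the site but no carbon data are
  ## flagged, not silently dropped
  attr(res, "empty") <- if (length(empty))
    data.frame(site_id = site_id, dclass = empty) else NULL
  class(res) <- c("acd_distributions", "data.frame")
  res
}

#' Combine per-site distribution tables
#'
#' @param ... `acd_distributions` objects (or a single list of them).
#' @return one `acd_distributions` table; the empty-class flags are
#'   concatenated.
#' @export
combine_distributions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "data.frame"))
    parts <- parts[[1L]]
  res <- do.call(rbind, lapply(parts, as.data.frame))
  empties <- do.call(rbind, lapply(parts, attr, "empty"))
  attr(res, "empty") <- empties
  class(res) <- c("acd_distributions", "data.frame")
  res
}

#' Fill empty site-class distributions from donor sites
#'
#' A site can lack local carbon data for a class that its classification
#' can still predict (e.g. no burned forest was overflown at one site).
#' Each flagged empty site-class pair is filled with the pooled values of
#' the same class from the donor sites; every substitution is recorded in
#' the `substitutions` attribute for the run manifest.
#'
#' @param dists an `acd_distributions` table with an `empty` attribute.
#' @param donors optional character vector restricting donor sites
#'   (default: all other sites with data for the class).
#' @return the completed table; `attr(, "substitutions")` lists what was
#'   filled from where.
#' @export
apply_substitution <- function(dists, donors = NULL) {
  empty <- attr(dists, "empty")
  if (is.null(empty) || nrow(empty) == 0L) {
    attr(dists, "substitutions") <- NULL
    return(dists)
  }
  subs <- list()
  for (i in seq_len(nrow(empty))) {
    site <- empty$site_id[i]; cl <- empty$dclass[i]
    pool <- dists[dists$dclass == cl & dists$site_id != site, ]
    if (!is.null(donors)) pool <- pool[pool$site_id %in% donors, ]
    if (nrow(pool) == 0L)
      stop("no donor distribution available for class '", cl,
           "' at site ", site)
    add <- data.frame(site_id = site, dclass = cl, acd = pool$acd)
    dists <- rbind(dists, add)
    subs[[length(subs) + 1L]] <-
      data.frame(site_id = site, dclass = cl,
                 donors = paste(sort(unique(pool$site_id)),
                                collapse = "+"),
                 n_values = nrow(pool))
  }
  attr(dists, "empty") <- NULL
  attr(dists, "substitutions") <- do.call(rbind, subs)
  class(dists) <- c("acd_distributions", "data.frame")
  dists
}

#' Summarize ACD distributions
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' site-class pair, in Mg C ha^-1.  With `pool_sites`, the named sites
#' are reported together as one unit (they remain separate for
#' simulation).
#'
#' @param dists an `acd_distributions` table.
#' @param pool_sites optional character vector of sites to pool into one
#'   reporting row (labelled by joining the names with "+").
#' @return data frame with `site_id`, `dclass`, `n`, `mean`, `sd`.
#' @export
summarize_distributions <- function(dists, pool_sites = NULL) {
  d <- as.data.frame(dists)
  if (!is.null(pool_sites)) {
    lab <- paste(sort(pool_sites), collapse = "+")
    d$site_id[d$site_id %in% pool_sites] <- lab
  }
  agg <- do.call(rbind, lapply(split(d, list(d$site_id, d$dclass),
                                     drop = TRUE), function(g)
    data.frame(site_id = g$site_id[1L], dclass = g$dclass[1L],
               n = nrow(g), mean = mean(g$acd),
               sd = if (nrow(g) > 1L) stats::sd(g$acd) else NA_real_)))
  rownames(agg) <- NULL
  agg[order(agg$site_id, match(agg$dclass, DCLASSES)), , drop = FALSE]
}

#' Percent ACD change of a degraded class relative to intact forest
#'
#' @param intact_mean mean ACD of intact forest (Mg C ha^-1, > 0).
#' @param other_mean mean ACD of the degraded class.
#' @return percent change, `100 * (other - intact) / intact`; negative
#'   for carbon losses.
#' @export
percent_change <- function(intact_mean, other_mean) {
  if (any(intact_mean == 0)) stop("intact mean ACD is zero")
  100 * (other_mean - intact_mean) / intact_mean
}
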