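#' Aggregation statistics for texture bands
#'
#' The nine per-cell resampling statistics applied to each texture band:
#' average, standard deviation, skewness, root mean square, minimum,
#' first quartile, median, third quartile and maximum.  Quantiles use
#' linear interpolation between order statistics; skewness is the
#' population-moment ratio m3 / m2^(3/2), defined as 0 when m2 = 0.
#'
#' @return named list of statistic functions.
#' @export
aggregation_statistics <- function() {
  skew <- function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 == 0) return(0)
    mean((x - mean(x))^3) / m2^1.5
  }
  list(avg = mean,
       sd = function(x) if (length(x) > 1L) stats::sd(x) else 0,
       skew = skew,
       rms = function(x) sqrt(mean(x^2)),
       min = min,
       q1 = function(x) unname(stats::quantile(x, 0.25, type = 7)),
       median = stats::median,
       q3 = function(x) unname(stats::quantile(x, 0.75, type = 7)),
       max = max)
}

#' Aggregate texture bands to the classification grid
#'
#' Computes the nine aggregation statistics of every texture band over
#' each grid cell of `cell_px` x `cell_px` pixels (default 180 px =
#' 562.5 m at 3.125 m pixels), giving 72 features per cell for the
#' default eight bands.  Cells with fewer than 50% unmasked pixels in a
#' band are dropped.
#'
#' @param bands named list of aligned `dgx_raster` texture bands.
#' @param cell_px grid cell edge in pixels (>= 2).
#' @param statistics named list of statistic functions, see
#'   [aggregation_statistics()].
#' @return data frame with `cell_row`, `cell_col` and one
#'   `<band>_<statistic>` column per combination; complete cells only.
#' @export
aggregate_features <- function(bands, cell_px = 180L,
                               statistics = aggregation_statistics()) {
  if (length(statistics) == 0L) stop("`statistics` must be nonempty")
  if (cell_px < 2L) stop("`cell_px` must be >= 2")
  stopifnot(length(bands) >= 1L)
  do.call(stopifnot_same_grid, unname(bands))
  cols <- list()
  for (bn in names(bands)) {
    for (sn in names(statistics)) {
      agg <- block_stat(bands[[bn]], cell_px, statistics[[sn]],
                        min_valid_frac = 0.5)
      cols[[paste(bn, sn, sep = "_")]] <- agg$values
    }
  }
  nbr <- nrow(cols[[1L]]); nbc <- ncol(cols[[1L]])
  df <- data.frame(cell_row = rep(seq_len(nbr), times = nbc),
                   cell_col = rep(seq_len(nbc), each = nbr))
  for (nm in names(cols)) df[[nm]] <- as.vector(cols[[nm]])
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Dominant reference class and purity per grid cell
#'
#' Purity is the fraction of a cell's unmasked pixels occupied by its
#' dominant class; 50/50 ties are resolved by the fixed priority
#' burned > logged > intact.  Fully masked cells are dropped.
#'
#' @param class_map class raster (0 intact, 1 logged, 2 burned).
#' @param year_map optional raster of disturbance years; the cell's event
#'   year is the most recent year among pixels of the dominant class.
#' @param cell_px grid cell edge in pixels.
#' @return data frame with `cell_row`, `cell_col`, `ref_class`, `purity`
#'   and (if `year_map` given) `event_year` (`NA` for intact cells).
#' @export
compute_purity <- function(class_map, cell_px = 180L, year_map = NULL) {
  stopifnot(is_raster(class_map))
  if (!is.null(year_map)) stopifnot_same_grid(class_map, year_map)
  v <- class_map$values
  nbr <- nrow(v) %/% cell_px; nbc <- ncol(v) %/% cell_px
  if (nbr < 1L || nbc < 1L)
    stop("class map smaller than one ", cell_px, "-px cell")
  cls_names <- c("intact", "logged", "burned")
  rows <- list()
  for (i in seq_len(nbr)) {
    ri <- ((i - 1L) * cell_px + 1L):(i * cell_px)
    for (j in seq_len(nbc)) {
      ci <- ((j - 1L) * cell_px + 1L):(j * cell_px)
      blk <- v[ri, ci]
      yblk <- if (!is.null(year_map)) year_map$values[ri, ci]
      ok <- !is.na(blk)
      if (!any(ok)) next
      counts <- vapply(0:2, function(k) sum(blk[ok] == k), 0L)
      dom <- max(which(counts == max(counts)))  # burned > logged > intact
      rec <- data.frame(cell_row = i, cell_col = j,
                        ref_class = cls_names[dom],
                        purity = counts[dom] / sum(ok))
      if (!is.null(year_map)) {
        ys <- yblk[ok & blk == (dom - 1L)]
        rec$event_year <- if (all(is.na(ys))) NA_integer_
                          else as.integer(max(ys, na.rm = TRUE))
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (!length(rows)) stop("no unmasked cells")
  do.call(rbind, rows)
}

#' Drop training cells with old disturbances
#'
#' The canopy signal of logging and fire fades within a few years;
#' disturbed cells whose event is more than five years older than the
#' image are removed from model training.  The boundary is inclusive
#' (exactly five years old is retained) and intact cells always pass.
#'
#' @param cells data frame with `ref_class` and `event_year`.
#' @param image_year calendar year of the classified image.
#' @param max_age_years age cutoff (default 5).
#' @return the filtered data frame.
#' @export
filter_recent <- function(cells, image_year, max_age_years = 5L) {
  disturbed <- cells$ref_class != "intact"
  age <- image_year - cells$event_year
  drop <- disturbed & !is.na(age) & age > max_age_years
  cells[!drop, , drop = FALSE]
}

#' Center and scale features within each site
#'
#' Each feature column is standardized to mean 0, SD 1 using all cells of
#' a site (train and test alike, matching how the multi-site feature
#' table is assembled before partitioning; the mild train/test leakage
#' this implies is documented in the methods vignette).  Zero-variance
#' features become all zeros.
#'
#' @param cells data frame with a `site_id` column and feature columns.
#' @param feature_cols character vector of feature column names (default:
#'   every numeric column except identifiers/labels).
#' @return `cells` with standardized feature columns.
#' @export
standardize_per_site <- function(cells, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(cells)
  for (site in unique(cells$site_id)) {
    idx <- cells$site_id == site
    if (sum(idx) < 2L)
      stop("site ", site, " has fewer than 2 cells; cannot standardize")
    for (fc in feature_cols) {
      x <- cells[[fc]][idx]
      s <- stats::sd(x)
      cells[[fc]][idx] <- if (s > 0) (x - mean(x)) / s else 0
    }
  }
  cells
}

feature_columns <- function(cells) {
  meta <- c("site_id", "cell_row", "cell_col", "ref_class", "purity",
            "event_year", "weight")
  setdiff(names(cells)[vapply(cells, is.numeric, TRUE)], meta)
}

#' Build the per-site classification feature table
#'
#' Runs texture aggregation and reference labelling on one generated (or
#' loaded) site: aggregates the texture bands to the classification grid,
#' attaches the dominant class, purity and event year per cell, and joins
#' them on cell indices.
#'
#' @param site_id site label.
#' @param bands named list of texture band rasters.
#' @param class_map,year_map reference rasters at native resolution.
#' @param cell_px grid cell edge in pixels.
#' @return data frame of grid-cell records (one row per complete cell).
#' @export
build_feature_table <- function(site_id, bands, class_map, year_map = NULL,
                                cell_px = 180L) {
  feats <- aggregate_features(bands, cell_px = cell_px)
  labs <- compute_purity(class_map, cell_px = cell_px, year_map = year_map)
  out <- merge(labs, feats, by = c("cell_row", "cell_col"))
  out <- cbind(site_id = site_id, out)
  out[order(out$cell_row, out$cell_col), , drop = FALSE]
}
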