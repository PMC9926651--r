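#' Default per-class canopy texture parameters
#'
#' Controls the synthetic EVI texture: intact canopy is a smooth spatially
#' correlated random field; logged forest adds linear low-EVI roads with
#' log-storage decks at their crossings; burned forest is darkened
#' diffusely and speckled with fine-grained variance.  Units are EVI
#' (unitless) and pixels.
#'
#' @param base_evi mean canopy EVI of intact forest.
#' @param corr_length_px Gaussian correlation length (sigma) of the canopy
#'   field, in pixels.
#' @param noise_sd standard deviation of the correlated canopy field.
#' @param road_spacing_px spacing between parallel logging roads.
#' @param road_width_px road width.
#' @param road_depth EVI drop on roads and decks.
#' @param deck_size_px edge length of square log decks at road crossings.
#' @param burn_depth mean EVI drop in burned forest.
#' @param burn_speckle_sd extra white-noise SD added in burned forest.
#' @return a named list of texture parameters.
#' @export
texture_params <- function(base_evi = 0.55, corr_length_px = 8,
                           noise_sd = 0.04, road_spacing_px = 40,
                           road_width_px = 2, road_depth = 0.25,
                           deck_size_px = 6, burn_depth = 0.15,
                           burn_speckle_sd = 0.06) {
  list(base_evi = base_evi, corr_length_px = corr_length_px,
       noise_sd = noise_sd, road_spacing_px = road_spacing_px,
       road_width_px = road_width_px, road_depth = road_depth,
       deck_size_px = deck_size_px, burn_depth = burn_depth,
       burn_speckle_sd = burn_speckle_sd)
}

#' Class-conditional aboveground carbon density parameters
#'
#' (mean, sd) in Mg C ha^-1 per degradation class.  `acd_params_low()`
#' carries the low-biomass regime typical of southeastern Amazonian
#' transitional forests; `acd_params_high()` the high-biomass regime of
#' dense central Amazonian forest, where burned forest is absent and its
#' entry is `NULL`.
#'
#' @return named list with entries `intact`, `logged`, `burned`, each a
#'   numeric `(mean, sd)` vector or `NULL` when the class has no local
#'   carbon data.
#' @export
acd_params_low <- function() {
  list(intact = c(mean = 89.2, sd = 10.2),
       logged = c(mean = 93.9, sd = 16.3),
       burned = c(mean = 57.9, sd = 35.0))
}

#' @rdname acd_params_low
#' @export
acd_params_high <- function() {
  list(intact = c(mean = 185.3, sd = 31.9),
       logged = c(mean = 156.8, sd = 26.0),
       burned = NULL)
}

#' Configuration of one synthetic site
#'
#' @param site_id site label.
#' @param extent `(rows, cols)` of the image in pixels.
#' @param pixel_size pixel edge in metres (default 3.125).
#' @param image_year calendar year of image acquisition.
#' @param class_fraction named proportions over intact/logged/burned;
#'   non-negative, summing to 1.
#' @param texture per-class texture parameters, see [texture_params()].
#' @param acd per-class ACD `(mean, sd)`, see [acd_params_low()].
#' @param seed integer seed; every stochastic draw for the site descends
#'   from it.
#' @return an object of class `site_config`.
#' @export
site_config <- function(site_id, extent = c(960L, 960L), pixel_size = 3.125,
                        image_year = 2018L,
                        class_fraction = c(intact = 0.5, logged = 0.3,
                                           burned = 0.2),
                        texture = texture_params(), acd = acd_params_low(),
                        seed = 1L) {
  cls <- c("intact", "logged", "burned")
  if (!all(cls %in% names(class_fraction)))
    stop("`class_fraction` must be named over intact, logged, burned")
  class_fraction <- class_fraction[cls]
  if (any(class_fraction < 0) || abs(sum(class_fraction) - 1) > 1e-8)
    stop("`class_fraction` entries must be >= 0 and sum to 1")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  for (cl in cls) {
    p <- acd[[cl]]
    if (!is.null(p) && (length(p) < 2L || p[["sd"]] < 0))
      stop("acd parameters for class ", cl, " need (mean, sd) with sd >= 0")
  }
  structure(list(site_id = site_id, extent = as.integer(extent),
                 pixel_size = pixel_size, image_year = as.integer(image_year),
                 class_fraction = class_fraction, texture = texture,
                 acd = acd, seed = as.integer(seed)),
            class = "site_config")
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("<site_config> %s: %d x %d px @ %.4g m, image year %d\n",
              x$site_id, x$extent[1L], x$extent[2L], x$pixel_size,
              x$image_year))
  cat("  class fractions:",
      paste(sprintf("%s %.2f", names(x$class_fraction), x$class_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

## circular FFT convolution with a separable Gaussian kernel; gives the
## spatially correlated canopy field (wrap-around is irrelevant for
## synthetic texture)
gaussian_field <- function(nr, nc, sigma, sd) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0 || sd <= 0) return(z * sd)
  g1 <- function(n) {
    d <- pmin(0:(n - 1L), n - (0:(n - 1L)))
    k <- exp(-0.5 * (d / sigma)^2)
    k / sum(k)
  }
  kern <- outer(g1(nr), g1(nc))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  sm * (sd / stats::sd(as.vector(sm)))
}

## contiguous column bands intact | logged | burned with widths from the
## class fractions, snapped to multiples of `quantum_px`
band_layout <- function(nc, frac, quantum_px) {
  q <- max(1L, as.integer(quantum_px))
  nq <- nc %/% q
  qs <- round(frac[c("logged", "burned")] * nq)
  for (cl in c("logged", "burned"))  # never round an ordered class away
    if (frac[[cl]] > 0 && qs[[cl]] == 0) qs[[cl]] <- 1
  if (sum(qs) > nq) qs <- pmax(0, qs - (sum(qs) - nq))
  w_logged <- qs[["logged"]] * q
  w_burned <- qs[["burned"]] * q
  list(intact = c(1L, nc - w_logged - w_burned),
       logged = if (w_logged > 0)
         c(nc - w_logged - w_burned + 1L, nc - w_burned) else NULL,
       burned = if (w_burned > 0) c(nc - w_burned + 1L, nc) else NULL)
}

rect_ring <- function(col0, col1, row0, row1) {
  ## pixel-index rectangle [col0,col1] x [row0,row1] (1-based, inclusive)
  ## as a ring in 0-based continuous coordinates
  rbind(c(col0 - 1, row0 - 1), c(col1, row0 - 1),
        c(col1, row1), c(col0 - 1, row1), c(col0 - 1, row0 - 1))
}

#' Generate one synthetic degraded-forest landscape
#'
#' Builds an EVI image with class-specific canopy texture, the matching
#' class and disturbance-year maps, and the reference polygons that
#' rasterize back to the class map exactly.  Disturbed classes occupy
#' contiguous column bands (widths set by the class fractions, snapped to
#' `patch_quantum_px`); each band is split into `polys_per_band` event
#' polygons whose years are drawn uniformly from
#' `[image_year - 8, image_year]` so that a 5-year disturbance-age filter
#' is exercised.
#'
#' @param config a [site_config()].
#' @param glcm_window texture window size the image must accommodate;
#'   extents smaller than one window are rejected.
#' @param patch_quantum_px band edges are snapped to multiples of this
#'   (default 160 px = one 500 m carbon block).
#' @param polys_per_band number of event polygons per disturbed band.
#' @return list with `evi`, `class_map`, `year_map` rasters, the logical
#'   `road_mask` matrix (road and deck pixels), the `polygons` list, and
#'   the `config`.
#' @export
generate_landscape <- function(config, glcm_window = 45L,
                               patch_quantum_px = 160L,
                               polys_per_band = 4L) {
  stopifnot(inherits(config, "site_config"))
  nr <- config$extent[1L]; nc <- config$extent[2L]
  if (nr < glcm_window || nc < glcm_window)
    stop("site extent ", nr, "x", nc, " px is smaller than one GLCM ",
         "window (", glcm_window, " px); enlarge the extent or shrink ",
         "the window")
  tp <- config$texture
  set.seed(config$seed)

  bands <- band_layout(nc, config$class_fraction, patch_quantum_px)

  ## reference polygons: each disturbed band split along rows
  polygons <- list()
  for (cl in c("logged", "burned")) {
    b <- bands[[cl]]
    if (is.null(b)) next
    cuts <- unique(round(seq(0L, nr, length.out = polys_per_band + 1L)))
    for (k in seq_len(length(cuts) - 1L)) {
      yr <- config$image_year - sample.int(9L, 1L) + 1L  # uniform on [iy-8, iy]
      polygons[[length(polygons) + 1L]] <-
        ref_polygon(rect_ring(b[1L], b[2L], cuts[k] + 1L, cuts[k + 1L]),
                    cl, yr)
    }
  }

  template <- dgx_raster(matrix(0, nr, nc), config$pixel_size)
  maps <- rasterize_polygons(polygons, template)
  cls <- maps$class_map$values

  ## canopy EVI: correlated field everywhere, then class overlays
  evi <- tp$base_evi + gaussian_field(nr, nc, tp$corr_length_px, tp$noise_sd)

  road_mask <- matrix(FALSE, nr, nc)
  if (!is.null(bands$logged)) {
    b <- bands$logged
    cols <- b[1L]:b[2L]
    road <- matrix(FALSE, nr, length(cols))
    seq_or_empty <- function(from, to, by)
      if (from <= to) seq(from, to, by = by) else integer(0)
    vpos <- seq_or_empty(tp$road_spacing_px %/% 2L, length(cols),
                         tp$road_spacing_px)
    hpos <- seq_or_empty(tp$road_spacing_px, nr, 2L * tp$road_spacing_px)
    half_w <- (tp$road_width_px - 1L) %/% 2L
    for (v in vpos)
      road[, pmax(1L, v - half_w):pmin(length(cols), v + half_w)] <- TRUE
    for (h in hpos)
      road[pmax(1L, h - half_w):pmin(nr, h + half_w), ] <- TRUE
    half_d <- tp$deck_size_px %/% 2L
    for (v in vpos) for (h in hpos)
      road[pmax(1L, h - half_d):pmin(nr, h + half_d),
           pmax(1L, v - half_d):pmin(length(cols), v + half_d)] <- TRUE
    evi[, cols][road] <- evi[, cols][road] - tp$road_depth
    road_mask[, cols] <- road
  }

  if (!is.null(bands$burned)) {
    b <- bands$burned
    cols <- b[1L]:b[2L]
    speckle <- matrix(stats::rnorm(nr * length(cols), 0, tp$burn_speckle_sd),
                      nr, length(cols))
    evi[, cols] <- evi[, cols] - tp$burn_depth + speckle
  }

  evi <- pmax(pmin(evi, 1), -1)  # matrix first so dim attributes survive
  list(evi = dgx_raster(evi, config$pixel_size),
       class_map = dgx_raster(cls, config$pixel_size),
       year_map = maps$year_map,
       road_mask = road_mask,
       polygons = polygons,
       config = config)
}

## truncated-at-zero normal by rejection (resample negative draws)
rtruncnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Draw plot-level ACD over a synthetic landscape
#'
#' Aggregates the class map to the 50 m plot grid (majority class) and
#' draws each plot's aboveground carbon density from the class's
#' `(mean, sd)` normal distribution truncated at zero, in Mg C ha^-1.
#'
#' @param config a [site_config()]; `config$acd` supplies per-class
#'   parameters and `config$seed + 1` seeds the draws.
#' @param class_map class raster at native resolution (0 intact, 1 logged,
#'   2 burned).
#' @param plot_m plot edge length in metres (default 50).
#' @return a `dgx_raster` of ACD at plot resolution.
#' @export
generate_acd_plots <- function(config, class_map, plot_m = 50) {
  stopifnot(inherits(config, "site_config"), is_raster(class_map))
  plot_px <- max(1L, round(plot_m / class_map$pixel_size))
  plot_cls <- block_majority(class_map, plot_px)
  v <- plot_cls$values
  cls_names <- c("intact", "logged", "burned")
  present <- sort(unique(v[!is.na(v)]))
  set.seed(config$seed + 1L)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (code in present) {
    cl <- cls_names[code + 1L]
    p <- config$acd[[cl]]
    if (is.null(p) || anyNA(p))
      stop("acd parameters missing for class '", cl,
           "' present in the class map")
    idx <- which(v == code)
    out[idx] <- rtruncnorm0(length(idx), p[["mean"]], p[["sd"]])
  }
  dgx_raster(out, plot_cls$pixel_size, plot_cls$origin)
}

#' Three-site synthetic study fixture
#'
#' Reproduces the structure of a three-site field design: one mixed site
#' with logging and fire in a low-biomass forest, one burn-only site in
#' the same biomass regime, and one logging-only site in a high-biomass
#' regime with no local burned-forest carbon data (its burned ACD must be
#' substituted from the other sites downstream).
#'
#' @param seed integer master seed; site seeds are derived from it.
#' @param extent_px per-site square image size (default 960 px = 3 km).
#' @param glcm_window,patch_quantum_px passed to [generate_landscape()].
#' @return named list of three site bundles, each the result of
#'   [generate_landscape()] plus an `acd_plots` raster.
#' @export
make_multisite_fixture <- function(seed = 1L, extent_px = 960L,
                                   glcm_window = 11L,
                                   patch_quantum_px = 160L) {
  specs <- list(
    list(site_id = "feliz_natal", image_year = 2018L,
         frac = c(intact = 0.5, logged = 2 / 6, burned = 1 / 6),
         acd = acd_params_low()),
    list(site_id = "xingu", image_year = 2017L,
         frac = c(intact = 4 / 6, logged = 0, burned = 2 / 6),
         acd = acd_params_low()),
    list(site_id = "saraca", image_year = 2020L,
         frac = c(intact = 4 / 6, logged = 2 / 6, burned = 0),
         acd = acd_params_high()))
  sites <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    cfg <- site_config(s$site_id, extent = c(extent_px, extent_px),
                       image_year = s$image_year, class_fraction = s$frac,
                       acd = s$acd, seed = seed + 1000L * i)
    land <- generate_landscape(cfg, glcm_window = glcm_window,
                               patch_quantum_px = patch_quantum_px)
    land$acd_plots <- generate_acd_plots(cfg, land$class_map)
    land
  })
  names(sites) <- vapply(specs, `[[`, "", "site_id")
  sites
}
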