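#' Enhanced vegetation index from surface reflectance
#'
#' EVI = G * (NIR - Red) / (NIR + C1 * Red - C2 * Blue + L) per pixel,
#' with the standard coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1.
#' Inputs are reflectances on the 0-1 scale (a `scale` divisor converts
#' sensor-native integer encodings).  Nodata in any band propagates;
#' pixels whose denominator is <= 0 are set to nodata rather than
#' returning an unstable ratio.
#'
#' @param blue,red,nir aligned reflectance rasters (`dgx_raster`).
#' @param scale divisor applied to all bands before computation
#'   (default 1, i.e. inputs already 0-1).
#' @return EVI raster on the same grid; values typically in [-1, 1].
#' @export
compute_evi <- function(blue, red, nir, scale = 1) {
  stopifnot(is_raster(blue), is_raster(red), is_raster(nir))
  stopifnot_same_grid(blue, red, nir)
  b <- blue$values / scale
  r <- red$values / scale
  n <- nir$values / scale
  rng <- range(c(b, r, n), na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    warning(sprintf(paste0("reflectance values outside [0, 1] ",
                           "(range %.3g to %.3g); check the `scale` ",
                           "divisor"), rng[1L], rng[2L]))
  den <- n + 6 * r - 7.5 * b + 1
  evi <- 2.5 * (n - r) / den
  evi[!is.finite(evi) | den <= 0] <- NA_real_
  dgx_raster(evi, blue$pixel_size, blue$origin)
}
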