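#' GLCM texture configuration
#'
#' @param window odd moving-window edge in pixels (default 45, i.e.
#'   140.625 m at 3.125 m pixels).
#' @param levels number of gray levels for quantization (default 32).
#' @param offsets integer matrix of unit displacements (drow, dcol); the
#'   default covers the four directions 0, 45, 90 and 135 degrees, whose
#'   metric values are averaged so the texture is direction-free.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(window = 45L, levels = 32L,
                        offsets = rbind(c(0L, 1L), c(1L, 1L),
                                        c(1L, 0L), c(1L, -1L))) {
  window <- as.integer(window)
  levels <- as.integer(levels)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3")
  if (levels < 2L) stop("`levels` must be >= 2")
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  if (nrow(offsets) < 1L) stop("`offsets` must be nonempty")
  structure(list(window = window, levels = levels, offsets = offsets,
                 metrics = glcm_metric_names()),
            class = "glcm_config")
}

#' @rdname glcm_config
#' @export
glcm_metric_names <- function() {
  c("mean", "variance", "correlation", "contrast",
    "homogeneity", "dissimilarity", "asm", "entropy")
}

#' Quantize a raster to gray levels
#'
#' Equal-width bins between the raster's unmasked minimum and maximum;
#' the minimum maps to level 0 and the maximum to `levels - 1`.  A
#' constant raster quantizes to all zeros.
#'
#' @param r a `dgx_raster`.
#' @param levels number of gray levels.
#' @return a `dgx_raster` of integer codes in `0 .. levels - 1`.
#' @export
quantize <- function(r, levels = 32L) {
  stopifnot(is_raster(r), levels >= 2L)
  v <- r$values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot quantize an all-nodata raster")
  lo <- min(v[ok]); hi <- max(v[ok])
  q <- matrix(NA_real_, nrow(v), ncol(v))
  if (hi > lo) {
    idx <- floor((v[ok] - lo) / (hi - lo) * levels)
    idx[idx >= levels] <- levels - 1  # the maximum belongs to the top bin
    q[ok] <- idx
  } else {
    q[ok] <- 0
  }
  dgx_raster(q, r$pixel_size, r$origin)
}

#' Symmetric co-occurrence matrix of one window
#'
#' Tabulates how often pairs of gray levels co-occur at the given
#' displacement inside a window, counting each pair in both orders and
#' normalizing to sum 1.  Masked (`NA`) pixels are excluded from pairs.
#'
#' @param window integer matrix of gray-level codes (`NA` = masked).
#' @param offset integer `(drow, dcol)` displacement.
#' @param levels number of gray levels (default: `max(window) + 1`).
#' @return a `levels x levels` symmetric probability matrix.
#' @export
glcm_cooccurrence <- function(window, offset, levels = NULL) {
  window <- as.matrix(window)
  if (is.null(levels)) levels <- max(window, na.rm = TRUE) + 1L
  nr <- nrow(window); nc <- ncol(window)
  dr <- offset[1L]; dc <- offset[2L]
  P <- matrix(0, levels, levels)
  npair <- 0L
  for (i in seq_len(nr)) {
    i2 <- i + dr
    if (i2 < 1L || i2 > nr) next
    for (j in seq_len(nc)) {
      j2 <- j + dc
      if (j2 < 1L || j2 > nc) next
      a <- window[i, j]; b <- window[i2, j2]
      if (is.na(a) || is.na(b)) next
      P[a + 1L, b + 1L] <- P[a + 1L, b + 1L] + 1
      P[b + 1L, a + 1L] <- P[b + 1L, a + 1L] + 1
      npair <- npair + 1L
    }
  }
  if (npair == 0L)
    stop("no valid pixel pairs for offset (", dr, ", ", dc, ")")
  P / sum(P)
}

#' Haralick metrics of a co-occurrence matrix
#'
#' Returns the eight texture metrics, in fixed order: mean
#' \eqn{\sum_i i\,p_{i+}}, variance \eqn{\sum_i (i-\mu)^2 p_{i+}},
#' correlation \eqn{\sum_{ij}(i-\mu)(j-\mu)P_{ij}/\sigma^2} (0 when the
#' variance is 0), contrast \eqn{\sum_{ij}(i-j)^2P_{ij}}, homogeneity
#' \eqn{\sum_{ij}P_{ij}/(1+(i-j)^2)}, dissimilarity
#' \eqn{\sum_{ij}|i-j|P_{ij}}, angular second moment
#' \eqn{\sum_{ij}P_{ij}^2} and entropy \eqn{-\sum_{ij}P_{ij}\ln P_{ij}}
#' (natural log, with \eqn{0\ln 0 \equiv 0}).  Levels are indexed from 0.
#'
#' @param P symmetric co-occurrence probability matrix.
#' @return named numeric vector of the 8 metrics.
#' @export
glcm_metrics <- function(P) {
  P <- as.matrix(P)
  if (abs(sum(P) - 1) > 1e-8 || any(P < 0))
    stop("`P` must be a probability matrix summing to 1")
  lv <- seq_len(nrow(P)) - 1
  pi_marg <- rowSums(P)
  mu <- sum(lv * pi_marg)
  va <- sum((lv - mu)^2 * pi_marg)
  I <- matrix(lv, nrow(P), ncol(P))
  J <- t(I)
  corr <- if (va > 0) sum((I - mu) * (J - mu) * P) / va else 0
  pos <- P > 0
  c(mean = mu,
    variance = va,
    correlation = corr,
    contrast = sum((I - J)^2 * P),
    homogeneity = sum(P / (1 + (I - J)^2)),
    dissimilarity = sum(abs(I - J) * P),
    asm = sum(P^2),
    entropy = -sum(P[pos] * log(P[pos])))
}

#' Moving-window GLCM texture metrics
#'
#' Quantizes the raster, then computes the eight co-occurrence metrics in
#' a centered moving window around every pixel, per displacement, and
#' averages the metric values across displacements.  A border of one full
#' window width along each image edge is set to nodata, so edge windows
#' with insufficient context never contribute artifacts.
#'
#' @param r input raster (typically EVI).
#' @param config a [glcm_config()].
#' @return named list of eight `dgx_raster` bands, in the fixed order of
#'   [glcm_metric_names()].
#' @export
windowed_glcm <- function(r, config = glcm_config()) {
  stopifnot(is_raster(r), inherits(config, "glcm_config"))
  v <- r$values
  if (nrow(v) <= config$window || ncol(v) <= config$window)
    stop("raster (", nrow(v), "x", ncol(v), ") not larger than one ",
         config$window, "-px window")
  q <- quantize(r, config$levels)$values
  qi <- matrix(as.integer(q), nrow(q), ncol(q))
  arr <- glcm_texture_cpp(qi, config$window, config$levels, config$offsets)
  out <- lapply(seq_len(8L), function(k)
    dgx_raster(arr[, , k], r$pixel_size, r$origin))
  names(out) <- glcm_metric_names()
  out
}

#' Naive per-window texture evaluation (reference path)
#'
#' Direct R evaluation of the moving-window metrics from
#' [glcm_cooccurrence()] and [glcm_metrics()], used as the independent
#' reference for the fast path; orders of magnitude slower and intended
#' for small rasters only.
#'
#' @inheritParams windowed_glcm
#' @return same structure as [windowed_glcm()].
#' @export
windowed_glcm_naive <- function(r, config = glcm_config()) {
  stopifnot(is_raster(r), inherits(config, "glcm_config"))
  v <- quantize(r, config$levels)$values
  nr <- nrow(v); nc <- ncol(v)
  w <- config$window; half <- (w - 1L) %/% 2L
  out <- array(NA_real_, c(nr, nc, 8L))
  for (i in (w + 1L):(nr - w)) {
    for (j in (w + 1L):(nc - w)) {
      win <- v[(i - half):(i + half), (j - half):(j + half)]
      vals <- matrix(NA_real_, nrow(config$offsets), 8L)
      for (o in seq_len(nrow(config$offsets))) {
        P <- tryCatch(glcm_cooccurrence(win, config$offsets[o, ],
                                        config$levels),
                      error = function(e) NULL)
        if (!is.null(P)) vals[o, ] <- glcm_metrics(P)
      }
      if (any(!is.na(vals[, 1L])))
        out[i, j, ] <- colMeans(vals, na.rm = TRUE)
    }
  }
  res <- lapply(seq_len(8L), function(k)
    dgx_raster(out[, , k], r$pixel_size, r$origin))
  names(res) <- glcm_metric_names()
  res
}
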