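#' Lightweight in-memory raster
#'
#' A `dgx_raster` is a numeric matrix with a pixel size (metres) and a grid
#' origin, using `NA` for nodata.  All pipeline stages work in raster
#' row/col space (0-based, half-open windows); no map projection is
#' attached.  Row 1 is the top (north) row, matching on-disk raster order.
#'
#' @param values numeric matrix; `NA` entries are nodata.
#' @param pixel_size cell edge length in metres (default 3.125).
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @return an object of class `dgx_raster`.
#' @export
dgx_raster <- function(values, pixel_size = 3.125, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(values = values,
                 pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin)),
            class = "dgx_raster")
}

#' @export
print.dgx_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<dgx_raster> %d x %d px, %.4g m/px (%.4g x %.4g m)\n",
              nrow(v), ncol(v), x$pixel_size,
              nrow(v) * x$pixel_size, ncol(v) * x$pixel_size))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%.4g, %.4g], nodata: %d px (%.1f%%)\n",
                min(v[ok]), max(v[ok]), sum(!ok), 100 * mean(!ok)))
  else cat("  all nodata\n")
  invisible(x)
}

#' @export
as.matrix.dgx_raster <- function(x, ...) x$values

#' @export
dim.dgx_raster <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "dgx_raster")

as_raster <- function(x, template = NULL, pixel_size = 3.125) {
  if (is_raster(x)) return(x)
  if (is.matrix(x)) {
    if (!is.null(template))
      return(dgx_raster(x, template$pixel_size, template$origin))
    return(dgx_raster(x, pixel_size))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to dgx_raster")
}

#' Check that rasters share one grid
#'
#' @param ... two or more `dgx_raster` objects.
#' @return `TRUE` invisibly; errors if shapes, pixel sizes or origins differ.
#' @export
stopifnot_same_grid <- function(...) {
  rs <- list(...)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!identical(dim(r$values), dim(ref$values)))
      stop("raster grids are misaligned: dimensions differ (",
           paste(dim(ref$values), collapse = "x"), " vs ",
           paste(dim(r$values), collapse = "x"), ")")
    if (!isTRUE(all.equal(r$pixel_size, ref$pixel_size)))
      stop("raster grids are misaligned: pixel sizes differ")
    if (!isTRUE(all.equal(r$origin, ref$origin)))
      stop("raster grids are misaligned: origins differ")
  }
  invisible(TRUE)
}

#' Apply a statistic over non-overlapping square blocks
#'
#' Blocks with fewer than `min_valid_frac` unmasked pixels yield `NA`.
#' Trailing rows/columns that do not fill a complete block are dropped.
#'
#' @param r a `dgx_raster`.
#' @param block_px block edge length in pixels (>= 1).
#' @param fun function of a numeric vector of unmasked pixel values.
#' @param min_valid_frac minimum unmasked fraction for a block (default 0.5).
#' @return a `dgx_raster` on the coarse grid (pixel size scaled by `block_px`).
#' @export
block_stat <- function(r, block_px, fun, min_valid_frac = 0.5) {
  stopifnot(is_raster(r), block_px >= 1)
  v <- r$values
  nbr <- nrow(v) %/% block_px
  nbc <- ncol(v) %/% block_px
  if (nbr < 1L || nbc < 1L)
    stop("raster (", nrow(v), "x", ncol(v),
         ") smaller than one block of ", block_px, " px")
  out <- matrix(NA_real_, nbr, nbc)
  need <- min_valid_frac * block_px^2
  for (i in seq_len(nbr)) {
    rows <- ((i - 1L) * block_px + 1L):(i * block_px)
    for (j in seq_len(nbc)) {
      blk <- v[rows, ((j - 1L) * block_px + 1L):(j * block_px)]
      blk <- blk[!is.na(blk)]
      if (length(blk) >= need && length(blk) > 0L) out[i, j] <- fun(blk)
    }
  }
  dgx_raster(out, r$pixel_size * block_px, r$origin)
}

## integer-coded class rasters: majority vote per block, ties broken by
## fixed class priority burned (2) > logged (1) > intact (0)
block_majority <- function(r, block_px, min_valid_frac = 0.5) {
  block_stat(r, block_px, function(x) {
    tab <- table(factor(x, levels = sort(unique(x))))
    win <- names(tab)[tab == max(tab)]
    max(as.numeric(win))  # highest code wins ties: burned > logged > intact
  }, min_valid_frac = min_valid_frac)
}

#' Read / write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: a 6-line header (ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows
#' from the top of the grid down.  Values round-trip at full double
#' precision.
#'
#' @param r a `dgx_raster`.
#' @param path file path.
#' @return `read_raster_asc` returns a `dgx_raster`; `write_raster_asc`
#'   returns `path` invisibly.
#' @export
write_raster_asc <- function(r, path) {
  stopifnot(is_raster(r))
  v <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$origin[1L], digits = 17)),
    paste("yllcorner", format(r$origin[2L], digits = 17)),
    paste("cellsize", format(r$pixel_size, digits = 17)),
    "NODATA_value -9999"), con)
  vv <- v
  vv[is.na(vv)] <- -9999
  utils::write.table(format(vv, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  if (any(lengths(kv) != 2L))
    stop("malformed ASCII grid header in ", path)
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% key) || anyNA(val[req]))
    stop("malformed ASCII grid header in ", path)
  m <- matrix(scan(path, skip = 6L, quiet = TRUE),
              nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  nd <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  m[m == nd] <- NA_real_
  org <- c(if ("xllcorner" %in% key) val[["xllcorner"]] else 0,
           if ("yllcorner" %in% key) val[["yllcorner"]] else 0)
  dgx_raster(m, val[["cellsize"]], org)
}
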