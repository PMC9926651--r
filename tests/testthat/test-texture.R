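test_that("quantization is monotone with full-range endpoints", {
  ## constant raster: single level
  q0 <- quantize(dgx_raster(matrix(0.7, 4, 4), 1), 32L)
  expect_true(all(q0$values == 0))

  ## linear ramp over 32 equal steps: one level per step, order kept
  ramp <- dgx_raster(matrix(rep(seq(0, 1, length.out = 32L), each = 2L),
                            2L, 32L), 1)
  qr <- quantize(ramp, 32L)
  expect_equal(qr$values[1, ], 0:31)
  expect_true(all(diff(qr$values[1, ]) >= 0))

  ## two-valued raster maps to the extreme levels
  q2 <- quantize(dgx_raster(matrix(c(0.2, 0.8), 2, 2), 1), 32L)
  expect_setequal(unique(as.vector(q2$values)), c(0, 31))

  expect_error(quantize(dgx_raster(matrix(NA_real_, 2, 2), 1), 32L),
               "all-nodata")
})

test_that("co-occurrence tabulation is symmetric and normalized", {
  ## 2x2 all-zero window, horizontal offset
  P <- glcm_cooccurrence(matrix(0L, 2, 2), c(0L, 1L), levels = 2L)
  expect_equal(P[1, 1], 1)

  ## 2x2 checkerboard: the two horizontal pairs, symmetrized
  chk <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  P2 <- glcm_cooccurrence(chk, c(0L, 1L), levels = 2L)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1], 0)

  ## contract on random windows: symmetric, sums to 1; masked excluded
  set.seed(5)
  for (i in 1:5) {
    w <- matrix(sample(0:3, 36, TRUE), 6, 6)
    w[sample(36, 4)] <- NA
    P <- glcm_cooccurrence(w, c(1L, -1L), levels = 4L)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }

  expect_error(glcm_cooccurrence(matrix(NA_integer_, 2, 2), c(0L, 1L),
                                 levels = 2L),
               "no valid")
})

test_that("metrics match their closed forms and a brute-force oracle", {
  ## single-level matrix
  P1 <- matrix(0, 4, 4); P1[1, 1] <- 1
  m1 <- glcm_metrics(P1)
  expect_equal(unname(m1[c("mean", "variance", "correlation", "contrast",
                           "dissimilarity", "entropy")]),
               rep(0, 6))
  expect_equal(unname(m1[c("homogeneity", "asm")]), c(1, 1))

  ## two-level checkerboard matrix, hand-evaluated
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  m2 <- glcm_metrics(P2)
  expect_equal(unname(m2), c(0.5, 0.25, -1, 1, 0.5, 1, 0.5, log(2)),
               tolerance = 1e-12)

  ## random symmetric P against an independent double-loop evaluation
  brute <- function(P) {
    L <- nrow(P); out <- numeric(8)
    mu <- 0
    for (i in 1:L) for (j in 1:L) mu <- mu + (i - 1) * P[i, j]
    va <- 0
    for (i in 1:L) for (j in 1:L) va <- va + (i - 1 - mu)^2 * P[i, j]
    co <- 0; ct <- 0; ho <- 0; di <- 0; as_ <- 0; en <- 0
    for (i in 1:L) for (j in 1:L) {
      p <- P[i, j]; d <- (i - 1) - (j - 1)
      co <- co + (i - 1 - mu) * (j - 1 - mu) * p
      ct <- ct + d^2 * p
      ho <- ho + p / (1 + d^2)
      di <- di + abs(d) * p
      as_ <- as_ + p^2
      if (p > 0) en <- en - p * log(p)
    }
    c(mu, va, if (va > 0) co / va else 0, ct, ho, di, as_, en)
  }
  set.seed(8)
  for (i in 1:5) {
    A <- matrix(stats::runif(36), 6, 6)
    P <- (A + t(A)); P <- P / sum(P)
    expect_equal(unname(glcm_metrics(P)), brute(P), tolerance = 1e-12)
  }
})

test_that("the moving-window path equals the naive per-pixel reference", {
  set.seed(60)
  r <- dgx_raster(matrix(stats::runif(60 * 60), 60, 60), 1)
  cfg <- glcm_config(window = 5L, levels = 16L)
  fast <- windowed_glcm(r, cfg)
  ref <- windowed_glcm_naive(r, cfg)
  for (k in glcm_metric_names())
    expect_equal(fast[[k]]$values, ref[[k]]$values, tolerance = 1e-10)
})

test_that("constant rasters give degenerate texture in the valid region", {
  r <- dgx_raster(matrix(1.5, 20, 20), 1)
  out <- windowed_glcm(r, glcm_config(window = 5L, levels = 32L))
  valid <- !is.na(out$contrast$values)
  expect_true(any(valid))
  expect_true(all(out$contrast$values[valid] == 0))
  expect_true(all(out$homogeneity$values[valid] == 1))
})

test_that("a border of one full window width is trimmed", {
  r <- dgx_raster(matrix(stats::runif(900), 30, 30), 1)
  w <- 7L
  out <- windowed_glcm(r, glcm_config(window = w, levels = 8L))
  m <- out$mean$values
  expect_true(all(is.na(m[seq_len(w), ])))
  expect_true(all(is.na(m[, seq_len(w)])))
  expect_true(all(is.na(m[(30 - w + 1):30, ])))
  expect_false(is.na(m[w + 1, w + 1]))

  expect_error(windowed_glcm(dgx_raster(matrix(1, 6, 6), 1),
                             glcm_config(window = 7L)),
               "not larger")
})

test_that("metrics are invariant to constant shifts of the raster", {
  set.seed(12)
  base <- matrix(stats::runif(625), 25, 25)
  cfg <- glcm_config(window = 5L, levels = 8L)
  a <- windowed_glcm(dgx_raster(base, 1), cfg)
  b <- windowed_glcm(dgx_raster(base + 100, 1), cfg)
  for (k in glcm_metric_names())
    expect_equal(a[[k]]$values, b[[k]]$values, tolerance = 1e-9)
})

test_that("metric ranges hold on random textures", {
  set.seed(13)
  r <- dgx_raster(matrix(stats::rnorm(40 * 40), 40, 40), 1)
  out <- windowed_glcm(r, glcm_config(window = 9L, levels = 16L))
  ok <- !is.na(out$mean$values)
  expect_true(all(out$homogeneity$values[ok] > 0 &
                    out$homogeneity$values[ok] <= 1))
  expect_true(all(out$asm$values[ok] > 0 & out$asm$values[ok] <= 1))
  expect_true(all(out$entropy$values[ok] >= 0 &
                    out$entropy$values[ok] <= 2 * log(16)))
  expect_true(all(out$contrast$values[ok] >= 0))
  expect_true(all(out$variance$values[ok] >= 0))
})
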