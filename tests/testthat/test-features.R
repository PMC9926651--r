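test_that("aggregation statistics match hand-computed values", {
  stats_ <- aggregation_statistics()
  ## constant block
  x <- rep(2.5, 16)
  expect_equal(stats_$avg(x), 2.5)
  expect_equal(stats_$min(x), 2.5)
  expect_equal(stats_$max(x), 2.5)
  expect_equal(stats_$median(x), 2.5)
  expect_equal(stats_$q1(x), 2.5)
  expect_equal(stats_$q3(x), 2.5)
  expect_equal(stats_$rms(x), 2.5)
  expect_equal(stats_$sd(x), 0)
  expect_equal(stats_$skew(x), 0)

  ## rms of equally frequent {3, 4}
  expect_equal(stats_$rms(c(3, 4, 3, 4)), sqrt(12.5))

  ## linear-interpolation quantiles of 1..8
  expect_equal(stats_$q1(1:8), 2.75)
  expect_equal(stats_$median(1:8), 4.5)
  expect_equal(stats_$q3(1:8), 6.25)
})

test_that("feature aggregation drops under-observed cells", {
  m <- matrix(stats::rnorm(16 * 16), 16, 16)
  m[1:8, 1:7] <- NA   # 56 of 64 px masked in the first 8x8 cell
  bands <- list(b1 = dgx_raster(m, 1))
  tab <- aggregate_features(bands, cell_px = 8L)
  expect_equal(nrow(tab), 3L)                  # 4 cells minus 1 dropped
  expect_equal(ncol(tab), 2L + 9L)
  expect_false(any(tab$cell_row == 1 & tab$cell_col == 1))

  expect_error(aggregate_features(bands, cell_px = 8L,
                                  statistics = list()),
               "nonempty")
})

test_that("72 features arise from 8 bands and 9 statistics", {
  set.seed(31)
  bands <- lapply(glcm_metric_names(), function(k)
    dgx_raster(matrix(stats::rnorm(64), 8, 8), 1))
  names(bands) <- glcm_metric_names()
  tab <- aggregate_features(bands, cell_px = 4L)
  expect_equal(ncol(tab) - 2L, 72L)
  expect_equal(nrow(tab), 4L)
})

test_that("purity is the dominant-class share with a fixed tie rule", {
  ## homogeneous cell
  cm <- dgx_raster(matrix(1, 4, 4), 1)
  p <- compute_purity(cm, cell_px = 4L)
  expect_equal(p$ref_class, "logged")
  expect_equal(p$purity, 1)

  ## 60/40 cell
  m <- matrix(0, 10, 10); m[, 1:6] <- 1
  p2 <- compute_purity(dgx_raster(m, 1), cell_px = 10L)
  expect_equal(p2$ref_class, "logged")
  expect_equal(p2$purity, 0.6)

  ## exact 50/50 tie: burned > logged > intact
  m3 <- matrix(c(1, 2), 4, 4)
  p3 <- compute_purity(dgx_raster(m3, 1), cell_px = 4L)
  expect_equal(p3$ref_class, "burned")
  expect_equal(p3$purity, 0.5)

  ## purity never 0, never above 1, on random maps
  set.seed(17)
  m4 <- matrix(sample(0:2, 400, TRUE), 20, 20)
  p4 <- compute_purity(dgx_raster(m4, 1), cell_px = 5L)
  expect_true(all(p4$purity > 0 & p4$purity <= 1))
})

test_that("cells get the most recent event year of their dominant class", {
  m <- matrix(1, 6, 6)
  y <- matrix(2014, 6, 6); y[1:3, ] <- 2017
  p <- compute_purity(dgx_raster(m, 1), cell_px = 6L,
                      year_map = dgx_raster(y, 1))
  expect_equal(p$event_year, 2017L)
  ## intact cells carry no event year
  p0 <- compute_purity(dgx_raster(matrix(0, 6, 6), 1), cell_px = 6L,
                       year_map = dgx_raster(matrix(NA_real_, 6, 6), 1))
  expect_true(is.na(p0$event_year))
})

test_that("the disturbance-age filter keeps the five-year boundary", {
  cells <- data.frame(ref_class = c("logged", "burned", "logged",
                                    "intact"),
                      event_year = c(2012L, 2017L, 2013L, NA),
                      purity = 1)
  out <- filter_recent(cells, image_year = 2018L)
  ## 2012 (6 y) removed; 2017 (1 y) and 2013 (exactly 5 y) retained;
  ## intact always retained
  expect_equal(out$event_year, c(2017L, 2013L, NA))
  expect_true("intact" %in% out$ref_class)
})

test_that("per-site standardization gives mean 0, SD 1 per feature", {
  set.seed(23)
  cells <- data.frame(site_id = rep(c("a", "b"), each = 40),
                      ref_class = "intact", purity = 1,
                      f1 = c(stats::rnorm(40, 5), stats::rnorm(40, -3)),
                      f2 = stats::rnorm(80),
                      f3 = 7)  # constant feature
  out <- standardize_per_site(cells)
  for (site in c("a", "b")) {
    idx <- out$site_id == site
    expect_equal(mean(out$f1[idx]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(out$f1[idx]), 1, tolerance = 1e-10)
    expect_true(all(out$f3[idx] == 0))
  }
  ## shifted copies of one distribution standardize identically
  base <- stats::rnorm(30)
  two <- data.frame(site_id = rep(c("a", "b"), each = 30),
                    ref_class = "intact", purity = 1,
                    f1 = c(base, base + 42))
  std <- standardize_per_site(two)
  expect_equal(std$f1[1:30], std$f1[31:60], tolerance = 1e-10)

  expect_error(standardize_per_site(
    data.frame(site_id = "solo", ref_class = "intact", purity = 1,
               f1 = 1)),
    "fewer than 2")
})

test_that("aggregation is idempotent on cell-constant rasters", {
  vals <- matrix(c(2, 5, 9, 11), 2, 2)
  m <- vals[rep(1:2, each = 4), rep(1:2, each = 4)]
  tab <- aggregate_features(list(b = dgx_raster(m, 1)), cell_px = 4L)
  for (s in c("avg", "min", "max", "median"))
    expect_equal(tab[[paste0("b_", s)]], as.vector(vals))
})
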