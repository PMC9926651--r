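test_that("site_config validates fractions and parameters", {
  expect_error(site_config("x", class_fraction = c(intact = 0.5,
                                                   logged = 0.6,
                                                   burned = -0.1)),
               "sum to 1")
  expect_error(site_config("x", pixel_size = 0), "positive")
  expect_error(site_config("x", acd = list(intact = c(mean = 10, sd = -1),
                                           logged = NULL, burned = NULL)),
               "sd >= 0")
})

test_that("an all-intact configuration yields no disturbance at all", {
  cfg <- site_config("pure", extent = c(100L, 100L),
                     class_fraction = c(intact = 1, logged = 0, burned = 0),
                     seed = 5L)
  land <- generate_landscape(cfg, glcm_window = 9L)
  expect_true(all(land$class_map$values == 0))
  expect_length(land$polygons, 0L)
  expect_true(all(is.na(land$year_map$values)))
})

test_that("landscapes regenerate bit-identically from their seed", {
  a <- mini_landscape(seed = 11L)
  b <- mini_landscape(seed = 11L)
  expect_identical(a$evi$values, b$evi$values)
  expect_identical(a$class_map$values, b$class_map$values)
  expect_identical(lapply(a$polygons, unclass),
                   lapply(b$polygons, unclass))
})

test_that("undersized extents are rejected with a sizing message", {
  cfg <- site_config("tiny", extent = c(30L, 30L))
  expect_error(generate_landscape(cfg, glcm_window = 45L),
               "smaller than one GLCM")
})

test_that("generated classes carry their canopy signatures", {
  land <- mini_landscape(seed = 3L)
  evi <- land$evi$values
  cls <- land$class_map$values
  expect_true(all(evi >= -1 & evi <= 1))
  ## burned forest darker than intact on average
  expect_lt(mean(evi[cls == 2]), mean(evi[cls == 0]))
  ## road pixels (low-EVI lines inside logged areas) darker than intact
  expect_true(any(land$road_mask))
  expect_lt(mean(evi[land$road_mask]), mean(evi[cls == 0]))
  ## and the logged band is more variable than intact canopy
  expect_gt(stats::sd(evi[cls == 1]), stats::sd(evi[cls == 0]))
})

test_that("polygons rasterize back to the class map exactly", {
  land <- mini_landscape(seed = 9L)
  maps <- rasterize_polygons(land$polygons, land$class_map)
  expect_identical(maps$class_map$values, land$class_map$values)
  expect_true(all(vapply(land$polygons, function(p)
    p$event_year <= land$config$image_year, TRUE)))
})

test_that("plot ACD draws honour class parameters and truncation", {
  ## mean recovery on an intact-only map, n = 10,000 plots
  cfg <- site_config("flat", extent = c(1600L, 1600L),
                     class_fraction = c(intact = 1, logged = 0, burned = 0),
                     seed = 21L)
  cls <- dgx_raster(matrix(0, 1600L, 1600L))
  acd <- generate_acd_plots(cfg, cls)
  vals <- as.vector(acd$values)
  expect_length(vals, 100L * 100L)
  se <- 10.2 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 89.2), 3 * se)
  expect_lt(abs(stats::sd(vals) - 10.2), 3 * se)

  ## sd = 0 collapses to the mean
  cfg0 <- site_config("pt", extent = c(160L, 160L),
                      class_fraction = c(intact = 1, logged = 0,
                                         burned = 0),
                      acd = list(intact = c(mean = 50, sd = 0),
                                 logged = NULL, burned = NULL), seed = 2L)
  acd0 <- generate_acd_plots(cfg0, dgx_raster(matrix(0, 160L, 160L)))
  expect_true(all(acd0$values == 50))

  ## heavy truncation still never yields negatives
  cfgt <- site_config("tr", extent = c(320L, 320L),
                      class_fraction = c(intact = 1, logged = 0,
                                         burned = 0),
                      acd = list(intact = c(mean = 5, sd = 35),
                                 logged = NULL, burned = NULL), seed = 3L)
  acdt <- generate_acd_plots(cfgt, dgx_raster(matrix(0, 320L, 320L)))
  expect_true(all(acdt$values >= 0))
})

test_that("missing ACD parameters name the offending class", {
  cfg <- site_config("gap", extent = c(160L, 160L),
                     class_fraction = c(intact = 0.5, logged = 0,
                                        burned = 0.5),
                     acd = acd_params_high(),  # burned is NULL here
                     seed = 4L)
  cls <- dgx_raster(matrix(c(0, 2), 160L, 160L))
  expect_error(generate_acd_plots(cfg, cls), "burned")
})

test_that("the three-site fixture mirrors the study design", {
  sites <- make_multisite_fixture(seed = 2L, extent_px = 480L,
                                  glcm_window = 9L,
                                  patch_quantum_px = 80L)
  expect_named(sites, c("feliz_natal", "xingu", "saraca"))
  expect_true(all(sites$xingu$class_map$values != 1))    # no logging
  expect_true(all(sites$saraca$class_map$values != 2))   # no burning
  expect_true(any(sites$feliz_natal$class_map$values == 1))
  expect_true(any(sites$feliz_natal$class_map$values == 2))
  ## distinct ACD regimes: high-biomass site vs the two low-biomass ones
  expect_equal(sites$saraca$config$acd$intact[["mean"]], 185.3)
  expect_equal(sites$xingu$config$acd$intact[["mean"]], 89.2)
  ## regenerates identically
  again <- make_multisite_fixture(seed = 2L, extent_px = 480L,
                                  glcm_window = 9L,
                                  patch_quantum_px = 80L)
  expect_identical(sites$feliz_natal$evi$values,
                   again$feliz_natal$evi$values)
  expect_identical(sites$saraca$acd_plots$values,
                   again$saraca$acd_plots$values)
})
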