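test_that("class weights balance classes before the purity multiplier", {
  cls <- rep(c("intact", "logged", "burned"), c(10, 20, 70))
  w <- compute_weights(cls)
  ## base weights N / (3 n_c)
  expect_equal(unique(w[cls == "intact"]), 10 / 3)
  expect_equal(unique(w[cls == "logged"]), 5 / 3)
  expect_equal(unique(w[cls == "burned"]), 10 / 21)
  ## per-class sums all equal N / 3
  sums <- tapply(w, cls, sum)
  expect_equal(as.vector(sums), rep(100 / 3, 3), tolerance = 1e-12)

  ## equal counts, purity 1: all weights 1
  expect_true(all(compute_weights(rep(c("intact", "logged", "burned"),
                                      each = 5)) == 1))

  ## purity scales the base weight
  w2 <- compute_weights(c("intact", "intact", "logged", "burned"),
                        purity = c(1, 0.5, 1, 1))
  expect_equal(w2[2], w2[1] / 2)

  expect_error(compute_weights(rep("intact", 5)), "logged")
})

test_that("stratified partitioning is balanced, seeded and exhaustive", {
  cells <- separable_cells(n_per_class = 60L, seed = 2L)
  spec <- training_spec(seed = 99L)
  part <- stratified_partition(cells, spec)
  expect_equal(nrow(part$train) + nrow(part$test), nrow(cells))

  ## per-stratum balance within one cell
  bins <- pmin(floor(cells$purity / 0.2), 4)
  strata <- paste(cells$ref_class, bins)
  key <- paste(cells$site_id, cells$cell_row, cells$cell_col)
  tr_key <- paste(part$train$site_id, part$train$cell_row,
                  part$train$cell_col)
  for (s in unique(strata)) {
    n_tr <- sum(key[strata == s] %in% tr_key)
    n_all <- sum(strata == s)
    expect_lte(abs(n_tr - (n_all - n_tr)), 1)
  }

  ## same seed, same split
  part2 <- stratified_partition(cells, spec)
  expect_identical(part$train$cell_row, part2$train$cell_row)

  ## a singleton stratum lands in training
  one <- cells[1, ]; one$purity <- 0.05   # its own purity bin
  part3 <- stratified_partition(rbind(cells, one), spec)
  expect_true(any(part3$train$purity == 0.05))

  expect_error(stratified_partition(cells[0, ], spec), "no cells")
})

test_that("the boosted classifier separates a well-separated fixture", {
  cells <- separable_cells(n_per_class = 100L, seed = 3L)
  spec <- training_spec(seed = 5L)
  part <- stratified_partition(cells, spec)
  model <- fit_degradation_model(part$train, spec)
  p <- predict(model, part$test)

  ## probabilities are a valid simplex
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)

  ## held-out accuracy on separable classes
  acc <- mean(hard_class(p) == part$test$ref_class)
  expect_gte(acc, 0.95)

  ## determinism: same seed, same predictions
  model2 <- fit_degradation_model(part$train, spec)
  expect_identical(predict(model2, part$test), p)

  ## missing class is an error
  expect_error(fit_degradation_model(
    part$train[part$train$ref_class != "burned", ], spec),
    "burned")
})

test_that("hard classification breaks ties burned > logged > intact", {
  p <- rbind(c(intact = 0.5, logged = 0.5, burned = 0),
             c(intact = 0.2, logged = 0.4, burned = 0.4),
             c(intact = 1 / 3, logged = 1 / 3, burned = 1 / 3))
  expect_equal(hard_class(p), c("logged", "burned", "burned"))
})

test_that("an all-zero extra feature leaves the hard classes unchanged", {
  cells <- separable_cells(n_per_class = 80L, seed = 11L)
  spec <- training_spec(seed = 6L)
  part <- stratified_partition(cells, spec)
  m1 <- fit_degradation_model(part$train, spec)
  h1 <- predict(m1, part$test, type = "class")

  aug <- function(df) { df$f_zero <- 0; df }
  m2 <- fit_degradation_model(aug(part$train), spec)
  h2 <- predict(m2, aug(part$test), type = "class")
  expect_equal(h2, h1)
})

test_that("the partition ensemble reports a full accuracy distribution", {
  cells <- separable_cells(n_per_class = 60L, seed = 13L)
  spec <- training_spec(n_partitions = 5L, seed = 17L)
  ens <- fit_ensemble(cells, spec)
  expect_length(ens$accuracies, 5L)
  expect_true(all(ens$accuracies >= 0.9))   # separable fixture
  expect_gte(ens$summary[["sd"]], 0)

  ## averaged test probabilities are a valid simplex with labels attached
  pm <- as.matrix(ens$probs[, c("intact", "logged", "burned")])
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-6)
  expect_true(all(ens$probs$ref_class %in% c("intact", "logged",
                                             "burned")))

  ## a single partition reduces to one fit and one accuracy
  ens1 <- fit_ensemble(cells, training_spec(n_partitions = 1L,
                                            seed = 17L))
  part <- stratified_partition(cells, training_spec(seed = 18L),
                               seed = 17L + 1L)
  model <- fit_degradation_model(part$train,
                                 training_spec(n_partitions = 1L,
                                               seed = 17L),
                                 seed = 17L + 1L)
  acc <- mean(predict(model, part$test, type = "class") ==
                part$test$ref_class)
  expect_equal(ens1$accuracies, acc)
})
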