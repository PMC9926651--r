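DCLASSES <- c("intact", "logged", "burned")  # fixed encoding 0, 1, 2

#' Training hyperparameters for the degradation classifier
#'
#' Defaults follow the published configuration of the stochastic
#' gradient-boosted multinomial model: 50/50 stratified train/test split
#' on 0.2-wide purity bins within each class, 80% row and 70% feature
#' subsampling per boosting round, learning rate 0.2, trees of depth at
#' most 4 with at least 5 observations per terminal node and a minimum
#' split-loss reduction of 0.2, early stopping once the validation
#' multiclass error fails to improve for 5 rounds, and 100 random
#' partitions for the ensemble assessment.
#'
#' @param train_frac fraction of cells in the training half.
#' @param purity_bin_width width of the purity strata.
#' @param row_subsample,feature_subsample per-round subsampling rates.
#' @param early_stop_rounds early-stopping patience (boosting rounds).
#' @param learning_rate shrinkage per round.
#' @param min_node_obs minimum observations in a terminal node.
#' @param max_depth maximum tree depth.
#' @param min_split_gain minimum loss reduction to split a node.
#' @param n_partitions number of random partitions for [fit_ensemble()].
#' @param max_rounds cap on boosting rounds (early stopping acts first).
#' @param validation_frac fraction of the training half carved out (by
#'   the same stratification) as the early-stopping validation set.
#' @param seed integer seed for partitioning and boosting.
#' @return an object of class `training_spec`.
#' @export
training_spec <- function(train_frac = 0.5, purity_bin_width = 0.2,
                          row_subsample = 0.8, feature_subsample = 0.7,
                          early_stop_rounds = 5L, learning_rate = 0.2,
                          min_node_obs = 5L, max_depth = 4L,
                          min_split_gain = 0.2, n_partitions = 100L,
                          max_rounds = 200L, validation_frac = 0.2,
                          seed = 1L) {
  fracs <- c(train_frac, purity_bin_width, row_subsample, feature_subsample,
             learning_rate, validation_frac)
  if (any(fracs <= 0) || any(fracs > 1))
    stop("fractions and rates must lie in (0, 1]")
  if (any(c(early_stop_rounds, min_node_obs, max_depth, n_partitions,
            max_rounds) < 1L))
    stop("counts must be >= 1")
  structure(list(train_frac = train_frac,
                 purity_bin_width = purity_bin_width,
                 row_subsample = row_subsample,
                 feature_subsample = feature_subsample,
                 early_stop_rounds = as.integer(early_stop_rounds),
                 learning_rate = learning_rate,
                 min_node_obs = as.integer(min_node_obs),
                 max_depth = as.integer(max_depth),
                 min_split_gain = min_split_gain,
                 n_partitions = as.integer(n_partitions),
                 max_rounds = as.integer(max_rounds),
                 validation_frac = validation_frac,
                 seed = as.integer(seed)),
            class = "training_spec")
}

#' Class-balanced, purity-weighted observation weights
#'
#' Base weight for class c is N / (3 n_c), so the per-class weight sums
#' are all equal (to N / 3) before purity enters; each cell's final
#' weight is its base weight times its purity, down-weighting the loss
#' contribution of heterogeneous reference cells.
#'
#' @param ref_class character vector of cell classes.
#' @param purity numeric vector in (0, 1].
#' @return numeric weight per cell.
#' @export
compute_weights <- function(ref_class, purity = rep(1, length(ref_class))) {
  stopifnot(length(ref_class) == length(purity))
  n <- length(ref_class)
  counts <- table(factor(ref_class, levels = DCLASSES))
  missing <- names(counts)[counts == 0L]
  if (length(missing))
    stop("no cells for modeled class(es): ", paste(missing, collapse = ", "))
  base <- n / (length(DCLASSES) * as.numeric(counts[ref_class]))
  base * purity
}

purity_bin <- function(purity, width = 0.2) {
  ## [0,.2), [.2,.4), ..., [.8,1] with the top bin right-closed
  pmin(floor(purity / width), ceiling(1 / width) - 1L)
}

#' Stratified 50/50 train/test partition
#'
#' Cells are stratified by class crossed with binned purity (bins of
#' width 0.2; the top bin includes 1) and split `train_frac`/rest at
#' random within each stratum.  Singleton strata go to the training half.
#'
#' @param cells data frame with `ref_class` and `purity`.
#' @param spec a [training_spec()].
#' @param seed seed for the split (default `spec$seed`).
#' @return list with `train` and `test` data frames.
#' @export
stratified_partition <- function(cells, spec = training_spec(),
                                 seed = spec$seed) {
  if (nrow(cells) == 0L) stop("no cells to partition")
  set.seed(seed)
  strata <- interaction(cells$ref_class,
                        purity_bin(cells$purity, spec$purity_bin_width),
                        drop = TRUE)
  in_train <- logical(nrow(cells))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    n_tr <- ceiling(length(idx) * spec$train_frac)
    in_train[idx[sample.int(length(idx), n_tr)]] <- TRUE
  }
  list(train = cells[in_train, , drop = FALSE],
       test = cells[!in_train, , drop = FALSE])
}

#' Fit the gradient-boosted degradation classifier
#'
#' Multinomial (softprob) gradient-boosted trees on the 72 texture
#' features, with class-balanced purity weights, per-round row/feature
#' subsampling, and early stopping on a stratified validation carve-out
#' of the training data.  Returns a classed model whose `predict` method
#' yields per-cell class probabilities.
#'
#' @param train data frame of training cells (features plus `ref_class`,
#'   `purity`).
#' @param spec a [training_spec()].
#' @param seed seed for the validation carve-out and booster (default
#'   `spec$seed`).
#' @param feature_cols feature column names (default: autodetected).
#' @return an object of class `degradation_model`.
#' @export
fit_degradation_model <- function(train, spec = training_spec(),
                                  seed = spec$seed, feature_cols = NULL) {
  if (nrow(train) == 0L) stop("empty training set")
  if (is.null(feature_cols)) feature_cols <- feature_columns(train)
  absent <- setdiff(DCLASSES, unique(train$ref_class))
  if (length(absent))
    stop("class(es) absent from training data: ",
         paste(absent, collapse = ", "))
  w <- if ("weight" %in% names(train)) train$weight
       else compute_weights(train$ref_class, train$purity)
  y <- match(train$ref_class, DCLASSES) - 1L

  ## stratified validation carve-out for early stopping
  set.seed(seed)
  strata <- interaction(train$ref_class,
                        purity_bin(train$purity, spec$purity_bin_width),
                        drop = TRUE)
  in_val <- logical(nrow(train))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    n_val <- floor(length(idx) * spec$validation_frac)
    if (n_val > 0L) in_val[idx[sample.int(length(idx), n_val)]] <- TRUE
  }
  if (!any(in_val))  # tiny data: fall back to a random 20%
    in_val[sample(nrow(train), max(1L, nrow(train) %/% 5L))] <- TRUE

  x <- as.matrix(train[, feature_cols, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(x[!in_val, , drop = FALSE],
                                 label = y[!in_val], weight = w[!in_val],
                                 nthread = 1)
  dval <- xgboost::xgb.DMatrix(x[in_val, , drop = FALSE],
                               label = y[in_val], weight = w[in_val],
                               nthread = 1)
  params <- xgboost::xgb.params(
    objective = "multi:softprob", num_class = length(DCLASSES),
    eta = spec$learning_rate, max_depth = spec$max_depth,
    min_child_weight = spec$min_node_obs, gamma = spec$min_split_gain,
    subsample = spec$row_subsample,
    colsample_bytree = spec$feature_subsample,
    eval_metric = "merror", nthread = 1, seed = seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = spec$max_rounds,
                                evals = list(val = dval),
                                early_stopping_rounds =
                                  spec$early_stop_rounds,
                                verbose = 0)
  structure(list(booster = booster, feature_cols = feature_cols,
                 spec = spec, seed = seed, classes = DCLASSES,
                 n_train = sum(!in_val), n_val = sum(in_val)),
            class = "degradation_model")
}

#' @export
print.degradation_model <- function(x, ...) {
  cat(sprintf(paste0("<degradation_model> boosted multinomial ",
                     "classifier\n  %d features, %d train / %d ",
                     "validation cells\n"),
              length(x$feature_cols), x$n_train, x$n_val))
  bi <- xgboost::xgb.attr(x$booster, "best_iteration")
  if (!is.null(bi)) cat("  best iteration:", bi, "\n")
  invisible(x)
}

#' Predict degradation class probabilities
#'
#' @param object a `degradation_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param type `"prob"` for the probability matrix (rows sum to 1) or
#'   `"class"` for the hard most-probable class, ties broken by the fixed
#'   priority burned > logged > intact.
#' @param ... unused.
#' @return matrix of probabilities with one column per class, or a
#'   character vector of classes.
#' @export
predict.degradation_model <- function(object, newdata, type = "prob", ...) {
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  p <- predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  colnames(p) <- object$classes
  if (identical(type, "class")) return(hard_class(p))
  p
}

#' Most-probable class from a probability matrix
#'
#' @param p matrix with columns intact, logged, burned.
#' @return character vector; ties resolved burned > logged > intact.
#' @export
hard_class <- function(p) {
  stopifnot(all(DCLASSES %in% colnames(p)))
  p <- p[, DCLASSES, drop = FALSE]
  apply(p, 1L, function(row) DCLASSES[max(which(row == max(row)))])
}

#' Ensemble of models over random partitions
#'
#' Refits the classifier on `spec$n_partitions` independent stratified
#' partitions, evaluating each on its own held-out half; reports the
#' distribution of overall accuracies (partition variability plus
#' algorithm stochasticity) and the per-cell test-fold probabilities
#' averaged over partitions.
#'
#' @param cells full feature table (all sites, standardized).
#' @param spec a [training_spec()].
#' @return an object of class `degradation_ensemble` with elements
#'   `accuracies`, `summary` (mean, sd), `probs` (per-cell averaged
#'   test probabilities with `ref_class`), and `spec`.
#' @export
fit_ensemble <- function(cells, spec = training_spec()) {
  stopifnot(spec$n_partitions >= 1L)
  key <- paste(cells$site_id, cells$cell_row, cells$cell_col)
  psum <- matrix(0, nrow(cells), length(DCLASSES),
                 dimnames = list(NULL, DCLASSES))
  pn <- integer(nrow(cells))
  accs <- numeric(spec$n_partitions)
  for (k in seq_len(spec$n_partitions)) {
    seed_k <- spec$seed + k
    part <- stratified_partition(cells, spec, seed = seed_k)
    model <- fit_degradation_model(part$train, spec, seed = seed_k)
    p <- predict(model, part$test)
    accs[k] <- mean(hard_class(p) == part$test$ref_class)
    rows <- match(paste(part$test$site_id, part$test$cell_row,
                        part$test$cell_col), key)
    psum[rows, ] <- psum[rows, ] + p
    pn[rows] <- pn[rows] + 1L
  }
  seen <- pn > 0L
  probs <- cells[seen, intersect(c("site_id", "cell_row", "cell_col",
                                   "ref_class", "purity"), names(cells)),
                 drop = FALSE]
  probs <- cbind(probs, psum[seen, , drop = FALSE] / pn[seen])
  structure(list(accuracies = accs,
                 summary = c(mean = mean(accs),
                             sd = if (length(accs) > 1L) stats::sd(accs)
                                  else 0),
                 probs = probs, spec = spec),
            class = "degradation_ensemble")
}

#' @export
print.degradation_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<degradation_ensemble> %d partitions\n  overall ",
                     "accuracy %.3f +/- %.3f (mean +/- SD over ",
                     "partitions)\n"),
              length(x$accuracies), x$summary[["mean"]],
              x$summary[["sd"]]))
  invisible(x)
}

#' @export
summary.degradation_ensemble <- function(object, ...) {
  qs <- stats::quantile(object$accuracies, c(0.025, 0.5, 0.975))
  out <- list(n_partitions = length(object$accuracies),
              mean = object$summary[["mean"]],
              sd = object$summary[["sd"]],
              quantiles = qs)
  class(out) <- "summary.degradation_ensemble"
  out
}

#' @export
print.summary.degradation_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d partitions\n", x$n_partitions))
  cat(sprintf("  accuracy: mean %.3f, SD %.3f\n", x$mean, x$sd))
  cat(sprintf("  2.5%% / 50%% / 97.5%%: %.3f / %.3f / %.3f\n",
              x$quantiles[1L], x$quantiles[2L], x$quantiles[3L]))
  invisible(x)
}
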