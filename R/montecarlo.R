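#' Monte Carlo propagation of ACD and classification uncertainty
#'
#' Simulates the site-level mean aboveground carbon density under one of
#' two uncertainty modes.  In `"acd_only"` every grid cell keeps its
#' most-probable (hard) class, which is deterministic, and only the ACD
#' draw varies between iterations.  In `"acd_plus_class"` each cell's
#' class is additionally redrawn from its probability vector at every
#' iteration, propagating classification uncertainty as well.  In both
#' modes the cell's ACD is then drawn uniformly with replacement from the
#' empirical site-class distribution of 500 m carbon values.  Draws are
#' independent across cells and iterations (no spatial error model); one
#' RNG stream per simulation is consumed in a fixed order - all class
#' draws first (iteration-major), then all ACD draws grouped by class -
#' so a run is exactly reproducible from its seed.
#'
#' @param probs data frame with columns `site_id`, `intact`, `logged`,
#'   `burned` (per-cell class probabilities; rows sum to 1).
#' @param dists an `acd_distributions` table covering every reachable
#'   site-class pair (after substitution).
#' @param mode `"acd_only"` or `"acd_plus_class"`.
#' @param n_iter number of iterations (default 10000).
#' @param seed integer seed.
#' @return an object of class `acd_simulation`: per-site list with the
#'   iteration vector of site-mean ACD and its (mean, sd) summary.
#' @export
simulate_acd <- function(probs, dists, mode = c("acd_plus_class",
                                                "acd_only"),
                         n_iter = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  pm <- as.matrix(probs[, DCLASSES])
  if (any(pm < -1e-9) || any(abs(rowSums(pm) - 1) > 1e-6))
    stop("invalid class probabilities: entries must be in [0,1] and rows ",
         "sum to 1")
  set.seed(seed)
  sites <- unique(probs$site_id)
  out <- list()
  for (site in sites) {
    rows <- which(probs$site_id == site)
    p <- pm[rows, , drop = FALSE]
    m <- nrow(p)

    ## class assignment per (cell, iteration)
    if (mode == "acd_only") {
      cls <- matrix(rep.int(match(hard_class(p), DCLASSES), n_iter),
                    m, n_iter)
    } else {
      cum <- t(apply(p, 1L, cumsum))
      u <- matrix(stats::runif(m * n_iter), m, n_iter)
      cls <- 1L + (u > cum[, 1L]) + (u > cum[, 2L])
    }

    ## ACD per (cell, iteration): empirical draw by class
    acd <- matrix(NA_real_, m, n_iter)
    for (k in seq_along(DCLASSES)) {
      idx <- which(cls == k)
      if (!length(idx)) next
      vals <- dists$acd[dists$site_id == site &
                          dists$dclass == DCLASSES[k]]
      if (!length(vals))
        stop("no ACD distribution for reachable class '", DCLASSES[k],
             "' at site ", site, " (substitution missing?)")
      acd[idx] <- vals[sample.int(length(vals), length(idx),
                                  replace = TRUE)]
    }
    means <- colMeans(acd)
    out[[site]] <- list(site_id = site, iterations = means,
                        summary = c(mean = mean(means),
                                    sd = stats::sd(means)),
                        n_cells = m)
  }
  structure(list(sites = out, mode = mode, n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "acd_simulation")
}

#' @export
print.acd_simulation <- function(x, ...) {
  cat(sprintf("<acd_simulation> mode %s, %d iterations, seed %d\n",
              x$mode, x$n_iter, x$seed))
  for (s in x$sites)
    cat(sprintf("  %-14s %8.1f (%.2f) Mg C/ha over %d cells\n",
                s$site_id, s$summary[["mean"]], s$summary[["sd"]],
                s$n_cells))
  invisible(x)
}

#' @export
summary.acd_simulation <- function(object, ...) {
  df <- do.call(rbind, lapply(object$sites, function(s)
    data.frame(site_id = s$site_id, mode = object$mode,
               n_cells = s$n_cells, n_iter = object$n_iter,
               mean = s$summary[["mean"]], sd = s$summary[["sd"]])))
  rownames(df) <- NULL
  df
}

## overlap coefficient of two empirical distributions on shared breaks
overlap_fraction <- function(a, b, nbins = 64L) {
  rng <- range(c(a, b))
  if (rng[1L] == rng[2L]) return(1)
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  ha <- hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  hb <- hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(pmin(ha, hb))
}

#' Compare two uncertainty simulations site by site
#'
#' For each site present in both runs: the difference of mean ACD
#' (b minus a), the ratio of iteration SDs (b over a) and the overlap
#' fraction of the two iteration distributions.  No significance test is
#' attached; the simulations themselves are the uncertainty statement.
#'
#' @param a,b `acd_simulation` objects with the same sites and `n_iter`,
#'   typically `a` = ACD only and `b` = ACD + classification.
#' @return data frame with one row per site.
#' @export
compare_simulations <- function(a, b) {
  stopifnot(inherits(a, "acd_simulation"), inherits(b, "acd_simulation"))
  if (!setequal(names(a$sites), names(b$sites)))
    stop("simulations cover different sites")
  if (a$n_iter != b$n_iter)
    stop("simulations have different iteration counts")
  out <- do.call(rbind, lapply(names(a$sites), function(site) {
    sa <- a$sites[[site]]; sb <- b$sites[[site]]
    data.frame(site_id = site,
               mean_a = sa$summary[["mean"]], mean_b = sb$summary[["mean"]],
               mean_diff = sb$summary[["mean"]] - sa$summary[["mean"]],
               sd_a = sa$summary[["sd"]], sd_b = sb$summary[["sd"]],
               sd_ratio = sb$summary[["sd"]] / sa$summary[["sd"]],
               overlap = overlap_fraction(sa$iterations, sb$iterations))
  }))
  rownames(out) <- NULL
  out
}
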