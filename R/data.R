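#' Bundled reference tables
#'
#' Small plain-text reference tables shipped with the package:
#' `load_reference_confusion()` returns a multi-site forest-degradation
#' confusion matrix (3,441 held-out grid cells) as a
#' [confusion_matrix]; `load_reference_acd_summary()` returns the
#' matching per-class aboveground carbon density summary (mean, SD in
#' Mg C ha^-1) for the combined low-biomass sites and the high-biomass
#' site.  Both are used as worked-example inputs for the assessment and
#' biomass summaries.
#'
#' @return see above.
#' @export
load_reference_confusion <- function() {
  f <- system.file("extdata", "confusion_multisite.csv",
                   package = "degratex", mustWork = TRUE)
  tab <- utils::read.csv(f)
  m <- as.matrix(tab[, DCLASSES])
  rownames(m) <- tab$predicted
  as_confusion_matrix(m[DCLASSES, ])
}

#' @rdname load_reference_confusion
#' @export
load_reference_acd_summary <- function() {
  f <- system.file("extdata", "acd_class_summary.csv",
                   package = "degratex", mustWork = TRUE)
  utils::read.csv(f)
}
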