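#' Scan candidate pool sizes and locate the lower-bound elbow
#'
#' Fits the model once per candidate K (sharing the same restart seeds so
#' the curves are comparable) and summarizes the evidence lower bound as a
#' function of K. The most probable pool size is read off the elbow of the
#' curve: the last K before the per-step ELBO gain first drops below
#' `elbow_frac` of the largest gain in the scan. The raw curve and the
#' per-component soft cell counts are always returned so the elbow can be
#' judged visually; the numeric rule is a stated heuristic, not part of
#' the model.
#'
#' @param data an [allele_counts()] object.
#' @param k_range integer vector of candidate K values (e.g. `2:8`).
#' @param config a [fit_config()]; the same seed is reused for every K.
#' @param elbow_frac relative-gain threshold of the elbow rule
#'   (default 0.1).
#' @return An object of class `k_scan`: list with `table` (K, elbo,
#'   iterations, converged), `soft_counts` (per K, the sorted soft cell
#'   mass per component), `elbow` (estimated K, `NA` for a single-K scan),
#'   and `fits` (the fitted models).
#' @export
scan_n_donors <- function(data, k_range, config = fit_config(),
                          elbow_frac = 0.1) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty K range")
  if (min(k_range) < 1 || max(k_range) > ncol(data$A))
    stop("K range must lie within [1, number of cells]")
  fits <- lapply(k_range, function(K)
    fit_donors(data, K, config = config, doublets = FALSE))
  elbo <- vapply(fits, function(f) f$elbo, numeric(1))
  soft <- lapply(fits, function(f) sort(colSums(f$r), decreasing = TRUE))
  tab <- data.frame(K = k_range, elbo = elbo,
                    iterations = vapply(fits, function(f)
                      length(f$elbo_trace), numeric(1)),
                    converged = vapply(fits, function(f)
                      f$converged, logical(1)))
  elbow <- NA_integer_
  if (length(k_range) > 1) {
    gains <- diff(elbo)
    small <- which(gains < elbow_frac * max(gains))
    elbow <- if (length(small)) k_range[min(small)] else k_range[length(k_range)]
  }
  structure(list(table = tab, soft_counts = soft, elbow = elbow,
                 fits = fits), class = "k_scan")
}

#' @export
print.k_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.na(x$elbow)) cat("estimated pool size (elbow): K =", x$elbow, "\n")
  invisible(x)
}
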