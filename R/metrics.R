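#' Most likely singlet donor per cell
#'
#' @param fit a `donor_fit`.
#' @return Integer vector of donor indices (argmax over the singlet
#'   columns of the assignment posterior).
#' @export
assigned_donor <- function(fit) {
  max.col(fit$r[, seq_len(fit$n_donors), drop = FALSE], ties.method = "first")
}

#' ARI-recall curve for singlet assignment
#'
#' Sweeps the singlet confidence threshold tau: at each value, recall is
#' the fraction of true singlets with `prob_max > tau`, and the adjusted
#' Rand index compares the most likely donor with the true donor over
#' those retained cells. The summary area integrates ARI over recall in
#' \[0, 1\] by the trapezoid rule (the curve reaches recall 1 at tau = 0;
#' the left end is extended at constant ARI).
#'
#' @param fit a `donor_fit`.
#' @param truth the `truth` element of a [simulate_pool()] result (or any
#'   list with `is_doublet` and `donor_index` per cell).
#' @param thresholds threshold grid (default `seq(0, 0.99, 0.01)`).
#' @return List with `curve` (data.frame threshold, recall, ari) and
#'   `area`.
#' @export
ari_recall_curve <- function(fit, truth, thresholds = seq(0, 0.99, 0.01)) {
  stopifnot(length(truth$is_doublet) == nrow(fit$r))
  singlet <- !truth$is_doublet
  pm <- fit$prob_max[singlet]
  pred <- assigned_donor(fit)[singlet]
  lab <- truth$donor_index[singlet]
  pts <- lapply(thresholds, function(tau) {
    sel <- pm > tau
    if (!any(sel)) return(NULL)
    data.frame(threshold = tau, recall = mean(sel),
               ari = mclust::adjustedRandIndex(pred[sel], lab[sel]))
  })
  curve <- do.call(rbind, pts)
  curve <- curve[order(curve$recall, curve$threshold), ]
  x <- curve$recall; y <- curve$ari
  x <- c(0, x, 1); y <- c(y[1], y, y[length(y)])
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(curve = curve, area = area)
}

#' ROC analysis of doublet detection
#'
#' Standard ROC of `prob_doublet` against the true doublet labels, with
#' the operating point at the recommended posterior cutoff.
#'
#' @param fit a `donor_fit` (doublet stage run).
#' @param truth as in [ari_recall_curve()].
#' @param threshold posterior cutoff for calling a doublet (default 0.9).
#' @return List with `auc`, `sensitivity`, `specificity`, `threshold`,
#'   and `roc` (the underlying `pROC::roc` object).
#' @export
doublet_roc <- function(fit, truth, threshold = 0.9) {
  y <- truth$is_doublet
  stopifnot(length(y) == nrow(fit$r))
  if (length(unique(y)) < 2)
    stop("doublet ROC undefined: truth contains a single class")
  pd <- fit$prob_doublet
  roc <- pROC::roc(response = y, predictor = pd, direction = "<",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)),
       sensitivity = mean(pd[y] > threshold),
       specificity = mean(pd[!y] <= threshold),
       threshold = threshold, roc = roc)
}

#' Precision of reconstructed donor genotypes
#'
#' Matches inferred donors to true donors by genotype concordance, then,
#' over (variant, donor) entries whose expected per-donor depth reaches
#' `min_umis`, scores the hard posterior genotype against the truth:
#' overall accuracy plus one precision per predicted state (the fraction
#' of entries predicted in state t that truly are t).
#'
#' @param fit a `donor_fit`.
#' @param truth as in [ari_recall_curve()] (needs `genotypes`).
#' @param min_umis depth filter (default 10).
#' @param matching optional precomputed [match_donors()] result mapping
#'   inferred donors to truth columns.
#' @return List with `overall`, `per_state` (named 0/1/2), `n_entries`,
#'   and `matching`.
#' @export
genotype_precision <- function(fit, truth, min_umis = 10, matching = NULL) {
  inferred <- donor_genotypes(fit)
  truthg <- donor_genotypes_from_matrix(truth$genotypes,
                                        ids = rownames(truth$genotypes))
  if (is.null(matching))
    matching <- match_donors(genotype_concordance(inferred, truthg,
                                                  min_umis = min_umis))
  ia <- match(truthg$ids, inferred$ids)
  pred <- true <- integer(0)
  for (k in seq_along(matching$to)) {
    t_col <- matching$to[k]
    if (is.na(t_col)) next
    ok <- !is.na(ia) & inferred$depth[ia, k] >= min_umis &
      !is.na(inferred$hard[ia, k])
    pred <- c(pred, inferred$hard[ia[ok], k])
    true <- c(true, truth$genotypes[ok, t_col])
  }
  if (!length(pred))
    stop("no (variant, donor) entries pass the ", min_umis, "-UMI filter")
  per_state <- vapply(0:2, function(t) {
    sel <- pred == t
    if (!any(sel)) NA_real_ else mean(true[sel] == t)
  }, numeric(1))
  names(per_state) <- c("0", "1", "2")
  list(overall = mean(pred == true), per_state = per_state,
       n_entries = length(pred), matching = matching)
}

#' ARI of the most likely assignment over true singlets
#'
#' @param fit a `donor_fit`.
#' @param truth as in [ari_recall_curve()].
#' @return Adjusted Rand index.
#' @export
singlet_ari <- function(fit, truth) {
  singlet <- !truth$is_doublet
  mclust::adjustedRandIndex(assigned_donor(fit)[singlet],
                            truth$donor_index[singlet])
}
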