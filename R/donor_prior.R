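#' Fit with a complete reference genotype
#'
#' Reference-genotype mode: the data are restricted to variants with a
#' known genotype for every donor, the genotype posterior is clamped to
#' the relaxed reference distribution and never updated, and only the
#' allele rates and cell assignments iterate.
#'
#' @param data an [allele_counts()] object.
#' @param prior_U a [genotype_prior()] covering all K donors.
#' @param config a [fit_config()].
#' @param doublets run the doublet extension stage (default TRUE).
#' @return A `donor_fit` (see [fit_donors()]).
#' @export
fit_with_full_genotype <- function(data, prior_U, config = fit_config(),
                                   doublets = TRUE) {
  keep <- rowSums(prior_U$known_mask) == length(prior_U$donors)
  if (!any(keep)) stop("no variants with known genotype for all donors")
  ids <- prior_U$variant_ids[keep]
  sub <- subset_variants(data, ids)
  sel <- match(sub$variants$id, prior_U$variant_ids)
  pri <- genotype_prior(prior_U$U[sel, , , drop = FALSE], prior_U$relax_rate,
                        prior_U$known_mask[sel, , drop = FALSE],
                        sub$variants$id, prior_U$donors)
  fit_donors(sub, K = length(pri$donors), prior_U = pri, config = config,
             doublets = doublets, fix_genotype = TRUE)
}

#' Fit with genotypes known for a subset of donors
#'
#' Two-step procedure for partial references. Step 1 runs the
#' genotype-free fit. Step 2 aligns each reference donor to an inferred
#' component by genotype concordance (globally optimal one-to-one
#' matching). Step 3 replaces the genotype prior of the matched components
#' with the relaxed reference genotypes, keeping the uniform prior
#' elsewhere. Step 4 refits with this mixed prior; the second fit is
#' returned, with reference donor names attached to matched components.
#'
#' @param data an [allele_counts()] object.
#' @param prior_partial a [genotype_prior()] covering K0 < K donors.
#' @param K total number of donors in the pool.
#' @param config a [fit_config()].
#' @param match_threshold minimum concordance to accept a reference-donor
#'   match (default 0.7); donors below it are reported unmatched and not
#'   anchored.
#' @param doublets run the doublet extension stage in the second fit.
#' @return A `donor_fit` with an extra element `anchors`: a data.frame of
#'   reference donors, their matched component, concordance, and whether
#'   the match was accepted.
#' @export
fit_with_partial_genotype <- function(data, prior_partial, K,
                                      config = fit_config(),
                                      match_threshold = 0.7,
                                      doublets = TRUE) {
  K0 <- length(prior_partial$donors)
  if (K0 > K) stop("prior covers ", K0, " donors but K = ", K)
  fit1 <- fit_donors(data, K, config = config, doublets = FALSE)

  known <- donor_genotypes_from_prior(prior_partial)
  inferred <- donor_genotypes(fit1)
  cm <- genotype_concordance(known, inferred, min_umis = 10)
  mm <- match_donors(cm)
  if (anyDuplicated(mm$to[!is.na(mm$to)]))
    stop("two reference donors matched the same component; concordance:\n",
         paste(utils::capture.output(print(round(cm$values, 3))),
               collapse = "\n"))
  accepted <- !is.na(mm$score) & mm$score >= match_threshold
  if (any(!accepted))
    warning("reference donors not matched (concordance < ", match_threshold,
            "): ", paste(prior_partial$donors[!accepted], collapse = ", "))

  N <- nrow(data$A)
  sel <- match(data$variants$id, prior_partial$variant_ids)
  U <- array(1 / 3, dim = c(N, K, 3))
  known_mask <- matrix(FALSE, N, K)
  donor_ids <- paste0("inferred", seq_len(K))
  for (d in which(accepted)) {
    comp <- mm$to[d]
    rows <- which(!is.na(sel) & prior_partial$known_mask[sel, d])
    U[rows, comp, ] <- prior_partial$U[sel[rows], d, ]
    known_mask[rows, comp] <- TRUE
    donor_ids[comp] <- prior_partial$donors[d]
  }
  pri <- genotype_prior(U, prior_partial$relax_rate, known_mask,
                        data$variants$id, donor_ids)
  fit2 <- fit_donors(data, K, prior_U = pri, config = config,
                     doublets = doublets)
  fit2$anchors <- data.frame(reference = prior_partial$donors,
                             component = mm$to, concordance = mm$score,
                             accepted = accepted)
  fit2
}
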