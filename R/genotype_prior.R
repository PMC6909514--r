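#' Genotype prior matrix
#'
#' Per-variant, per-donor categorical prior over the three genotype states
#' {hom-REF, het, hom-ALT}. Where no genotype information is supplied the
#' prior is uniform (1/3, 1/3, 1/3). A hard genotype `t` supplied for a
#' (variant, donor) pair is relaxed to probability `1 - relax_rate` on state
#' `t` with the remaining mass split equally over the two other states, so
#' each row remains a proper distribution while the stated confidence in
#' the supplied call is preserved.
#'
#' @param U numeric array, variants x donors x 3, rows summing to 1.
#' @param relax_rate the relax rate xi in \[0, 1\].
#' @param known_mask logical variants x donors matrix; `TRUE` where a
#'   genotype was supplied.
#' @param variant_ids,donors dimension labels.
#' @return An object of class `genotype_prior`.
#' @export
genotype_prior <- function(U, relax_rate, known_mask, variant_ids, donors) {
  stopifnot(length(dim(U)) == 3, dim(U)[3] == 3,
            all(dim(known_mask) == dim(U)[1:2]),
            relax_rate >= 0, relax_rate <= 1)
  s <- U[, , 1] + U[, , 2] + U[, , 3]
  if (max(abs(s - 1)) > 1e-9) stop("prior rows must sum to 1")
  dimnames(U) <- list(variant_ids, donors, c("0", "1", "2"))
  structure(list(U = U, relax_rate = relax_rate, known_mask = known_mask,
                 variant_ids = variant_ids, donors = donors),
            class = "genotype_prior")
}

#' @export
print.genotype_prior <- function(x, ...) {
  cat("genotype_prior: ", length(x$variant_ids), " variants x ",
      length(x$donors), " donors; ", sum(x$known_mask), " known entries, ",
      "relax rate ", x$relax_rate, "\n", sep = "")
  invisible(x)
}

#' Uniform genotype prior
#'
#' @param variant_ids variant identifiers.
#' @param K number of donors (or a vector of donor names).
#' @return A [genotype_prior()] with every row at (1/3, 1/3, 1/3).
#' @export
uniform_genotype_prior <- function(variant_ids, K) {
  donors <- if (is.character(K)) K else paste0("donor", seq_len(K))
  N <- length(variant_ids); Kn <- length(donors)
  U <- array(1 / 3, dim = c(N, Kn, 3))
  genotype_prior(U, relax_rate = 0,
                 known_mask = matrix(FALSE, N, Kn), variant_ids, donors)
}

relax_hard_genotype <- function(t, relax_rate) {
  u <- rep(relax_rate / 2, 3)
  u[t + 1] <- 1 - relax_rate
  u
}

#' Build a genotype prior from a hard genotype matrix
#'
#' Convenience constructor used e.g. with simulator ground truth: encodes a
#' variants x donors matrix of hard genotypes (0/1/2, `NA` for unknown) as
#' a relaxed categorical prior.
#'
#' @param G integer matrix, variants x donors, values 0, 1, 2 or `NA`.
#' @param variant_ids variant identifiers (default taken from rownames).
#' @param donors donor names (default from colnames or `donor1..K`).
#' @param relax_rate relax rate xi (default 0.05).
#' @return A [genotype_prior()].
#' @export
genotype_prior_from_matrix <- function(G, variant_ids = rownames(G),
                                       donors = colnames(G),
                                       relax_rate = 0.05) {
  N <- nrow(G); K <- ncol(G)
  if (is.null(variant_ids)) variant_ids <- as.character(seq_len(N))
  if (is.null(donors)) donors <- paste0("donor", seq_len(K))
  U <- array(1 / 3, dim = c(N, K, 3))
  known <- !is.na(G)
  for (t in 0:2) {
    sel <- known & G == t
    u <- relax_hard_genotype(t, relax_rate)
    for (s in 1:3) {
      slab <- U[, , s]
      slab[sel] <- u[s]
      U[, , s] <- slab
    }
  }
  genotype_prior(U, relax_rate, known, variant_ids, donors)
}

parse_gt_state <- function(gt) {
  # "0/1", "1|0", "0/0", "./.", half-missing -> NA
  gt <- sub(":.*$", "", gt)
  a <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1", gt)
  b <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\2", gt)
  ok <- a %in% c("0", "1") & b %in% c("0", "1")
  out <- rep(NA_integer_, length(gt))
  out[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  out
}

parse_triplet <- function(x) {
  # comma-separated 3-vectors; returns n x 3 matrix with NA rows on failure
  parts <- strsplit(sub(":.*$", "", x), ",", fixed = TRUE)
  out <- matrix(NA_real_, length(x), 3)
  ok <- lengths(parts) == 3
  if (any(ok))
    out[ok, ] <- matrix(suppressWarnings(as.numeric(unlist(parts[ok]))),
                        ncol = 3, byrow = TRUE)
  out
}

#' Read donor genotypes from a VCF as a prior matrix
#'
#' Matches variants between the VCF and `variants` by exact
#' (chrom, pos, ref, alt) and encodes the requested FORMAT tag as a
#' categorical prior per (variant, donor): `GT` hard calls are relaxed by
#' `relax_rate`; `GP` probabilities are renormalized and used directly;
#' `GL` log10-likelihoods are exponentiated and renormalized. Unmatched
#' variants and missing calls get the uniform prior.
#'
#' @param vcf_path VCF 4.x file with the requested tag.
#' @param variants variant table to match against ([variant_table()]).
#' @param donors sample names to use (default: all samples in the VCF).
#' @param tag one of `"GT"`, `"GP"`, `"GL"`.
#' @param relax_rate relax rate xi applied to hard `GT` calls (default 0.05).
#' @return A [genotype_prior()] over `variants` x `donors`.
#' @export
read_genotype_prior <- function(vcf_path, variants, donors = NULL,
                                tag = c("GT", "GP", "GL"), relax_rate = 0.05) {
  tag <- match.arg(tag)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vkey <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
                sep = "_")
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!tag %in% fmt_keys)
    stop("FORMAT tag ", tag, " absent from ", vcf_path)
  gt <- vcfR::extract.gt(v, element = tag)
  if (is.null(donors)) donors <- colnames(gt)
  missing_d <- setdiff(donors, colnames(gt))
  if (length(missing_d))
    stop("donors absent from VCF: ", paste(missing_d, collapse = ", "))
  gt <- gt[, donors, drop = FALSE]
  idx <- match(variant_key(variants), vkey)
  if (all(is.na(idx))) stop("no variants in ", vcf_path,
                            " overlap the count data (matched by chrom,pos,ref,alt)")
  N <- nrow(variants); K <- length(donors)
  U <- array(1 / 3, dim = c(N, K, 3))
  known <- matrix(FALSE, N, K)
  hit <- which(!is.na(idx))
  n_missing <- 0L
  for (k in seq_len(K)) {
    calls <- gt[idx[hit], k]
    if (tag == "GT") {
      st <- parse_gt_state(calls)
      ok <- !is.na(st)
      for (t in 0:2) {
        rows <- hit[ok][st[ok] == t]
        if (length(rows)) {
          u <- relax_hard_genotype(t, relax_rate)
          U[rows, k, 1] <- u[1]; U[rows, k, 2] <- u[2]; U[rows, k, 3] <- u[3]
        }
      }
      known[hit[ok], k] <- TRUE
      n_missing <- n_missing + sum(!ok)
    } else {
      p <- parse_triplet(calls)
      if (tag == "GL") p <- 10^p
      s <- rowSums(p)
      ok <- !is.na(s) & s > 0
      p <- p / s
      U[hit[ok], k, ] <- p[ok, , drop = FALSE]
      known[hit[ok], k] <- TRUE
      n_missing <- n_missing + sum(!ok)
    }
  }
  if (n_missing > 0)
    message("read_genotype_prior: ", n_missing,
            " missing calls treated as unknown (uniform prior)")
  genotype_prior(U, relax_rate, known, variants$id, donors)
}
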