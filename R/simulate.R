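#' Simulation configuration for a pooled experiment
#'
#' Defines a generative pool at the count level: donor genotypes are drawn
#' under Hardy-Weinberg equilibrium from per-variant allele frequencies,
#' each singlet cell covers a Poisson number of variants (uniformly chosen)
#' with geometric per-variant UMI depth, ALT counts are binomial with a
#' per-genotype allele rate, and doublets are sums of two independently
#' drawn singlet profiles from distinct donors.
#'
#' @param n_donors number of donors K (default 8).
#' @param cells_per_donor scalar or length-K vector of singlet cells per
#'   donor (default 1000).
#' @param doublet_rate fraction of extra doublet droplets relative to the
#'   singlet count, or `"auto"` for `n_singlets / 100000` (default),
#'   mirroring droplet-platform loading behaviour.
#' @param n_variants number of variants (default 2000).
#' @param maf_range range of the uniform ALT allele-frequency law
#'   (default c(0.05, 0.5)).
#' @param mean_variants_per_cell Poisson mean of covered variants per cell
#'   (default 100).
#' @param mean_depth mean of the geometric (support 1, 2, ...) UMI depth
#'   per covered variant (default 2).
#' @param theta_truth ALT-allele rate per genotype state (default 0.01,
#'   0.5, 0.99, the prior means of the model).
#' @param seed integer seed; the simulation is fully determined by it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 8, cells_per_donor = 1000,
                       doublet_rate = "auto", n_variants = 2000,
                       maf_range = c(0.05, 0.5),
                       mean_variants_per_cell = 100, mean_depth = 2,
                       theta_truth = c(0.01, 0.5, 0.99), seed = 1) {
  if (n_donors < 1) stop("n_donors must be >= 1")
  stopifnot(n_variants >= 1, mean_variants_per_cell > 0, mean_depth >= 1,
            length(theta_truth) == 3, all(theta_truth >= 0),
            all(theta_truth <= 1))
  if (length(cells_per_donor) == 1)
    cells_per_donor <- rep(cells_per_donor, n_donors)
  stopifnot(length(cells_per_donor) == n_donors, all(cells_per_donor >= 1))
  if (!identical(doublet_rate, "auto"))
    stopifnot(doublet_rate >= 0, doublet_rate < 1)
  structure(list(n_donors = n_donors, cells_per_donor = cells_per_donor,
                 doublet_rate = doublet_rate, n_variants = n_variants,
                 maf_range = maf_range,
                 mean_variants_per_cell = mean_variants_per_cell,
                 mean_depth = mean_depth, theta_truth = theta_truth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one singlet expression profile for donor k: covered variants, depth, ALT
draw_profile <- function(k, cfg, G) {
  n_cov <- min(cfg$n_variants,
               max(1L, stats::rpois(1, cfg$mean_variants_per_cell)))
  idx <- sample.int(cfg$n_variants, n_cov)
  d <- 1L + stats::rgeom(n_cov, 1 / cfg$mean_depth)
  a <- stats::rbinom(n_cov, d, cfg$theta_truth[G[idx, k] + 1L])
  list(i = idx, d = d, a = a)
}

#' Simulate a pooled single-cell experiment with ground truth
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_pool` with `data` (an [allele_counts()]
#'   object) and `truth`: `donor_of_cell` (label, `"donorX,donorY"` for
#'   doublets), `is_doublet`, `donor_index` (first/single donor index),
#'   `genotypes` (variants x donors hard genotype matrix), `doublet_rate`,
#'   and `config`.
#' @export
simulate_pool <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$n_donors
  N <- cfg$n_variants
  donors <- paste0("donor", seq_len(K))
  maf <- stats::runif(N, cfg$maf_range[1], cfg$maf_range[2])
  G <- matrix(stats::rbinom(N * K, 2, rep(maf, K)), N, K,
              dimnames = list(NULL, donors))

  n_singlets <- sum(cfg$cells_per_donor)
  rate <- if (identical(cfg$doublet_rate, "auto")) n_singlets / 1e5 else
    cfg$doublet_rate
  n_doublets <- round(rate * n_singlets)
  M <- n_singlets + n_doublets

  donor1 <- rep(seq_len(K), cfg$cells_per_donor)
  donor2 <- rep(NA_integer_, M)
  if (n_doublets > 0) {
    d1 <- sample(donor1, n_doublets, replace = TRUE)
    d2 <- vapply(d1, function(k)
      sample(setdiff(seq_len(K), k), 1), integer(1))
    donor1 <- c(donor1, pmin(d1, d2))
    donor2[n_singlets + seq_len(n_doublets)] <- pmax(d1, d2)
  }

  ii <- vector("list", M); jj <- vector("list", M)
  dd <- vector("list", M); aa <- vector("list", M)
  for (j in seq_len(M)) {
    pr <- draw_profile(donor1[j], cfg, G)
    if (!is.na(donor2[j])) {
      pr2 <- draw_profile(donor2[j], cfg, G)
      pr <- list(i = c(pr$i, pr2$i), d = c(pr$d, pr2$d), a = c(pr$a, pr2$a))
    }
    ii[[j]] <- pr$i
    jj[[j]] <- rep.int(j, length(pr$i))
    dd[[j]] <- pr$d
    aa[[j]] <- pr$a
  }
  i <- unlist(ii); j <- unlist(jj)
  A <- Matrix::sparseMatrix(i = i, j = j, x = unlist(aa), dims = c(N, M))
  D <- Matrix::sparseMatrix(i = i, j = j, x = unlist(dd), dims = c(N, M))

  variants <- variant_table(chrom = "1", pos = seq_len(N) * 10L,
                            ref = "A", alt = "G")
  rownames(G) <- variants$id
  cells <- sprintf("cell%05d", seq_len(M))
  is_doublet <- !is.na(donor2)
  label <- ifelse(is_doublet,
                  paste(donors[donor1], donors[donor2], sep = ","),
                  donors[donor1])
  structure(list(
    data = allele_counts(A, D, variants, cells),
    truth = list(donor_of_cell = label, is_doublet = is_doublet,
                 donor_index = donor1, donor_index2 = donor2,
                 genotypes = G, doublet_rate = rate, config = cfg)),
    class = "sim_pool")
}

#' @export
print.sim_pool <- function(x, ...) {
  cat("sim_pool: ", ncol(x$data$A), " cells (",
      sum(x$truth$is_doublet), " doublets, rate ",
      format(x$truth$doublet_rate, digits = 3), "), ",
      nrow(x$data$A), " variants, K = ", ncol(x$truth$genotypes), "\n",
      sep = "")
  invisible(x)
}

#' Write a simulated pool to disk
#'
#' Emits the sparse pileup layout ([write_cell_counts()]) plus a
#' `truth.tsv` table (cell, donor, is_doublet) and a `GT_truth.vcf` with
#' the true donor genotypes as GT calls.
#'
#' @param sim a [simulate_pool()] result.
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_pool <- function(sim, dir_path) {
  write_cell_counts(sim$data, dir_path)
  utils::write.table(
    data.frame(cell = sim$data$cells, donor = sim$truth$donor_of_cell,
               is_doublet = sim$truth$is_doublet),
    file.path(dir_path, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotype_vcf(sim$truth$genotypes, sim$data$variants,
                     file.path(dir_path, "GT_truth.vcf"))
  invisible(dir_path)
}

write_genotype_vcf <- function(G, variants, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=demuxpool",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(G)), collapse = "\t")), con)
  body <- matrix(ifelse(is.na(G), "./.", gt_str[G + 1L]), nrow(G), ncol(G))
  writeLines(paste(variants$chrom, variants$pos, variants$id, variants$ref,
                   variants$alt, ".", "PASS", ".", "GT",
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Binomial thinning of coverage
#'
#' Emulates read subsampling: every sequenced UMI is kept independently
#' with probability `fraction`, thinning ALT and REF counts separately.
#'
#' @param data an [allele_counts()] object.
#' @param fraction keep probability in (0, 1].
#' @param seed optional seed for the thinning draw.
#' @return The thinned [allele_counts()] object (zero-depth entries
#'   dropped).
#' @export
thin_coverage <- function(data, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  trip <- Matrix::summary(data$D)
  a <- data$A[cbind(trip$i, trip$j)]
  ref <- trip$x - a
  a2 <- stats::rbinom(length(a), a, fraction)
  r2 <- stats::rbinom(length(ref), ref, fraction)
  keep <- (a2 + r2) > 0
  N <- nrow(data$A); M <- ncol(data$A)
  A <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                            x = a2[keep], dims = c(N, M))
  D <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                            x = (a2 + r2)[keep], dims = c(N, M))
  allele_counts(A, D, data$variants, data$cells)
}
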