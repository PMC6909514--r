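#' Write the per-cell assignment table
#'
#' Tab-separated table, one row per cell: `cell`, `donor_id` (the argmax
#' donor; `"doublet"` if `prob_doublet` exceeds its threshold,
#' `"unassigned"` if `prob_max` does not exceed its threshold),
#' `prob_max`, `prob_doublet`, `n_vars` (covered variants in the cell) and
#' `best_doublet_pair`.
#'
#' @param fit a `donor_fit`.
#' @param cells cell barcodes (in the fit's cell order).
#' @param path output file.
#' @param singlet_threshold `prob_max` must exceed this for a singlet call
#'   (default 0.9).
#' @param doublet_threshold `prob_doublet` above this calls a doublet
#'   (default 0.9).
#' @return The assignment data.frame, invisibly.
#' @export
write_assignments <- function(fit, cells, path, singlet_threshold = 0.9,
                              doublet_threshold = 0.9) {
  stopifnot(length(cells) == nrow(fit$r))
  donor <- fit$donor_ids[assigned_donor(fit)]
  donor[fit$prob_max <= singlet_threshold] <- "unassigned"
  donor[fit$prob_doublet > doublet_threshold] <- "doublet"
  tab <- data.frame(cell = cells, donor_id = donor,
                    prob_max = fit$prob_max,
                    prob_doublet = fit$prob_doublet,
                    n_vars = fit$n_vars,
                    best_doublet_pair = fit$best_doublet_pair)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write inferred donor genotypes as a VCF
#'
#' One sample column per inferred donor, with `GT` the hard posterior
#' call, `GP` the posterior probability 3-vector and `DP` the rounded
#' expected per-donor depth. Entries with an uninformative posterior (no
#' coverage) are written as missing (`./.`).
#'
#' @param fit a `donor_fit`.
#' @param data the [allele_counts()] object the fit was run on.
#' @param path output VCF file.
#' @return `path`, invisibly.
#' @export
write_donor_vcf <- function(fit, data, path) {
  stopifnot(all(fit$variant_ids == data$variants$id))
  K <- fit$n_donors
  N <- length(fit$variant_ids)
  gt_str <- c("0/0", "0/1", "1/1")
  hard <- hard_calls(fit$g)
  dp <- round(fit$depth[, seq_len(K), drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=demuxpool",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Hard posterior genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Posterior genotype probabilities (0/0,0/1,1/1)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Expected aggregate UMI depth for the donor\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", fit$donor_ids), collapse = "\t")), con)
  cols <- lapply(seq_len(K), function(k) {
    gp <- sapply(1:3, function(s) fit$g[, k, s])
    gp <- matrix(gp, N, 3)
    gt <- ifelse(is.na(hard[, k]), "./.", gt_str[hard[, k] + 1L])
    paste0(gt, ":",
           apply(round(gp, 6), 1, paste, collapse = ","), ":", dp[, k])
  })
  body <- do.call(paste, c(list(data$variants$chrom, data$variants$pos,
                                data$variants$id, data$variants$ref,
                                data$variants$alt, ".", "PASS", ".",
                                "GT:GP:DP"), cols, sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' End-to-end demultiplexing pipeline
#'
#' Reads a sparse pileup directory, filters variants, fits the model
#' (genotype-free, or with a full/partial reference VCF), runs doublet
#' detection, and writes `donor_ids.tsv`, `GT_donors.vcf` and
#' `fit_summary.json` into `out_dir`.
#'
#' @param count_dir pileup directory for [read_cell_counts()].
#' @param n_donors pool size K.
#' @param out_dir output directory (created if needed).
#' @param donor_vcf optional reference genotype VCF; if it holds fewer
#'   samples than `n_donors`, the partial two-step mode is used.
#' @param vcf_tag FORMAT tag to read from `donor_vcf` (default GT).
#' @param relax_rate prior relax rate xi for reference genotypes
#'   (default 0.05).
#' @param config a [fit_config()].
#' @param min_total_umis,min_minor_frac variant filters
#'   ([filter_variants()]).
#' @param singlet_threshold,doublet_threshold assignment thresholds
#'   ([write_assignments()]).
#' @return The `donor_fit`, invisibly.
#' @export
demux <- function(count_dir, n_donors, out_dir, donor_vcf = NULL,
                  vcf_tag = "GT", relax_rate = 0.05, config = fit_config(),
                  min_total_umis = 20, min_minor_frac = 0.10,
                  singlet_threshold = 0.9, doublet_threshold = 0.9) {
  if (n_donors < 1) stop("n_donors must be >= 1")
  data <- read_cell_counts(count_dir)
  data <- filter_variants(data, min_total_umis, min_minor_frac)
  mode <- "genotype-free"
  if (is.null(donor_vcf)) {
    fit <- fit_donors(data, n_donors, config = config)
  } else {
    prior <- read_genotype_prior(donor_vcf, data$variants, tag = vcf_tag,
                                 relax_rate = relax_rate)
    if (length(prior$donors) >= n_donors) {
      mode <- "full-reference"
      fit <- fit_with_full_genotype(data, prior, config = config)
      if (length(prior$donors) > n_donors)
        warning("reference VCF holds ", length(prior$donors),
                " samples; all were used")
    } else {
      mode <- "partial-reference"
      fit <- fit_with_partial_genotype(data, prior, n_donors,
                                       config = config)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_cells <- if (mode == "full-reference") data$cells else data$cells
  write_assignments(fit, fit_cells, file.path(out_dir, "donor_ids.tsv"),
                    singlet_threshold, doublet_threshold)
  fit_data <- if (length(fit$variant_ids) == nrow(data$A)) data else
    subset_variants(data, fit$variant_ids)
  write_donor_vcf(fit, fit_data, file.path(out_dir, "GT_donors.vcf"))
  summary <- list(
    mode = mode, n_donors = fit$n_donors, n_cells = length(fit$n_vars),
    n_variants = length(fit$variant_ids), elbo = fit$elbo,
    iterations = length(fit$elbo_trace), converged = fit$converged,
    eta = fit$eta, seed = fit$seed,
    settings = list(min_total_umis = min_total_umis,
                    min_minor_frac = min_minor_frac,
                    singlet_threshold = singlet_threshold,
                    doublet_threshold = doublet_threshold,
                    relax_rate = relax_rate,
                    n_init = config$n_init,
                    warmup_iters = config$warmup_iters,
                    max_iters = config$max_iters,
                    elbo_tol = config$elbo_tol),
    n_doublet_calls = sum(fit$prob_doublet > doublet_threshold),
    elbo_trace = fit$elbo_trace)
  jsonlite::write_json(summary, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
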