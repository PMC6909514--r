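#' Allele count data for a pooled experiment
#'
#' Container pairing two sparse variants-by-cells matrices: `A`, UMI counts
#' supporting the alternative allele, and `D`, total UMI depth (ALT + REF),
#' together with the variant table and the cell barcodes. These counts are
#' the sole cell-level evidence used by the demultiplexing model.
#'
#' @param A sparse integer matrix, variants x cells, ALT-allele UMI counts.
#' @param D sparse integer matrix, variants x cells, total UMI depth. Every
#'   stored entry of `A` must have a (larger or equal) entry in `D`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `id`; one row per row of `A`/`D`. See [variant_table()].
#' @param cells character vector of cell barcodes, one per column.
#'
#' @return An object of class `allele_counts`: a list with elements `A`,
#'   `D`, `variants`, `cells`.
#' @export
allele_counts <- function(A, D, variants, cells) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  D <- methods::as(methods::as(D, "CsparseMatrix"), "generalMatrix")
  A <- Matrix::drop0(A)
  D <- Matrix::drop0(D)
  if (!all(dim(A) == dim(D)))
    stop("dimension mismatch between ALT matrix (", paste(dim(A), collapse = "x"),
         ") and depth matrix (", paste(dim(D), collapse = "x"), ")")
  if (nrow(A) != nrow(variants))
    stop("dimension mismatch: ", nrow(A), " matrix rows vs ",
         nrow(variants), " variants")
  if (ncol(A) != length(cells))
    stop("dimension mismatch: ", ncol(A), " matrix columns vs ",
         length(cells), " cell barcodes")
  if (length(A@x) && any(A@x < 0)) stop("negative ALT counts")
  if (length(D@x) && any(D@x < 0)) stop("negative depth counts")
  B <- D - A
  bad <- which(B@x < -1e-9)
  if (length(bad)) {
    trip <- Matrix::summary(B)
    trip <- trip[trip$x < -1e-9, , drop = FALSE]
    stop("integrity error: ALT count exceeds depth (or depth entry missing) at ",
         nrow(trip), " entries, e.g. variant ", trip$i[1], ", cell ", trip$j[1])
  }
  stopifnot(anyDuplicated(variants$id) == 0)
  structure(list(A = A, D = D, variants = variants, cells = as.character(cells)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts: ", nrow(x$A), " variants x ", ncol(x$A), " cells; ",
      length(x$D@x), " covered entries (",
      format(100 * length(x$D@x) / prod(dim(x$D)), digits = 3),
      "% dense), ", sum(x$D@x), " total UMIs\n", sep = "")
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$A)

#' Build a variant table
#'
#' @param chrom,pos,ref,alt vectors describing bi-allelic SNVs (`pos` is the
#'   1-based coordinate).
#' @param id optional variant identifiers; entries that are `NA` or `"."`
#'   are replaced by `chrom_pos_ref_alt`.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @export
variant_table <- function(chrom, pos, ref, alt, id = NULL) {
  chrom <- as.character(chrom); ref <- as.character(ref)
  alt <- as.character(alt); pos <- as.integer(pos)
  key <- paste(chrom, pos, ref, alt, sep = "_")
  if (is.null(id)) id <- key
  id <- as.character(id)
  id[is.na(id) | id == "."] <- key[is.na(id) | id == "."]
  stopifnot(all(pos >= 1), all(ref != alt))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, id = id,
             stringsAsFactors = FALSE)
}

variant_key <- function(variants)
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "_")

is_biallelic_snv <- function(variants) {
  nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    !grepl(",", variants$alt, fixed = TRUE) & variants$ref != variants$alt
}

#' Read sparse allele counts from a pileup output directory
#'
#' Reads the standard sparse pileup layout: two Matrix-Market triplet files
#' for ALT counts and total depth, a sites-only VCF listing the variants,
#' and a one-barcode-per-line cell list. Variants that are not bi-allelic
#' SNVs are dropped (with their matrix rows).
#'
#' @param dir_path directory containing the four files.
#' @param ad_file,dp_file,vcf_file,barcode_file file names within
#'   `dir_path`; defaults follow the common pileup tool naming.
#' @return An [allele_counts()] object.
#' @export
read_cell_counts <- function(dir_path,
                             ad_file = "cellSNP.tag.AD.mtx",
                             dp_file = "cellSNP.tag.DP.mtx",
                             vcf_file = NULL,
                             barcode_file = "cellSNP.samples.tsv") {
  if (!dir.exists(dir_path)) stop("count directory not found: ", dir_path)
  if (is.null(vcf_file)) {
    vcf_file <- if (file.exists(file.path(dir_path, "cellSNP.base.vcf")))
      "cellSNP.base.vcf" else "cellSNP.base.vcf.gz"
  }
  paths <- file.path(dir_path, c(ad_file, dp_file, vcf_file, barcode_file))
  for (p in paths) if (!file.exists(p)) stop("missing input file: ", p)
  A <- tryCatch(Matrix::readMM(paths[1]),
                error = function(e) stop("failed to read ", paths[1], ": ",
                                         conditionMessage(e)))
  D <- tryCatch(Matrix::readMM(paths[2]),
                error = function(e) stop("failed to read ", paths[2], ": ",
                                         conditionMessage(e)))
  variants <- read_variant_vcf(paths[3])
  cells <- readLines(paths[4])
  cells <- cells[nzchar(cells)]
  if (nrow(A) != nrow(variants))
    stop("dimension mismatch: ", paths[1], " has ", nrow(A),
         " rows but ", paths[3], " lists ", nrow(variants), " variants")
  if (ncol(A) != length(cells))
    stop("dimension mismatch: ", paths[1], " has ", ncol(A),
         " columns but ", paths[4], " lists ", length(cells), " barcodes")
  keep <- is_biallelic_snv(variants)
  out <- allele_counts(A[keep, , drop = FALSE], D[keep, , drop = FALSE],
                       variants[keep, , drop = FALSE], cells)
  out
}

#' Read the variant sites of a VCF into a variant table
#'
#' @param path VCF file (sites-only or with samples; plain or gzipped).
#' @return data.frame as produced by [variant_table()].
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variant_table(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                ref = fix[, "REF"], alt = fix[, "ALT"], id = fix[, "ID"])
}

#' Write allele counts in the sparse pileup layout
#'
#' Inverse of [read_cell_counts()]: writes the two Matrix-Market files, a
#' sites-only VCF and the barcode list into `dir_path`.
#'
#' @param data an [allele_counts()] object.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_cell_counts <- function(data, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(data$A, file.path(dir_path, "cellSNP.tag.AD.mtx"))
  Matrix::writeMM(data$D, file.path(dir_path, "cellSNP.tag.DP.mtx"))
  write_sites_vcf(data$variants, file.path(dir_path, "cellSNP.base.vcf"))
  writeLines(data$cells, file.path(dir_path, "cellSNP.samples.tsv"))
  invisible(dir_path)
}

write_sites_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=demuxpool",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(paste(variants$chrom, variants$pos, variants$id, variants$ref,
                   variants$alt, ".", "PASS", ".", sep = "\t"), con)
  invisible(path)
}

#' Filter variants by coverage and minor-allele content
#'
#' Keeps variants with at least `min_total_umis` UMIs summed across all
#' cells and whose minor (second most abundant) allele carries at least
#' `min_minor_frac` of those UMIs. Both filters target variants that are
#' either barely observed or close to monomorphic in the pool, which carry
#' no donor-discriminating signal.
#'
#' @param data an [allele_counts()] object.
#' @param min_total_umis minimum total UMIs across cells (default 20).
#' @param min_minor_frac minimum minor-allele UMI fraction (default 0.10).
#' @return The filtered [allele_counts()] object, variant order preserved.
#' @export
filter_variants <- function(data, min_total_umis = 20, min_minor_frac = 0.10) {
  tot <- Matrix::rowSums(data$D)
  alt <- Matrix::rowSums(data$A)
  minor <- pmin(alt, tot - alt) / pmax(tot, 1)
  keep <- tot >= min_total_umis & minor >= min_minor_frac
  if (!any(keep))
    stop("all ", length(keep), " variants removed by filtering; ",
         "consider relaxing min_total_umis/min_minor_frac")
  allele_counts(data$A[keep, , drop = FALSE], data$D[keep, , drop = FALSE],
                data$variants[keep, , drop = FALSE], data$cells)
}

#' Subset allele counts to a set of variant ids
#'
#' @param data an [allele_counts()] object.
#' @param ids variant ids to keep (order taken from `data`).
#' @return The subsetted [allele_counts()] object.
#' @export
subset_variants <- function(data, ids) {
  keep <- data$variants$id %in% ids
  if (!any(keep)) stop("no overlapping variants")
  allele_counts(data$A[keep, , drop = FALSE], data$D[keep, , drop = FALSE],
                data$variants[keep, , drop = FALSE], data$cells)
}
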