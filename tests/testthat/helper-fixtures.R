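# shared small simulation settings used by several test files; sizes are
# kept small so the whole suite stays fast
small_cfg <- function(seed, n_donors = 4, cells_per_donor = 120,
                      n_variants = 400, ...) {
  sim_config(n_donors = n_donors, cells_per_donor = cells_per_donor,
             n_variants = n_variants, seed = seed, ...)
}

quick_fit_config <- function(seed, n_init = 5, ...) {
  fit_config(n_init = n_init, seed = seed, ...)
}

# tiny 3 variants x 2 cells fixture matching the documented layout
tiny_counts <- function() {
  A <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(3, 2))
  D <- Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(3, 2))
  allele_counts(A, D, variant_table(c("1", "1", "2"), c(10, 20, 30),
                                    c("A", "C", "G"), c("G", "T", "A")),
                c("AAAC", "GGGT"))
}
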