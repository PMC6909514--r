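# brute-force combination over the 9 genotype pairs: a doublet of
# genotypes (gx, gy) shows average dosage (gx + gy) / 2
combine_by_enumeration <- function(x, y) {
  states <- c(0, 0.5, 1, 1.5, 2)
  out <- setNames(numeric(5), as.character(states))
  for (gx in 0:2) for (gy in 0:2) {
    t <- (gx + gy) / 2
    out[as.character(t)] <- out[as.character(t)] + x[gx + 1] * y[gy + 1]
  }
  out
}

test_that("genotype combination matches the 9-case enumeration", {
  expect_equal(combine_genotype_probs(c(1, 0, 0), c(1, 0, 0)),
               c(1, 0, 0, 0, 0), ignore_attr = TRUE)
  # hom-REF x hom-ALT looks heterozygous
  expect_equal(combine_genotype_probs(c(1, 0, 0), c(0, 0, 1))[["1"]], 1)
  set.seed(4)
  for (s in 1:1000) {
    x <- as.vector(prop.table(rexp(3)))
    y <- as.vector(prop.table(rexp(3)))
    got <- combine_genotype_probs(x, y)
    expect_equal(got, combine_by_enumeration(x, y), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(got, combine_genotype_probs(y, x))  # symmetry
  }
})

test_that("pseudo-genotype beta parameters satisfy both moment constraints", {
  # from the default priors beta(0.3, 29.7) and beta(3, 3):
  # mean 0.5*(0.01 + 0.5) = 0.255, concentration sqrt(30 * 6)
  th <- doublet_theta_params(theta_prior())
  expect_equal(th$states, c(0, 0.5, 1, 1.5, 2))
  m05 <- th$alpha[2] / (th$alpha[2] + th$beta[2])
  expect_equal(m05, 0.255, tolerance = 1e-12)
  expect_equal(th$alpha[2] + th$beta[2], sqrt(180), tolerance = 1e-12)
  expect_equal(th$alpha[2], 3.4212, tolerance = 1e-4)
  expect_equal(th$beta[2], 9.9952, tolerance = 1e-4)

  # identical components are a fixed point
  same <- theta_dist(c(5, 5, 5), c(2, 2, 2))
  ths <- doublet_theta_params(same)
  expect_equal(ths$alpha[2], 5, tolerance = 1e-10)
  expect_equal(ths$beta[2], 2, tolerance = 1e-10)

  # constraint residuals on random parameter draws
  set.seed(8)
  for (s in 1:50) {
    base <- theta_dist(rexp(3) * 10 + 0.1, rexp(3) * 10 + 0.1)
    ext <- doublet_theta_params(base)
    m <- base$alpha / (base$alpha + base$beta)
    conc <- base$alpha + base$beta
    for (slot in c(2, 4)) {
      mean_got <- ext$alpha[slot] / (ext$alpha[slot] + ext$beta[slot])
      conc_got <- (ext$alpha[slot] + ext$beta[slot])^2
      i <- c(slot / 2, slot / 2 + 1)  # neighbouring pure-state indices
      expect_lt(abs(mean_got - mean(m[i])), 1e-10)
      expect_lt(abs(conc_got - prod(conc[i])), 1e-7)
    }
  }
})

test_that("the extension enumerates pairs and splits the prior per eta", {
  g <- demuxpool:::random_g_init(5, 8)
  ext <- build_doublet_extension(g, theta_prior(), eta = 0.05, K = 8, M = 100)
  expect_identical(ncol(ext$pairs), 28L)                 # (K-1)K/2
  expect_true(all(ext$pairs[1, ] < ext$pairs[2, ]))
  expect_equal(sum(ext$pi_extended), 1)

  ext2 <- build_doublet_extension(g[, 1:4, , drop = FALSE], theta_prior(),
                                  eta = 0.05, K = 4, M = 100)
  expect_equal(ext2$pi_extended,
               c(rep(0.95 / 4, 4), rep(0.05 / 6, 6)))

  # auto eta follows the loading rule M / 100,000
  ext3 <- build_doublet_extension(g, theta_prior(), eta = "auto", K = 8,
                                  M = 8000)
  expect_equal(ext3$eta, 0.08)

  expect_warning(build_doublet_extension(g[, 1, , drop = FALSE],
                                         theta_prior(), 0.1, K = 1, M = 10),
                 "K >= 2")
})

test_that("doublet posteriors behave at the evidence extremes", {
  sim <- simulate_pool(small_cfg(12, cells_per_donor = 150,
                                 n_variants = 500))
  data <- filter_variants(sim$data)
  fit <- fit_donors(data, 4, config = quick_fit_config(3))

  # true doublets are flagged and attributed to the right donor pair
  dbl <- which(sim$truth$is_doublet)
  expect_gt(mean(fit$prob_doublet[dbl] > 0.9), 0.9)
  # component labels are arbitrary: map true donors to fit components
  mm <- match_donors(genotype_concordance(
    donor_genotypes_from_matrix(sim$truth$genotypes),
    donor_genotypes(fit)))
  comp_of <- mm$to
  pair_truth <- vapply(dbl, function(j) {
    p <- sort(comp_of[c(sim$truth$donor_index[j],
                        sim$truth$donor_index2[j])])
    paste(fit$donor_ids[p], collapse = ",")
  }, "")
  called <- fit$prob_doublet[dbl] > 0.9
  expect_gt(mean(fit$best_doublet_pair[dbl][called] ==
                   pair_truth[called]), 0.9)

  # singlet cells keep high prob_max and low prob_doublet
  sgl <- which(!sim$truth$is_doublet)
  expect_gt(mean(fit$prob_max[sgl] > 0.9), 0.95)

  # a zero-coverage cell sits exactly at the prior: prob_doublet = eta
  data0 <- data
  zero_cell <- 1
  keep <- Matrix::summary(data$D)$j != zero_cell
  tripA <- Matrix::summary(data$A); tripD <- Matrix::summary(data$D)
  data0 <- allele_counts(
    Matrix::sparseMatrix(i = tripA$i[tripA$j != zero_cell],
                         j = tripA$j[tripA$j != zero_cell],
                         x = tripA$x[tripA$j != zero_cell],
                         dims = dim(data$A)),
    Matrix::sparseMatrix(i = tripD$i[tripD$j != zero_cell],
                         j = tripD$j[tripD$j != zero_cell],
                         x = tripD$x[tripD$j != zero_cell],
                         dims = dim(data$D)),
    data$variants, data$cells)
  ext <- build_doublet_extension(fit$g, fit$theta, eta = 0.07, K = 4,
                                 M = ncol(data$A))
  ra <- assign_extended(data0, ext, fit$g, fit$theta)
  expect_equal(ra$prob_doublet[zero_cell], 0.07, tolerance = 1e-9)
})
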