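test_that("concordance is 1 on the diagonal for identical profiles", {
  set.seed(1)
  G <- matrix(sample(0:2, 200 * 3, TRUE), 200, 3)
  a <- donor_genotypes_from_matrix(G)
  cm <- genotype_concordance(a, a)
  expect_equal(diag(cm$values), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(cm$n_shared_variants == 200))
})

test_that("independent random genotypes concord at about one third", {
  set.seed(2)
  a <- donor_genotypes_from_matrix(matrix(sample(0:2, 1000, TRUE), 1000, 1))
  b <- donor_genotypes_from_matrix(matrix(sample(0:2, 1000, TRUE), 1000, 1))
  # uniform states: P(agree) = 3 * (1/3)^2 = 1/3; binomial sd ~ 0.015
  cm_val <- genotype_concordance(a, b)$values[1, 1]
  expect_lt(abs(cm_val - 1 / 3), 0.05)
})

test_that("the depth filter and missing calls restrict the comparison", {
  G <- cbind(c(0, 1, 2, NA), c(0, 2, 2, 1))
  a <- donor_genotypes_from_matrix(G[, 1, drop = FALSE])
  b <- donor_genotypes_from_matrix(G[, 2, drop = FALSE])
  a$depth <- matrix(c(20, 20, 5, 20), 4, 1)   # variant 3 under-covered
  cm <- genotype_concordance(a, b, min_umis = 10)
  # comparable variants: 1 (agree), 2 (disagree); 3 filtered, 4 is NA
  expect_equal(cm$values[1, 1], 0.5)
  expect_equal(cm$n_shared_variants[1, 1], 2L)
  # no qualifying variants -> NA with count 0
  a$depth[] <- 0
  cm0 <- genotype_concordance(a, b, min_umis = 10)
  expect_true(is.na(cm0$values[1, 1]))
  expect_equal(cm0$n_shared_variants[1, 1], 0L)
})

test_that("donor matching recovers permutations and breaks ties low", {
  P <- diag(4)[, c(3, 1, 4, 2)]
  mm <- match_donors(P)
  expect_equal(mm$to, c(2L, 4L, 1L, 3L))
  expect_equal(mm$total, 4)

  # all-equal matrix: deterministic lowest-index matching
  mm2 <- match_donors(matrix(1, 3, 3))
  expect_equal(mm2$to, 1:3)

  # rectangular: partial matching of the smaller side
  mm3 <- match_donors(rbind(c(0.9, 0.1, 0.2)))
  expect_equal(mm3$to, 1L)
})

test_that("donor matching equals factorial brute force up to K = 8", {
  set.seed(5)
  for (K in c(3, 5, 8)) {
    cm <- matrix(runif(K * K), K, K)
    mm <- match_donors(cm)
    perms <- all_perms(K)
    scores <- apply(perms, 1, function(p) sum(cm[cbind(1:K, p)]))
    expect_equal(mm$total, max(scores), tolerance = 1e-12)
  }
})

test_that("a perfectly split two-donor panel needs one variant", {
  G <- cbind(c(0, 1, 1), c(2, 1, 1))  # donors differ only at variant 1
  g <- donor_genotypes_from_matrix(G, ids = c("v1", "v2", "v3"))
  sel <- select_discriminatory_variants(g)
  expect_identical(sel$variants, "v1")
  expect_true(sel$complete)
  expect_equal(sel$entropy, 1)  # H = log2(2)
})

test_that("orthogonal splitting patterns reach full entropy in two picks", {
  # 2 variants x 4 donors with orthogonal splitting patterns
  G <- cbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  g <- donor_genotypes_from_matrix(G, ids = c("v1", "v2"))
  sel <- select_discriminatory_variants(g)
  expect_setequal(sel$variants, c("v1", "v2"))
  expect_true(sel$complete)
  expect_equal(sel$entropy, c(1, 2))  # 1 bit then log2(4)
  expect_equal(sel$target_entropy, 2)
})

test_that("entropy grows monotonically and indistinct donors warn", {
  sim <- simulate_pool(small_cfg(31, n_donors = 6, cells_per_donor = 60,
                                 n_variants = 300))
  g <- donor_genotypes_from_matrix(sim$truth$genotypes)
  sel <- select_discriminatory_variants(g, min_umis = 0)
  expect_true(all(diff(c(0, sel$entropy)) > 0))
  expect_lte(max(sel$entropy), log2(6) + 1e-9)
  expect_true(sel$complete)

  # two identical donors can never be split
  G <- cbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0))
  gdup <- donor_genotypes_from_matrix(G)
  expect_warning(seld <- select_discriminatory_variants(gdup),
                 "unresolved")
  expect_false(seld$complete)
})

test_that("the hom-ALT pre-filter removes uninformative candidates", {
  G <- rbind(c(2, 2, 2), c(0, 1, 2))
  g <- donor_genotypes_from_matrix(G, ids = c("homalt", "good"))
  sel <- select_discriminatory_variants(g, exclude_all_hom_alt = TRUE)
  expect_false("homalt" %in% sel$variants)
  expect_true(sel$complete)
})

test_that("donors split across two fits are re-linked by concordance", {
  sim <- simulate_pool(small_cfg(41, n_donors = 3, cells_per_donor = 160,
                                 n_variants = 400))
  data <- filter_variants(sim$data)
  half1 <- seq(1, ncol(data$A), 2)
  half2 <- seq(2, ncol(data$A), 2)
  sub <- function(idx) allele_counts(data$A[, idx], data$D[, idx],
                                     data$variants, data$cells[idx])
  fa <- fit_donors(sub(half1), 3, config = quick_fit_config(4),
                   doublets = FALSE)
  fb <- fit_donors(sub(half2), 3, config = quick_fit_config(9),
                   doublets = FALSE)
  cm <- genotype_concordance(donor_genotypes(fa), donor_genotypes(fb))
  mm <- match_donors(cm)
  matched <- cm$values[cbind(1:3, mm$to)]
  expect_true(all(matched > 0.9))
  others <- cm$values
  others[cbind(1:3, mm$to)] <- NA
  expect_true(all(others < 0.8, na.rm = TRUE))
  # the matching is the true cell-label correspondence
  ta <- sim$truth$donor_index[half1][!sim$truth$is_doublet[half1]]
  tb <- sim$truth$donor_index[half2][!sim$truth$is_doublet[half2]]
  map_a <- sapply(1:3, function(k)
    which.max(table(factor(ta[assigned_donor(fa)[!sim$truth$is_doublet[half1]] == k],
                           levels = 1:3))))
  map_b <- sapply(1:3, function(k)
    which.max(table(factor(tb[assigned_donor(fb)[!sim$truth$is_doublet[half2]] == k],
                           levels = 1:3))))
  expect_equal(map_b[mm$to], map_a, ignore_attr = TRUE)
})
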