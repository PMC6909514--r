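sharp_theta <- function() theta_dist(c(1, 300, 599) + 0.5,
                                     c(599, 300, 1) + 0.5)

test_that("assignment update resolves a discriminating homozygote", {
  # donor 1 hom-REF, donor 2 hom-ALT at the single variant; cell is 5/5 ALT
  data <- dense_counts(matrix(5), matrix(5))
  g <- array(0, c(1, 2, 3))
  g[1, 1, 1] <- 1; g[1, 2, 3] <- 1
  r <- update_assignment(data, g, sharp_theta(), pi = c(0.5, 0.5))
  expect_gt(r[1, 2], 0.999)

  # zero-coverage cell falls back to the prior
  data0 <- dense_counts(matrix(0, 1, 1), matrix(0, 1, 1))
  pi <- c(0.3, 0.7)
  r0 <- update_assignment(data0, g, sharp_theta(), pi)
  expect_equal(r0[1, ], pi)
})

test_that("assignment update equals an independent scalar softmax", {
  inst <- random_tiny_instance(2, 1, 2, seed = 9)
  g <- demuxpool:::random_g_init(2, 2)
  theta <- theta_dist(c(2, 4, 9), c(8, 4, 1))
  r <- update_assignment(inst$data, g, theta, inst$pi)
  A <- as.matrix(inst$data$A); B <- as.matrix(inst$data$D) - A
  el1 <- digamma(theta$alpha) - digamma(theta$alpha + theta$beta)
  el0 <- digamma(theta$beta) - digamma(theta$alpha + theta$beta)
  lw <- numeric(2)
  for (k in 1:2) {
    s <- log(inst$pi[k])
    for (i in 1:2) for (t in 1:3)
      s <- s + g[i, k, t] * (A[i, 1] * el1[t] + B[i, 1] * el0[t])
    lw[k] <- s
  }
  expect_equal(r[1, ], exp(lw) / sum(exp(lw)), tolerance = 1e-12)
})

test_that("genotype update follows the evidence and respects the prior", {
  # 3 cells hard-assigned to donor 1, all reads ALT at the variant
  data <- dense_counts(matrix(c(4, 4, 4), 1, 3), matrix(c(4, 4, 4), 1, 3))
  r <- cbind(c(1, 1, 1), c(0, 0, 0))
  U <- array(1 / 3, c(1, 2, 3))
  g <- update_genotype(data, r, sharp_theta(), U)
  expect_gt(g[1, 1, 3], 0.999)          # pure ALT evidence -> hom-ALT
  expect_equal(g[1, 2, ], rep(1 / 3, 3))  # no cells -> prior

  # a degenerate one-hot prior clamps the posterior whatever the data say
  U2 <- array(0, c(1, 2, 3)); U2[, , 1] <- 1
  g2 <- update_genotype(data, r, sharp_theta(), U2)
  expect_equal(g2[1, 1, ], c(1, 0, 0))
})

test_that("genotype update equals an independent scalar softmax", {
  inst <- random_tiny_instance(2, 3, 2, seed = 17)
  theta <- theta_dist(c(2, 4, 9), c(8, 4, 1))
  set.seed(2)
  r <- prop.table(matrix(rexp(6), 3, 2), 1)
  g <- update_genotype(inst$data, r, theta, inst$U)
  A <- as.matrix(inst$data$A); B <- as.matrix(inst$data$D) - A
  el1 <- digamma(theta$alpha) - digamma(theta$alpha + theta$beta)
  el0 <- digamma(theta$beta) - digamma(theta$alpha + theta$beta)
  for (i in 1:2) for (k in 1:2) {
    lw <- numeric(3)
    for (t in 1:3) {
      s <- log(inst$U[i, k, t])
      for (j in 1:3)
        s <- s + r[j, k] * (A[i, j] * el1[t] + B[i, j] * el0[t])
      lw[t] <- s
    }
    expect_equal(g[i, k, ], exp(lw) / sum(exp(lw)), tolerance = 1e-12)
  }
})

test_that("theta update is exact conjugate accumulation", {
  pri <- theta_prior()
  # no data -> posterior equals prior
  data0 <- dense_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  th0 <- update_theta(data0, prop.table(matrix(1, 2, 2), 1),
                      demuxpool:::random_g_init(2, 2), pri)
  expect_equal(th0$alpha, pri$alpha)
  expect_equal(th0$beta, pri$beta)

  # one cell, one variant, r and g one-hot at (donor 1, het), a=4, d=6
  data <- dense_counts(matrix(4), matrix(6))
  r <- matrix(c(1, 0), 1, 2)
  g <- array(0, c(1, 2, 3)); g[1, 1, 2] <- 1; g[1, 2, 1] <- 1
  th <- update_theta(data, r, g, pri)
  expect_equal(th$alpha, pri$alpha + c(0, 4, 0))
  expect_equal(th$beta, pri$beta + c(0, 2, 0))

  # mass conservation: total added pseudo-counts equal total ALT/REF UMIs
  inst <- random_tiny_instance(3, 4, 2, seed = 33)
  set.seed(3)
  r2 <- prop.table(matrix(rexp(8), 4, 2), 1)
  g2 <- demuxpool:::random_g_init(3, 2)
  th2 <- update_theta(inst$data, r2, g2, pri)
  expect_equal(sum(th2$alpha - pri$alpha), sum(inst$data$A),
               tolerance = 1e-9)
  expect_equal(sum(th2$beta - pri$beta),
               sum(inst$data$D) - sum(inst$data$A), tolerance = 1e-9)
})

test_that("every coordinate update is monotone in the lower bound", {
  pri <- theta_prior()
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    N <- sample(2:5, 1); M <- sample(2:6, 1); K <- sample(2:3, 1)
    inst <- random_tiny_instance(N, M, K, seed = 500 + s, depth_mean = 3)
    st <- list(g = demuxpool:::random_g_init(N, K), theta = pri)
    st$r <- update_assignment(inst$data, st$g, st$theta, inst$pi)
    el <- function() compute_elbo(inst$data, st$r, inst$pi, st$g, inst$U,
                                  st$theta, pri)
    e_prev <- el()
    for (it in 1:3) {
      st$g <- update_genotype(inst$data, st$r, st$theta, inst$U)
      e1 <- el()
      st$theta <- update_theta(inst$data, st$r, st$g, pri)
      e2 <- el()
      st$r <- update_assignment(inst$data, st$g, st$theta, inst$pi)
      e3 <- el()
      worst <- min(worst, e1 - e_prev, e2 - e1, e3 - e2)
      e_prev <- e3
    }
  }
  expect_gte(worst, -1e-8)
})

test_that("permuting the initialization permutes the solution identically", {
  inst <- random_tiny_instance(4, 5, 3, seed = 77)
  pri <- theta_prior()
  perm <- c(3, 1, 2)
  run <- function(g0, U, pi) {
    theta <- pri
    r <- update_assignment(inst$data, g0, theta, pi)
    for (it in 1:5) {
      g0 <- update_genotype(inst$data, r, theta, U)
      theta <- update_theta(inst$data, r, g0, pri)
      r <- update_assignment(inst$data, g0, theta, pi)
    }
    list(r = r, g = g0)
  }
  g0 <- demuxpool:::random_g_init(4, 3)
  a <- run(g0, inst$U, inst$pi)
  b <- run(g0[, perm, , drop = FALSE], inst$U[, perm, , drop = FALSE],
           inst$pi[perm])
  expect_equal(b$r, a$r[, perm], tolerance = 1e-12)
  expect_equal(b$g, a$g[, perm, , drop = FALSE], tolerance = 1e-12)
})
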