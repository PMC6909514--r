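# Independent oracles used across the test suite. Everything here is
# deliberately scalar / brute-force and shares no code with the package
# internals it checks.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# dense tiny allele_counts from plain matrices
dense_counts <- function(A, D) {
  N <- nrow(A); M <- ncol(A)
  allele_counts(Matrix::Matrix(A, sparse = TRUE),
                Matrix::Matrix(D, sparse = TRUE),
                variant_table("1", seq_len(N), "A", "G"),
                sprintf("c%02d", seq_len(M)))
}

# random tiny instance drawn from the generative model, with identifiable
# (non-symmetric) priors so the exact posterior has a unique argmax
random_tiny_instance <- function(N, M, K, seed, depth_mean = 6) {
  set.seed(seed)
  G <- matrix(sample(0:2, N * K, replace = TRUE), N, K)
  random_tiny_body(N, M, K, G, depth_mean)
}

# as above, but conditioned on discernible donors (genotype columns differ
# at >= 2 variants) and guaranteed coverage of every entry, so each cell
# carries decisive evidence and the exact argmax is stable
random_identifiable_instance <- function(N, M, K, seed) {
  set.seed(seed)
  repeat {
    G <- matrix(sample(0:2, N * K, replace = TRUE), N, K)
    pairs <- utils::combn(K, 2)
    if (all(apply(pairs, 2, function(p) sum(G[, p[1]] != G[, p[2]]) >= 2)))
      break
  }
  random_tiny_body(N, M, K, G, depth_mean = 4, depth_floor = 2)
}

random_tiny_body <- function(N, M, K, G, depth_mean, depth_floor = 0) {
  z <- sample(seq_len(K), M, replace = TRUE)
  th <- c(0.01, 0.5, 0.99)
  D <- matrix(depth_floor + stats::rpois(N * M, depth_mean), N, M)
  p <- th[G[cbind(rep(seq_len(N), M), rep(z, each = N))] + 1]
  A <- matrix(stats::rbinom(N * M, as.vector(D), p), N, M)
  U <- array(stats::rexp(N * K * 3), c(N, K, 3))
  U <- U / as.vector(U[, , 1] + U[, , 2] + U[, , 3])
  pi <- as.vector(prop.table(stats::rexp(K) + 0.2))
  list(data = dense_counts(A, D), U = U, pi = pi, z = z, G = G)
}

# Exact joint enumeration over all Z and G configurations, integrating the
# allele rates against their beta priors in closed form. Returns the log
# marginal likelihood (including the binomial coefficients) and the exact
# per-cell posterior over components.
enumerate_exact <- function(data, K, pi, U, prior = theta_prior()) {
  A <- as.matrix(data$A); D <- as.matrix(data$D); B <- D - A
  N <- nrow(A); M <- ncol(A)
  gcfg <- as.matrix(expand.grid(rep(list(0:2), N * K)))
  zcfg <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  lconst <- sum(lchoose(D, A))
  lp <- matrix(-Inf, nrow(zcfg), nrow(gcfg))
  for (zi in seq_len(nrow(zcfg))) {
    z <- zcfg[zi, ]
    for (gi in seq_len(nrow(gcfg))) {
      G <- matrix(gcfg[gi, ], N, K)
      at <- bt <- numeric(3)
      for (j in seq_len(M)) {
        for (i in seq_len(N)) {
          t <- G[i, z[j]] + 1L
          at[t] <- at[t] + A[i, j]
          bt[t] <- bt[t] + B[i, j]
        }
      }
      lpg <- sum(log(U[cbind(rep(seq_len(N), K), rep(seq_len(K), each = N),
                             as.vector(G) + 1L)]))
      lp[zi, gi] <- sum(log(pi[z])) + lpg +
        sum(lbeta(prior$alpha + at, prior$beta + bt) -
              lbeta(prior$alpha, prior$beta))
    }
  }
  lp <- lp + lconst
  post_z_cfg <- vapply(seq_len(nrow(zcfg)), function(zi)
    logsumexp(lp[zi, ]), numeric(1))
  cell_post <- matrix(0, M, K)
  for (j in seq_len(M)) {
    for (k in seq_len(K)) {
      cell_post[j, k] <- logsumexp(post_z_cfg[zcfg[, j] == k])
    }
  }
  cell_post <- exp(cell_post - apply(cell_post, 1, logsumexp))
  list(log_marginal = logsumexp(as.vector(lp)), cell_post = cell_post)
}

# coordinate ascent to convergence from restarts, returning the best run
vb_converge <- function(data, K, pi, U, n_restart = 10, seed = 1,
                        max_iters = 300, tol = 1e-9) {
  prior <- theta_prior()
  best <- NULL
  for (rs in seq_len(n_restart)) {
    set.seed(seed * 1000 + rs)
    g <- array(stats::rexp(nrow(data$A) * K * 3), c(nrow(data$A), K, 3))
    g <- g / as.vector(g[, , 1] + g[, , 2] + g[, , 3])
    theta <- prior
    r <- update_assignment(data, g, theta, pi)
    cur <- -Inf
    for (it in seq_len(max_iters)) {
      prev <- cur
      g <- update_genotype(data, r, theta, U)
      theta <- update_theta(data, r, g, prior)
      r <- update_assignment(data, g, theta, pi)
      cur <- compute_elbo(data, r, pi, g, U, theta, prior)
      if (abs(cur - prev) < tol) break
    }
    if (is.null(best) || cur > best$elbo)
      best <- list(r = r, g = g, theta = theta, elbo = cur)
  }
  best
}

# all permutations of 1..n (for brute-force assignment matching)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
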