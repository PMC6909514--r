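#' Beta prior on the per-genotype ALT allele rates
#'
#' One beta distribution per genotype state t in {0, 1, 2} for the binomial
#' rate theta_t of observing the ALT allele. Theoretically theta_t = t/2;
#' the priors concentrate near (0.01, 0.5, 0.99) to absorb sequencing
#' error, genotyping error and allelic imbalance.
#'
#' @param alpha,beta positive 3-vectors of beta shape parameters; defaults
#'   (0.3, 3, 29.7) and (29.7, 3, 0.3), i.e. prior means 0.01, 0.5, 0.99
#'   with concentrations 30, 6, 30.
#' @return An object of class `theta_dist` with fields `alpha`, `beta`,
#'   `states`.
#' @export
theta_prior <- function(alpha = c(0.3, 3, 29.7), beta = c(29.7, 3, 0.3)) {
  theta_dist(alpha, beta, states = c(0, 1, 2))
}

#' Beta distribution set over genotype states
#'
#' @param alpha,beta positive shape vectors, one entry per state.
#' @param states ordered genotype labels; `c(0, 1, 2)` for the singlet
#'   model, `c(0, 0.5, 1, 1.5, 2)` when doublet pseudo-genotypes are active.
#' @return An object of class `theta_dist`.
#' @export
theta_dist <- function(alpha, beta, states = c(0, 1, 2)) {
  stopifnot(length(alpha) == length(beta), length(alpha) == length(states),
            all(alpha > 0), all(beta > 0))
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 states = states), class = "theta_dist")
}

#' @export
print.theta_dist <- function(x, ...) {
  cat("theta_dist over states {", paste(x$states, collapse = ", "), "}\n",
      sep = "")
  print(data.frame(state = x$states, alpha = x$alpha, beta = x$beta,
                   mean = x$alpha / (x$alpha + x$beta)), row.names = FALSE)
  invisible(x)
}

# E[log theta_t] and E[log(1 - theta_t)] under beta(alpha_t, beta_t).
# Both include the -digamma(alpha+beta) part, so a*elog1 + b*elog0 is the
# complete expected log binomial kernel (up to the data-constant log C(d,a)).
elog_theta <- function(theta) {
  dg <- digamma(theta$alpha + theta$beta)
  list(log1 = digamma(theta$alpha) - dg,
       log0 = digamma(theta$beta) - dg)
}

#' Expected binomial log-likelihood contributions per genotype state
#'
#' For every covered (variant, cell) entry and genotype state t, the
#' variational expectation of the binomial log-likelihood,
#' `a * E[log theta_t] + b * E[log(1 - theta_t)]` with `b = d - a` and
#' `E[log theta_t] = digamma(alpha_t) - digamma(alpha_t + beta_t)` (and
#' analogously for `1 - theta_t`). The multinomial coefficient log C(d, a)
#' is constant in all latent variables and is excluded here. Entries with
#' no depth contribute 0.
#'
#' @param data an [allele_counts()] object.
#' @param theta a [theta_dist()].
#' @return List of sparse variants x cells matrices, one per state, named
#'   by state.
#' @export
expected_binom_loglik <- function(data, theta) {
  el <- elog_theta(theta)
  B <- data$D - data$A
  out <- lapply(seq_along(theta$states), function(s) {
    m <- data$A * el$log1[s] + B * el$log0[s]
    if (length(m@x) && any(!is.finite(m@x)))
      stop("non-finite expected log-likelihood for state ", theta$states[s])
    m
  })
  names(out) <- as.character(theta$states)
  out
}

# sum of log C(d, a) over stored entries; the data-constant part of the
# expected log-likelihood, included once in the ELBO.
lchoose_const <- function(data) {
  trip <- Matrix::summary(data$D)
  a <- data$A[cbind(trip$i, trip$j)]
  sum(lchoose(trip$x, a))
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

kl_beta <- function(a, b, a0, b0) {
  lbeta(a0, b0) - lbeta(a, b) +
    (a - a0) * digamma(a) + (b - b0) * digamma(b) +
    (a0 - a + b0 - b) * digamma(a + b)
}

#' Evidence lower bound of the singlet model
#'
#' Computes L(q) = E_q\[log p(A,D|Z,G,theta)\] - KL(q(Z)||p(Z|pi))
#' - KL(q(G)||p(G|U)) - KL(q(theta)||p(theta)), with the convention
#' 0 log 0 = 0 and the binomial coefficient term included in the data term.
#'
#' @param data an [allele_counts()] object.
#' @param r cells x K assignment posterior matrix (rows sum to 1).
#' @param pi length-K prior weights.
#' @param g variants x K x 3 genotype posterior array.
#' @param U variants x K x 3 genotype prior array.
#' @param theta a [theta_dist()] posterior over states (0, 1, 2).
#' @param prior a [theta_prior()].
#' @param lconst precomputed [sum of log C(d, a)]; recomputed if `NULL`.
#' @return Scalar lower-bound value.
#' @export
compute_elbo <- function(data, r, pi, g, U, theta, prior, lconst = NULL) {
  el <- elog_theta(theta)
  B <- data$D - data$A
  AR <- as.matrix(data$A %*% r)
  BR <- as.matrix(B %*% r)
  lik <- 0
  for (s in 1:3)
    lik <- lik + sum(g[, , s] * (el$log1[s] * AR + el$log0[s] * BR))
  if (is.null(lconst)) lconst <- lchoose_const(data)
  kl_z <- sum(xlogy(r, r)) - sum(r %*% diag(log(pi), length(pi)))
  kl_g <- sum(xlogy(g, g)) - sum(xlogy(g, U))
  kl_t <- sum(kl_beta(theta$alpha, theta$beta, prior$alpha, prior$beta))
  out <- lik + lconst - kl_z - kl_g - kl_t
  if (!is.finite(out)) stop("non-finite ELBO")
  out
}
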