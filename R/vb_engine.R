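#' Fit configuration
#'
#' Tuning knobs of the coordinate-ascent variational fit.
#'
#' @param n_init number of random initializations in the warm-up pre-search
#'   (default 50).
#' @param warmup_iters iterations per random initialization (default 15).
#' @param max_iters iteration cap for the main coordinate ascent
#'   (default 200).
#' @param elbo_tol absolute lower-bound change declaring convergence
#'   (default 1e-2).
#' @param seed integer seed controlling all randomness of the fit.
#' @param n_extra_clusters surplus components searched during warm-up and
#'   pruned afterwards; default `ceiling(sqrt(K))`, resolved at fit time
#'   (`NULL`), capped so that the total never exceeds the number of cells.
#' @param doublet_prior prior doublet probability eta: a number in \[0, 1)
#'   or `"auto"` for M / 100,000 with M the number of cells.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_init = 50, warmup_iters = 15, max_iters = 200,
                       elbo_tol = 1e-2, seed = 1, n_extra_clusters = NULL,
                       doublet_prior = "auto") {
  stopifnot(n_init >= 1, warmup_iters >= 1, warmup_iters <= max_iters,
            elbo_tol > 0)
  if (!identical(doublet_prior, "auto"))
    stopifnot(is.numeric(doublet_prior), doublet_prior >= 0, doublet_prior < 1)
  structure(list(n_init = n_init, warmup_iters = warmup_iters,
                 max_iters = max_iters, elbo_tol = elbo_tol,
                 seed = as.integer(seed), n_extra_clusters = n_extra_clusters,
                 doublet_prior = doublet_prior),
            class = "fit_config")
}

# row-wise softmax of a dense log-weight matrix, max-subtracted
softmax_rows <- function(lw) {
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

# GE[i,k] = sum_t g[i,k,t] * elog[t]; dense N x K
ge_from_g <- function(g, elog) {
  d <- dim(g)
  out <- matrix(0, d[1], d[2])
  for (s in seq_len(d[3])) out <- out + matrix(g[, , s], d[1], d[2]) * elog[s]
  out
}

#' Update the cell-assignment posterior q(Z)
#'
#' One coordinate-ascent step: `r[j,k]` proportional to
#' `pi[k] * exp( sum_i sum_t g[i,k,t] * (a_ij E[log theta_t] + b_ij
#' E[log(1-theta_t)]) )`, normalized per cell in log space. Cells with no
#' covered variant fall back to the prior `pi`.
#'
#' @param data an [allele_counts()] object.
#' @param g variants x K x 3 genotype posterior array.
#' @param theta [theta_dist()] posterior.
#' @param pi length-K prior weights.
#' @return cells x K posterior matrix with unit row sums.
#' @export
update_assignment <- function(data, g, theta, pi) {
  B <- data$D - data$A
  update_assignment_fast(Matrix::t(data$A), Matrix::t(B), g, theta, pi)
}

update_assignment_fast <- function(tA, tB, g, theta, pi) {
  el <- elog_theta(theta)
  GE1 <- ge_from_g(g, el$log1)
  GE0 <- ge_from_g(g, el$log0)
  lw <- as.matrix(tA %*% GE1 + tB %*% GE0)
  lw <- sweep(lw, 2, log(pi), "+")
  softmax_rows(lw)
}

#' Update the genotype posterior q(G)
#'
#' One coordinate-ascent step: `g[i,k,t]` proportional to
#' `u[i,k,t] * exp( sum_j r[j,k] * (a_ij E[log theta_t] + b_ij
#' E[log(1-theta_t)]) )`, normalized over t. Variants with no coverage in
#' cells assigned to donor k revert to the prior row.
#'
#' @param data an [allele_counts()] object.
#' @param r cells x K assignment posterior.
#' @param theta [theta_dist()] posterior.
#' @param U variants x K x 3 prior array.
#' @return variants x K x 3 posterior array.
#' @export
update_genotype <- function(data, r, theta, U) {
  B <- data$D - data$A
  AR <- as.matrix(data$A %*% r)
  BR <- as.matrix(B %*% r)
  update_genotype_fast(AR, BR, theta, U)
}

update_genotype_fast <- function(AR, BR, theta, U) {
  el <- elog_theta(theta)
  lg <- array(0, dim = dim(U))
  for (s in 1:3)
    lg[, , s] <- log(U[, , s]) + el$log1[s] * AR + el$log0[s] * BR
  mx <- pmax(lg[, , 1], lg[, , 2], lg[, , 3])
  g <- array(0, dim = dim(U))
  for (s in 1:3) g[, , s] <- exp(lg[, , s] - mx)
  tot <- g[, , 1] + g[, , 2] + g[, , 3]
  for (s in 1:3) g[, , s] <- g[, , s] / tot
  g
}

#' Update the allele-rate posterior q(theta)
#'
#' Conjugate beta accumulation: `alpha_t = alpha0_t + sum_{i,j,k} r[j,k]
#' g[i,k,t] a[i,j]` and `beta_t` likewise with `b = d - a`. Only singlet
#' assignment columns contribute.
#'
#' @param data an [allele_counts()] object.
#' @param r cells x K assignment posterior.
#' @param g variants x K x 3 genotype posterior.
#' @param prior a [theta_prior()].
#' @return [theta_dist()] posterior over states (0, 1, 2).
#' @export
update_theta <- function(data, r, g, prior) {
  B <- data$D - data$A
  AR <- as.matrix(data$A %*% r)
  BR <- as.matrix(B %*% r)
  update_theta_fast(AR, BR, g, prior)
}

update_theta_fast <- function(AR, BR, g, prior) {
  alpha <- prior$alpha
  beta <- prior$beta
  for (s in 1:3) {
    alpha[s] <- alpha[s] + sum(g[, , s] * AR)
    beta[s] <- beta[s] + sum(g[, , s] * BR)
  }
  theta_dist(alpha, beta, states = c(0, 1, 2))
}

# one full coordinate sweep (genotype -> theta -> assignment) returning the
# refreshed state; AR/BR are recomputed from the incoming r
vb_sweep <- function(st, env) {
  AR <- as.matrix(env$A %*% st$r)
  BR <- as.matrix(env$B %*% st$r)
  st$g <- update_genotype_fast(AR, BR, st$theta, st$U)
  st$theta <- update_theta_fast(AR, BR, st$g, env$theta_prior)
  st$r <- update_assignment_fast(env$tA, env$tB, st$g, st$theta, st$pi)
  st
}

vb_elbo <- function(st, env) {
  compute_elbo(env$data, st$r, st$pi, st$g, st$U, st$theta, env$theta_prior,
               lconst = env$lconst)
}

make_vb_env <- function(data, theta_prior) {
  B <- data$D - data$A
  list(data = data, A = data$A, B = B,
       tA = Matrix::t(data$A), tB = Matrix::t(B),
       theta_prior = theta_prior, lconst = lchoose_const(data))
}

random_g_init <- function(N, K) {
  # Dirichlet(1,1,1) per (variant, component)
  x <- array(stats::rexp(N * K * 3), dim = c(N, K, 3))
  tot <- x[, , 1] + x[, , 2] + x[, , 3]
  for (s in 1:3) x[, , s] <- x[, , s] / tot
  x
}

run_ascent <- function(st, env, max_iters, tol) {
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iters)) {
    st <- vb_sweep(st, env)
    cur <- vb_elbo(st, env)
    trace <- c(trace, cur)
    if (abs(cur - prev) < tol) break
    prev <- cur
  }
  st$trace <- trace
  st
}

#' Fit the donor mixture model by variational inference
#'
#' Runs the full genotype-free (or prior-informed) fit: a warm-up
#' pre-search of `n_init` random genotype initializations with
#' `K + n_extra_clusters` components for `warmup_iters` sweeps each; the
#' initialization with the highest lower bound is kept and pruned to the K
#' components holding the most softly-assigned cells; coordinate ascent
#' then continues to convergence. Finally, if `doublets = TRUE` and K >= 2,
#' the component space is augmented with the K(K-1)/2 combined-genotype
#' doublet pseudo-donors and the assignment posterior is recomputed there
#' (genotypes and allele rates stay fixed), yielding `prob_max` and
#' `prob_doublet` per cell.
#'
#' @param data an [allele_counts()] object (typically after
#'   [filter_variants()]).
#' @param K number of donors in the pool.
#' @param prior_U optional [genotype_prior()] over the data's variants; if
#'   it contains informative rows, the warm-up skips the surplus-cluster
#'   pre-search so prior columns keep their donor identity.
#' @param config a [fit_config()].
#' @param doublets logical; run the doublet extension stage (default TRUE).
#' @param fix_genotype logical; clamp q(G) to the prior and never update it
#'   (reference-genotype mode, used by [fit_with_full_genotype()]).
#' @return An object of class `donor_fit`; see Details.
#'
#' @details The returned `donor_fit` contains: `r` (cells x H posterior,
#'   H = K + K(K-1)/2 after the doublet stage), `pi`, `prob_max`,
#'   `prob_doublet`, `best_doublet_pair`, `donor_ids`, `g` (variants x K x 3
#'   genotype posterior), `theta` (and `theta_extended`), `elbo_trace`,
#'   `elbo` (final singlet-phase lower bound), `n_donors`, `converged`,
#'   `seed`, `eta`, `n_vars` (covered variants per cell), `depth`
#'   (variants x K expected per-donor depth), and `variant_ids`.
#' @export
fit_donors <- function(data, K, prior_U = NULL, config = fit_config(),
                       doublets = TRUE, fix_genotype = FALSE) {
  N <- nrow(data$A); M <- ncol(data$A)
  if (K < 1) stop("K must be >= 1")
  if (K > M) stop("K = ", K, " exceeds the number of cells (", M, ")")
  if (sum(data$D@x) == 0) stop("all-zero depth matrix")
  if (!is.null(prior_U)) {
    if (length(prior_U$variant_ids) != N ||
        !all(prior_U$variant_ids == data$variants$id))
      stop("prior variants do not match the count data")
    if (dim(prior_U$U)[2] != K)
      stop("prior covers ", dim(prior_U$U)[2], " donors but K = ", K)
  }
  theta_pri <- theta_prior()
  env <- make_vb_env(data, theta_pri)
  informative <- !is.null(prior_U) && any(prior_U$known_mask)
  donor_ids <- if (!is.null(prior_U)) prior_U$donors else paste0("donor", seq_len(K))

  if (fix_genotype) {
    if (is.null(prior_U)) stop("fix_genotype requires a genotype prior")
    st <- list(g = prior_U$U, U = prior_U$U, pi = rep(1 / K, K),
               theta = theta_pri)
    st$r <- update_assignment_fast(env$tA, env$tB, st$g, st$theta, st$pi)
    trace <- numeric(0); prev <- -Inf; converged <- FALSE
    for (it in seq_len(config$max_iters)) {
      AR <- as.matrix(env$A %*% st$r)
      BR <- as.matrix(env$B %*% st$r)
      st$theta <- update_theta_fast(AR, BR, st$g, theta_pri)
      st$r <- update_assignment_fast(env$tA, env$tB, st$g, st$theta, st$pi)
      cur <- vb_elbo(st, env)
      trace <- c(trace, cur)
      if (abs(cur - prev) < config$elbo_tol) { converged <- TRUE; break }
      prev <- cur
    }
    st$trace <- trace
  } else {
    n_extra <- config$n_extra_clusters
    if (is.null(n_extra)) n_extra <- if (informative) 0L else ceiling(sqrt(K))
    n_extra <- min(n_extra, M - K)
    Kw <- K + n_extra
    Uw <- array(1 / 3, dim = c(N, Kw, 3))
    if (!is.null(prior_U)) Uw[, seq_len(K), ] <- prior_U$U
    piw <- rep(1 / Kw, Kw)

    best <- NULL
    for (i in seq_len(config$n_init)) {
      set.seed(config$seed + i)
      st <- list(g = random_g_init(N, Kw), U = Uw, pi = piw, theta = theta_pri)
      st$r <- update_assignment_fast(env$tA, env$tB, st$g, st$theta, st$pi)
      st <- run_ascent(st, env, config$warmup_iters, config$elbo_tol)
      if (is.null(best) || utils::tail(st$trace, 1) > best$score) {
        best <- st
        best$score <- utils::tail(st$trace, 1)
      }
    }
    st <- best

    if (Kw > K) {
      mass <- colSums(st$r)
      keep <- order(-mass, seq_len(Kw))[seq_len(K)]
      keep <- sort(keep)
      st$g <- st$g[, keep, , drop = FALSE]
      st$r <- st$r[, keep, drop = FALSE]
      st$r <- st$r / rowSums(st$r)
      st$U <- Uw[, keep, , drop = FALSE]
      st$pi <- rep(1 / K, K)
    }
    st <- run_ascent(st, env, config$max_iters, config$elbo_tol)
    converged <- length(st$trace) < config$max_iters
    if (!converged)
      warning("coordinate ascent did not converge in ", config$max_iters,
              " iterations")
  }

  fit <- structure(list(
    r = st$r, pi = st$pi, g = st$g, theta = st$theta,
    elbo_trace = st$trace, elbo = utils::tail(st$trace, 1),
    n_donors = K, donor_ids = donor_ids, converged = converged,
    seed = config$seed,
    n_vars = Matrix::colSums(data$D > 0),
    depth = as.matrix(data$D %*% st$r),
    variant_ids = data$variants$id,
    pairs = NULL, theta_extended = NULL, eta = 0,
    prob_max = apply(st$r, 1, max),
    prob_doublet = rep(0, M),
    best_doublet_pair = rep(NA_character_, M)
  ), class = "donor_fit")

  if (doublets) {
    eta <- config$doublet_prior
    if (identical(eta, "auto")) eta <- M / 1e5
    if (K < 2) {
      if (eta > 0) warning("doublet detection requires K >= 2; eta forced to 0")
      return(fit)
    }
    ext <- build_doublet_extension(st$g, st$theta, eta = eta, K = K, M = M)
    ra <- assign_extended(data, ext, st$g, st$theta)
    fit$r <- ra$r
    fit$prob_max <- ra$prob_max
    fit$prob_doublet <- ra$prob_doublet
    fit$best_doublet_pair <- pair_labels(ext$pairs, donor_ids)[ra$best_pair]
    fit$pairs <- ext$pairs
    fit$theta_extended <- ext$theta_extended
    fit$eta <- eta
  }
  fit
}

#' @export
print.donor_fit <- function(x, ...) {
  cat("donor_fit: K = ", x$n_donors, ", ", length(x$n_vars), " cells, ",
      length(x$variant_ids), " variants\n", sep = "")
  cat("  ELBO ", format(x$elbo, digits = 10), " after ",
      length(x$elbo_trace), " iterations (",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  if (!is.null(x$pairs))
    cat("  doublet prior eta = ", format(x$eta, digits = 4), "; ",
        sum(x$prob_doublet > 0.9), " cells with prob_doublet > 0.9\n",
        sep = "")
  tab <- table(factor(x$donor_ids[apply(x$r[, seq_len(x$n_donors), drop = FALSE],
                                        1, which.max)], levels = x$donor_ids))
  cat("  cells per donor (argmax): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
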