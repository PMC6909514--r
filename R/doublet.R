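#' Combine two donor genotype distributions into a doublet distribution
#'
#' A droplet holding cells from two donors shows the average allele dosage
#' of the two genotypes, which lives on the extended state space
#' (0, 0.5, 1, 1.5, 2). Given the two donors' categorical genotype
#' probabilities `x` and `y` over (0, 1, 2), the combined distribution is
#' `p(0) = x0 y0`, `p(0.5) = x0 y1 + x1 y0`,
#' `p(1) = x1 y1 + x0 y2 + x2 y0`, `p(1.5) = x1 y2 + x2 y1`,
#' `p(2) = x2 y2`.
#'
#' @param x,y normalized 3-vectors (or N x 3 matrices, combined row-wise).
#' @return A 5-vector (or N x 5 matrix) over states (0, 0.5, 1, 1.5, 2);
#'   sums to 1 and is symmetric in `x` and `y`.
#' @export
combine_genotype_probs <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  out <- cbind(x[, 1] * y[, 1],
               x[, 1] * y[, 2] + x[, 2] * y[, 1],
               x[, 2] * y[, 2] + x[, 1] * y[, 3] + x[, 3] * y[, 1],
               x[, 2] * y[, 3] + x[, 3] * y[, 2],
               x[, 3] * y[, 3])
  colnames(out) <- c("0", "0.5", "1", "1.5", "2")
  if (nrow(out) == 1) drop(out) else out
}

#' Beta parameters for the doublet pseudo-genotypes
#'
#' Extends a beta posterior over states (0, 1, 2) with the pseudo-states
#' 0.5 and 1.5. Each pseudo-state's beta distribution is pinned by two
#' moment constraints on the neighbouring states: its mean is the
#' arithmetic mean of the two component means, and its concentration
#' (alpha + beta) is the geometric mean of the two component
#' concentrations.
#'
#' @param theta a [theta_dist()] over states (0, 1, 2).
#' @return A [theta_dist()] over states (0, 0.5, 1, 1.5, 2).
#' @export
doublet_theta_params <- function(theta) {
  stopifnot(length(theta$alpha) == 3)
  m <- theta$alpha / (theta$alpha + theta$beta)
  s <- theta$alpha + theta$beta
  mean05 <- (m[1] + m[2]) / 2; conc05 <- sqrt(s[1] * s[2])
  mean15 <- (m[2] + m[3]) / 2; conc15 <- sqrt(s[2] * s[3])
  theta_dist(alpha = c(theta$alpha[1], mean05 * conc05, theta$alpha[2],
                       mean15 * conc15, theta$alpha[3]),
             beta = c(theta$beta[1], (1 - mean05) * conc05, theta$beta[2],
                      (1 - mean15) * conc15, theta$beta[3]),
             states = c(0, 0.5, 1, 1.5, 2))
}

pair_labels <- function(pairs, donor_ids)
  paste(donor_ids[pairs[1, ]], donor_ids[pairs[2, ]], sep = ",")

#' Build the doublet pseudo-donor extension
#'
#' Constructs the K(K-1)/2 unordered donor pairs, their combined genotype
#' distributions over the 5 extended states, the extended allele-rate
#' posterior, and the doublet-aware component prior: each singlet donor
#' gets prior mass `(1 - eta) / K` and each pair `eta / K2`.
#'
#' @param g variants x K x 3 genotype posterior.
#' @param theta [theta_dist()] posterior over (0, 1, 2).
#' @param eta prior doublet probability; `"auto"` resolves to `M / 100000`.
#' @param K number of donors.
#' @param M number of cells (used for `eta = "auto"`).
#' @return List of class `doublet_extension` with `pairs` (2 x K2 matrix,
#'   k < l), `g_doublet` (variants x K2 x 5), `theta_extended`,
#'   `pi_extended`, `eta`.
#' @export
build_doublet_extension <- function(g, theta, eta = "auto", K, M) {
  if (identical(eta, "auto")) eta <- M / 1e5
  if (K < 2) {
    warning("doublet extension requires K >= 2; returning empty extension")
    return(structure(list(pairs = matrix(integer(0), 2, 0),
                          g_doublet = NULL, theta_extended = NULL,
                          pi_extended = rep(1, K), eta = 0),
                     class = "doublet_extension"))
  }
  stopifnot(eta >= 0, eta < 1)
  pairs <- utils::combn(K, 2)
  K2 <- ncol(pairs)
  N <- dim(g)[1]
  gd <- array(0, dim = c(N, K2, 5))
  for (p in seq_len(K2)) {
    x <- matrix(g[, pairs[1, p], ], N, 3)
    y <- matrix(g[, pairs[2, p], ], N, 3)
    cmb <- combine_genotype_probs(x, y)
    gd[, p, ] <- if (is.null(dim(cmb))) matrix(cmb, 1, 5) else cmb
  }
  structure(list(pairs = pairs, g_doublet = gd,
                 theta_extended = doublet_theta_params(theta),
                 pi_extended = c(rep((1 - eta) / K, K), rep(eta / K2, K2)),
                 eta = eta),
            class = "doublet_extension")
}

#' Assignment posterior over singlet and doublet components
#'
#' Softmax assignment update over the K + K(K-1)/2 extended components,
#' using the singlet genotype posterior with the 3-state allele rates and
#' the combined doublet genotypes with the 5-state extension.
#' `prob_max` is each cell's largest singlet probability; `prob_doublet`
#' the summed probability of all doublet components. Cells with no covered
#' variant fall back to the prior, so their `prob_doublet` equals `eta`.
#'
#' @param data an [allele_counts()] object.
#' @param ext a [build_doublet_extension()] result.
#' @param g variants x K x 3 singlet genotype posterior.
#' @param theta [theta_dist()] posterior over (0, 1, 2).
#' @return List with `r` (cells x (K + K2)), `prob_max`, `prob_doublet`,
#'   `best_pair` (index into `ext$pairs` of each cell's best doublet
#'   component).
#' @export
assign_extended <- function(data, ext, g, theta) {
  K <- dim(g)[2]
  K2 <- ncol(ext$pairs)
  B <- data$D - data$A
  tA <- Matrix::t(data$A); tB <- Matrix::t(B)
  el_s <- elog_theta(theta)
  el_d <- elog_theta(ext$theta_extended)
  GE1 <- cbind(ge_from_g(g, el_s$log1), ge_from_g(ext$g_doublet, el_d$log1))
  GE0 <- cbind(ge_from_g(g, el_s$log0), ge_from_g(ext$g_doublet, el_d$log0))
  lw <- as.matrix(tA %*% GE1 + tB %*% GE0)
  lw <- sweep(lw, 2, log(ext$pi_extended), "+")
  r <- softmax_rows(lw)
  rs <- r[, seq_len(K), drop = FALSE]
  rd <- r[, K + seq_len(K2), drop = FALSE]
  list(r = r,
       prob_max = apply(rs, 1, max),
       prob_doublet = rowSums(rd),
       best_pair = apply(rd, 1, which.max))
}
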