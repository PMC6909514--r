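#' Donor genotype profiles for matching
#'
#' A light container of hard genotype calls plus the per-(variant, donor)
#' aggregate depth, the currency used for aligning donors across runs and
#' for panel design. Depth for a fitted model is the expected depth
#' `D %*% r` under the assignment posterior; reference genotypes carry
#' infinite depth so they always pass coverage filters.
#'
#' @param fit a `donor_fit` from [fit_donors()].
#' @return An object of class `donor_genotypes`: list with `hard`
#'   (variants x donors matrix of 0/1/2 calls, `NA` where the posterior is
#'   uninformative), `g` (the full posterior array or `NULL`), `depth`,
#'   `ids`, `donors`.
#' @export
donor_genotypes <- function(fit) {
  K <- fit$n_donors
  g <- fit$g
  hard <- hard_calls(g)
  structure(list(hard = hard, g = g,
                 depth = fit$depth[, seq_len(K), drop = FALSE],
                 ids = fit$variant_ids, donors = fit$donor_ids),
            class = "donor_genotypes")
}

hard_calls <- function(g) {
  d <- dim(g)
  flat <- cbind(as.vector(g[, , 1]), as.vector(g[, , 2]), as.vector(g[, , 3]))
  call <- max.col(flat, ties.method = "first") - 1L
  call[abs(flat[, 1] - flat[, 2]) < 1e-12 &
         abs(flat[, 2] - flat[, 3]) < 1e-12] <- NA_integer_
  matrix(call, d[1], d[2])
}

#' @rdname donor_genotypes
#' @param prior a [genotype_prior()]; entries without a known genotype
#'   become `NA` calls.
#' @export
donor_genotypes_from_prior <- function(prior) {
  hard <- hard_calls(prior$U)
  hard[!prior$known_mask] <- NA_integer_
  structure(list(hard = hard, g = prior$U,
                 depth = matrix(Inf, nrow(hard), ncol(hard)),
                 ids = prior$variant_ids, donors = prior$donors),
            class = "donor_genotypes")
}

#' @rdname donor_genotypes
#' @param G variants x donors hard genotype matrix (0/1/2, `NA` unknown).
#' @param ids variant identifiers.
#' @param donors donor names.
#' @export
donor_genotypes_from_matrix <- function(G, ids = rownames(G),
                                        donors = colnames(G)) {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  if (is.null(donors)) donors <- paste0("donor", seq_len(ncol(G)))
  structure(list(hard = G, g = NULL,
                 depth = matrix(Inf, nrow(G), ncol(G)),
                 ids = ids, donors = donors),
            class = "donor_genotypes")
}

#' Genotype concordance between two sets of donor profiles
#'
#' For each donor pair across the two profile sets, the fraction of shared
#' variants on which the hard genotype calls agree, restricted to variants
#' with at least `min_umis` aggregate depth in both donors. Pairs with no
#' qualifying variant are reported as `NA` with a shared count of 0.
#'
#' @param gA,gB [donor_genotypes()] objects; variants matched by id.
#' @param min_umis per-donor depth filter (default 10).
#' @return Object of class `concordance_matrix`: list with `values`
#'   (K_A x K_B fractions) and `n_shared_variants` (qualifying variant
#'   counts).
#' @export
genotype_concordance <- function(gA, gB, min_umis = 10) {
  shared <- intersect(gA$ids, gB$ids)
  if (!length(shared)) stop("no shared variants between the two profiles")
  ia <- match(shared, gA$ids); ib <- match(shared, gB$ids)
  hA <- gA$hard[ia, , drop = FALSE]; dA <- gA$depth[ia, , drop = FALSE]
  hB <- gB$hard[ib, , drop = FALSE]; dB <- gB$depth[ib, , drop = FALSE]
  KA <- ncol(hA); KB <- ncol(hB)
  values <- matrix(NA_real_, KA, KB, dimnames = list(gA$donors, gB$donors))
  n_shared <- matrix(0L, KA, KB, dimnames = list(gA$donors, gB$donors))
  for (a in seq_len(KA)) {
    for (b in seq_len(KB)) {
      ok <- dA[, a] >= min_umis & dB[, b] >= min_umis &
        !is.na(hA[, a]) & !is.na(hB[, b])
      n_shared[a, b] <- sum(ok)
      if (any(ok)) values[a, b] <- mean(hA[ok, a] == hB[ok, b])
    }
  }
  structure(list(values = values, n_shared_variants = n_shared),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("concordance_matrix (", nrow(x$values), " x ", ncol(x$values),
      " donors)\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

# Exact rectangular assignment by shortest augmenting paths (minimization,
# square matrix). Deterministic: ties resolve toward lower column index.
solve_lap_min <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, all(is.finite(a)))
  u <- numeric(n)
  v <- numeric(n + 1)   # column 0 (virtual) at index 1
  p <- integer(n + 1)   # p[j + 1]: row assigned to column j, 0 = none
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Optimal one-to-one donor matching
#'
#' Globally optimal assignment maximizing total concordance between the
#' rows and columns of a concordance matrix (undefined entries count as
#' 0). Non-square matrices yield a partial matching of the smaller side.
#' Ties are broken deterministically toward the lowest index pair.
#'
#' @param cm a [genotype_concordance()] result, or a plain numeric matrix.
#' @return List with `to` (for each row donor, the matched column index or
#'   `NA`), `score` (that pair's concordance), `total` (sum of matched
#'   scores), `pairs` (data.frame view).
#' @export
match_donors <- function(cm) {
  values <- if (inherits(cm, "concordance_matrix")) cm$values else as.matrix(cm)
  raw <- values
  values[is.na(values)] <- 0
  KA <- nrow(values); KB <- ncol(values)
  n <- max(KA, KB)
  cost <- matrix(0, n, n)
  cost[seq_len(KA), seq_len(KB)] <- max(values) - values
  sol <- solve_lap_min(cost)
  to <- rep(NA_integer_, KA)
  for (i in seq_len(KA)) if (sol[i] <= KB) to[i] <- sol[i]
  score <- ifelse(is.na(to), NA_real_, raw[cbind(seq_len(KA), to)])
  pairs <- data.frame(
    from = if (!is.null(rownames(values))) rownames(values) else
      as.character(seq_len(KA)),
    to = ifelse(is.na(to), NA_character_,
                if (!is.null(colnames(values))) colnames(values)[to] else
                  as.character(to)),
    score = score)
  list(to = to, score = score, total = sum(score, na.rm = TRUE),
       pairs = pairs)
}

partition_entropy <- function(blocks) {
  p <- table(blocks) / length(blocks)
  -sum(p * log2(p))
}

#' Greedy selection of discriminatory variants
#'
#' Designs a minimal panel of variants whose joint hard-genotype patterns
#' distinguish all K donors, for targeted genotyping follow-up. Variants
#' with less than `min_umis` aggregate depth in any donor are removed
#' first (optionally also variants homozygous-ALT in every donor). The
#' donors start in a single block with partition entropy H = 0; each step
#' greedily adds the variant whose genotype pattern maximizes the
#' information gain, i.e. the increase in the (base-2, block-proportion
#' weighted) entropy of the partition induced jointly by the selected
#' variants. Selection stops when H = log2(K) (all donors separated) or no
#' variant adds gain, in which case the panel is reported incomplete with
#' the unresolved donor blocks named.
#'
#' @param g a [donor_genotypes()] object (fitted or reference profiles).
#' @param min_umis per-donor depth filter (default 20).
#' @param exclude_all_hom_alt drop variants called homozygous-ALT in all
#'   donors before selection (default FALSE).
#' @return List with `variants` (ordered selected ids), `partition`
#'   (donor block labels), `entropy` (bits, per greedy step), `complete`
#'   (logical), `target_entropy` (log2 K), `table` (per selected variant,
#'   the hard genotype of each donor).
#' @export
select_discriminatory_variants <- function(g, min_umis = 20,
                                           exclude_all_hom_alt = FALSE) {
  K <- length(g$donors)
  if (K < 2) stop("panel design needs K >= 2 donors")
  ok <- rowSums(g$depth >= min_umis & !is.na(g$hard)) == K
  if (exclude_all_hom_alt) ok <- ok & rowSums(g$hard == 2, na.rm = TRUE) < K
  cand <- which(ok)
  if (!length(cand)) stop("no variants pass the depth filter")
  hard <- g$hard[cand, , drop = FALSE]
  depth_tot <- rowSums(g$depth[cand, , drop = FALSE])
  depth_tot[!is.finite(depth_tot)] <- .Machine$double.xmax

  target <- log2(K)
  blocks <- rep(1L, K)
  H <- 0
  sel <- integer(0)
  Hpath <- numeric(0)
  avail <- rep(TRUE, length(cand))
  repeat {
    if (H >= target - 1e-9) break
    gains <- rep(-Inf, length(cand))
    for (v in which(avail)) {
      newb <- paste(blocks, hard[v, ])
      gains[v] <- partition_entropy(newb) - H
    }
    best_gain <- max(gains)
    if (best_gain <= 1e-12) break
    tie <- which(gains > best_gain - 1e-12)
    tie <- tie[order(-depth_tot[tie], tie)]
    v <- tie[1]
    sel <- c(sel, v)
    avail[v] <- FALSE
    blocks <- as.integer(factor(paste(blocks, hard[v, ])))
    H <- partition_entropy(blocks)
    Hpath <- c(Hpath, H)
  }
  complete <- H >= target - 1e-9
  if (!complete) {
    dup <- split(g$donors, blocks)
    dup <- dup[lengths(dup) > 1]
    warning("donors not fully separated; unresolved blocks: ",
            paste(vapply(dup, paste, "", collapse = "+"), collapse = "; "))
  }
  tab <- hard[sel, , drop = FALSE]
  rownames(tab) <- g$ids[cand[sel]]
  colnames(tab) <- g$donors
  list(variants = g$ids[cand[sel]], partition = blocks,
       entropy = Hpath, complete = complete, target_entropy = target,
       table = tab)
}
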