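#' SparCC compositional correlation
#'
#' Correlations between components of compositional count data (relative
#' abundances) are biased by the unit-sum constraint. SparCC estimates the
#' correlations of the unobserved basis abundances from log-ratio variances
#' t_ij = Var\[log(x_i/x_j)\] under a sparsity assumption: solving the linear
#' system T = M w for basis variances w = omega^2, where M has D-1 on the
#' diagonal and 1 off-diagonal, then rho_ij = (w_i + w_j - t_ij) /
#' (2 sqrt(w_i w_j)). Strongly correlated pairs violate the sparsity
#' assumption, so the single most correlated pair above an exclusion
#' threshold is iteratively removed from the system (a rank-one update) and
#' the system re-solved. Uncertainty in the fractions themselves is
#' integrated out by Dirichlet resampling of fractions from counts over
#' `n_inner` iterations, taking the median correlation.
#'
#' @name sparcc
NULL

# log-ratio variance matrix from a samples x components fraction matrix:
# t_ij = Var(log f_i) + Var(log f_j) - 2 Cov(log f_i, log f_j)
logratio_var <- function(frac) {
  lf <- log(frac)
  v <- stats::cov(lf)
  d <- diag(v)
  outer(d, d, "+") - 2 * v
}

# Solve the sparcc basis-variance system for one t matrix, with iterative
# exclusion of the strongest pair. Returns the correlation matrix.
sparcc_one <- function(tmat, exclusion_threshold, exclusion_rounds) {
  D <- nrow(tmat)
  Tsum <- rowSums(tmat)
  # base system M = (D-2) I + 11'; analytic inverse, then Sherman-Morrison
  # downdates M <- M - u u' (u = e_i + e_j) per excluded pair
  Minv <- diag(1 / (D - 2), D) - matrix(1 / ((D - 2) * (2 * D - 2)), D, D)
  excluded <- matrix(FALSE, D, D)
  rho_from <- function(w) {
    w <- pmax(w, 1e-12)
    sw <- sqrt(w)
    r <- (outer(w, w, "+") - tmat) / (2 * outer(sw, sw))
    diag(r) <- 1
    pmin(pmax(r, -1), 1)
  }
  w <- drop(Minv %*% Tsum)
  rho <- rho_from(w)
  for (round in seq_len(exclusion_rounds)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    # drop t_ij from both row sums and downdate the system matrix
    Tsum[i] <- Tsum[i] - tmat[i, j]
    Tsum[j] <- Tsum[j] - tmat[i, j]
    u <- numeric(D); u[i] <- 1; u[j] <- 1
    Mu <- Minv %*% u
    denom <- 1 - drop(crossprod(u, Mu))
    if (abs(denom) < 1e-12) break  # system would become singular
    Minv <- Minv + (Mu %*% t(Mu)) / denom
    w <- drop(Minv %*% Tsum)
    rho <- rho_from(w)
  }
  if (any(w < 0)) warning("negative basis variance clipped")
  rho
}

#' SparCC correlations between grass species and microbial taxa
#'
#' Stacks a grass table and one microbial table over shared samples, runs
#' SparCC on the joint composition, and extracts the grass x microbe block.
#'
#' @param grass_table [count_table()] with domain `"grass"`.
#' @param microbe_table [count_table()] of one microbial domain.
#' @param n_inner Dirichlet-resampling iterations (default 20); the returned
#'   correlation is the element-wise median.
#' @param exclusion_threshold correlation magnitude above which the strongest
#'   pair is excluded from the basis-variance system (default 0.1).
#' @param exclusion_rounds maximum exclusion iterations (default 10).
#' @param resample `FALSE` uses exact fractions (counts/total, with
#'   `pseudocount`) and a single pass - used by oracle tests.
#' @param pseudocount added to counts before forming fractions (default 1).
#' @param seed integer seed.
#' @return An `assoc_matrix` list: `r` (grass x microbe), `row_taxa`,
#'   `col_taxa`, `domain`, `n_iterations`, `seed`, plus `r_full` (the full
#'   joint correlation matrix, needed for deconvolution).
#' @export
sparcc_correlation <- function(grass_table, microbe_table, n_inner = 20L,
                               exclusion_threshold = 0.1,
                               exclusion_rounds = 10L,
                               resample = TRUE, pseudocount = 1,
                               seed = 1L) {
  stopifnot(identical(rownames(grass_table), rownames(microbe_table)))
  joint <- cbind(unclass(grass_table), unclass(microbe_table))
  if (nrow(joint) < 4L) stop("need at least 4 samples")
  if (ncol(joint) < 3L) stop("SparCC needs at least 3 components")
  ng <- ncol(grass_table)
  rfull <- sparcc_joint(joint, n_inner, exclusion_threshold, exclusion_rounds,
                        resample, pseudocount, seed)
  dimnames(rfull) <- list(colnames(joint), colnames(joint))
  structure(list(
    r = rfull[seq_len(ng), -seq_len(ng), drop = FALSE],
    p = NULL,
    r_full = rfull,
    row_taxa = colnames(grass_table),
    col_taxa = colnames(microbe_table),
    domain = ct_domain(microbe_table),
    n_iterations = if (resample) n_inner else 1L,
    n_bootstraps = 0L,
    seed = seed), class = "assoc_matrix")
}

sparcc_joint <- function(joint, n_inner, exclusion_threshold, exclusion_rounds,
                         resample, pseudocount, seed) {
  if (!resample) {
    frac <- (joint + pseudocount) / rowSums(joint + pseudocount)
    return(sparcc_one(logratio_var(frac), exclusion_threshold, exclusion_rounds))
  }
  D <- ncol(joint)
  rhos <- with_seed(derive_seed(seed, "sparcc"), {
    lapply(seq_len(n_inner), function(it) {
      # Dirichlet(counts + 1) resample of each sample's fractions
      g <- matrix(rgamma(length(joint), shape = joint + 1), nrow(joint), D)
      frac <- g / rowSums(g)
      suppressWarnings(
        sparcc_one(logratio_var(frac), exclusion_threshold, exclusion_rounds))
    })
  })
  elementwise_median(rhos, D)
}

# element-wise median over a list of equal-size matrices, via a vectorized
# bubble sorting network (n is small, each compare-swap is C-speed pmin/pmax)
elementwise_median <- function(mats, D) {
  n <- length(mats)
  if (n == 1L) return(mats[[1L]])
  for (pass in seq_len(n - 1L)) for (j in seq_len(n - pass)) {
    lo <- pmin(mats[[j]], mats[[j + 1L]])
    hi <- pmax(mats[[j]], mats[[j + 1L]])
    mats[[j]] <- lo; mats[[j + 1L]] <- hi
  }
  if (n %% 2L == 1L) mats[[(n + 1L) %/% 2L]]
  else (mats[[n %/% 2L]] + mats[[n %/% 2L + 1L]]) / 2
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix [grass x %s]: %d x %d, %s\n", x$domain,
              length(x$row_taxa), length(x$col_taxa),
              if (is.null(x$p)) "r only" else
                sprintf("r + p (%d bootstraps)", x$n_bootstraps)))
  invisible(x)
}

#' Bootstrap p-values for SparCC associations
#'
#' Builds a null by independently permuting each component's counts across
#' samples, recomputing SparCC, and comparing magnitudes per pair with the
#' add-one convention: p = (#\{|r_null| >= |r_obs|\} + 1) / (n_boot + 1),
#' two-sided.
#'
#' @param grass_table,microbe_table the tables used for `observed`.
#' @param observed the `assoc_matrix` from [sparcc_correlation()].
#' @param n_boot number of null resamples (default 100).
#' @param n_inner inner iterations per null recomputation (default 5; the
#'   null needs far less smoothing than the point estimate).
#' @param seed integer seed.
#' @return `observed` with `p` (grass x microbe) filled in.
#' @export
bootstrap_pvalues <- function(grass_table, microbe_table, observed,
                              n_boot = 100L, n_inner = 5L, seed = 1L) {
  if (n_boot < 20L) warning("n_boot < 20 gives coarse p-value resolution")
  joint <- cbind(unclass(grass_table), unclass(microbe_table))
  ng <- ncol(grass_table)
  robs <- abs(observed$r)
  exceed <- matrix(0L, nrow(robs), ncol(robs))
  n <- nrow(joint)
  base_seed <- derive_seed(seed, "sparccboot")
  for (b in seq_len(n_boot)) {
    null_joint <- with_seed(base_seed + b, {
      apply(joint, 2L, sample)  # break all couplings, keep margins
    })
    rn <- sparcc_joint(null_joint, n_inner, 0.1, 10L, TRUE, 1,
                       seed = base_seed + b)
    rb <- abs(rn[seq_len(ng), -seq_len(ng), drop = FALSE])
    exceed <- exceed + (rb >= robs)
  }
  observed$p <- (exceed + 1) / (n_boot + 1)
  dimnames(observed$p) <- dimnames(observed$r)
  observed$n_bootstraps <- n_boot
  observed
}
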