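# shared fixture builders and a per-session cache for expensive objects

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# default-world study, memoised by seed
study_fixture <- function(seed) {
  cached(paste0("study", seed), generate_study(generator_config(seed = seed)))
}

# small count table fixture
toy_table <- function(domain = "bacteria") {
  count_table(matrix(c(5L, 3L, 2L,
                       1L, 6L, 3L,
                       4L, 4L, 2L), 3, 3, byrow = TRUE,
                     dimnames = list(c("S1", "S2", "S3"),
                                     c("t1", "t2", "t3"))),
              domain)
}

# build a bipartite network straight from an incidence matrix
net_from_inc <- function(inc) {
  if (is.null(rownames(inc))) rownames(inc) <- paste0("p", seq_len(nrow(inc)))
  if (is.null(colnames(inc))) colnames(inc) <- paste0("m", seq_len(ncol(inc)))
  graminet:::network_from_incidence(inc)
}

# hand-built association matrix with p-values for filter tests
toy_assoc <- function(r, p) {
  rn <- paste0("g", seq_len(nrow(r)))
  cn <- paste0("m", seq_len(ncol(r)))
  dimnames(r) <- dimnames(p) <- list(rn, cn)
  full <- diag(length(rn) + length(cn))
  dimnames(full) <- list(c(rn, cn), c(rn, cn))
  full[rn, cn] <- r; full[cn, rn] <- t(r)
  structure(list(r = r, p = p, r_full = full, row_taxa = rn, col_taxa = cn,
                 domain = "bacteria", n_iterations = 1L, n_bootstraps = 99L,
                 seed = 1L), class = "assoc_matrix")
}

# independent brute-force NODF from the definition (oracle)
nodf_oracle <- function(inc) {
  inc <- (inc > 0) + 0
  pair_terms <- function(a) {
    n <- nrow(a); deg <- rowSums(a)
    out <- c()
    if (n < 2) return(out)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      hi <- if (deg[i] >= deg[j]) i else j; lo <- setdiff(c(i, j), hi)
      out <- c(out, if (deg[hi] == deg[lo] || deg[lo] == 0) 0 else
        100 * sum(a[hi, ] * a[lo, ]) / deg[lo])
    }
    out
  }
  mean(c(pair_terms(inc), pair_terms(t(inc))))
}

# exhaustive PERMANOVA p on small fixtures: enumerate all label permutations
permanova_exhaustive_p <- function(dm, groups) {
  d2 <- unclass(dm)^2
  n <- nrow(d2); a <- length(unique(groups))
  fstat <- function(g) {
    tot <- sum(d2[upper.tri(d2)]) / n
    wit <- 0
    for (l in unique(g)) {
      idx <- which(g == l)
      if (length(idx) > 1)
        wit <- wit + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((tot - wit) / (a - 1)) / (wit / (n - a))
  }
  f_obs <- fstat(groups)
  perms <- gtools_permutations(n)
  fs <- apply(perms, 1, function(o) fstat(groups[o]))
  mean(fs >= f_obs - 1e-12)
}

# all permutations of 1..n (n <= 6) without extra packages
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}
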