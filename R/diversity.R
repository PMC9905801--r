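#' Rarefaction, alpha diversity and Bray-Curtis beta diversity
#'
#' Read counts are normalized by rarefying every sample to a common depth
#' (subsampling without replacement, one seed-controlled draw per sample;
#' samples below the depth are dropped and reported). Alpha diversity is
#' summarized by observed richness, Shannon H' = -sum p_i ln p_i (nats),
#' Pielou J = H'/ln S (undefined when S <= 1) and Margalef (S-1)/ln N.
#' Community dissimilarity uses abundance-based Bray-Curtis.
#'
#' @name diversity
NULL

#' Rarefy a count table to fixed depth
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (e.g. 20828 for 16S, 10140 for ITS).
#' @param seed integer seed controlling the subsampling draw.
#' @return list with `table` (rarefied [count_table()]) and `dropped`
#'   (character vector of samples whose total was below `depth`).
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- rowSums(table)
  keep <- names(totals)[totals >= depth]
  dropped <- setdiff(rownames(table), keep)
  if (!length(keep)) stop("all samples fall below rarefaction depth ", depth)
  out <- with_seed(derive_seed(seed, "rarefy"), {
    res <- matrix(0L, length(keep), ncol(table),
                  dimnames = list(keep, colnames(table)))
    for (s in keep) {
      x <- as.integer(round(table[s, ]))
      if (sum(x) == depth) { res[s, ] <- x; next }
      draw <- sample.int(sum(x), depth)  # reads without replacement
      cum <- cumsum(x)
      res[s, ] <- tabulate(findInterval(draw - 1L, cum) + 1L, ncol(table))
    }
    res
  })
  list(table = count_table(out, ct_domain(table)), dropped = dropped)
}

#' Per-sample alpha diversity indices
#'
#' @param table a [count_table()].
#' @return data.frame with `sample_id`, `richness`, `shannon` (nats),
#'   `pielou` (NA when richness <= 1) and `margalef`.
#' @export
alpha_diversity <- function(table) {
  res <- t(apply(unclass(table), 1L, function(x) {
    n <- sum(x)
    p <- x[x > 0] / n
    s <- length(p)
    h <- -sum(p * log(p))
    c(richness = s,
      shannon = h,
      pielou = if (s > 1L) h / log(s) else NA_real_,
      margalef = if (n > 1) (s - 1) / log(n) else 0)
  }))
  data.frame(sample_id = rownames(table), res, row.names = rownames(table))
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(i, j) = 1 - 2 sum min(x_i, x_j) / (sum x_i + sum x_j).
#'
#' @param table a [count_table()] or plain abundance matrix (samples x taxa).
#' @return A [dist_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2L) stop("need at least 2 samples")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero-sum sample; filter before computing Bray-Curtis")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    # vectorized over the remaining samples
    js <- (i + 1L):n
    mins <- pmin(matrix(m[i, ], length(js), ncol(m), byrow = TRUE),
                 m[js, , drop = FALSE])
    bc <- 1 - 2 * rowSums(mins) / (tot[i] + tot[js])
    d[i, js] <- bc
    d[js, i] <- bc
  }
  dist_matrix(pmin(pmax(d, 0), 1), "bray_curtis")
}
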