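#' Variance partitioning on CCA inertia
#'
#' Community variation is decomposed among three explanatory-variable blocks
#' (grass productivity, grass diversity, soil variables) by running the seven
#' constrained correspondence analyses (each block alone, each pair, all
#' three) and applying inclusion-exclusion to the explained-inertia fractions.
#' Constrained inertia follows the CCA construction: the chi-square
#' standardized community matrix is projected onto the constraint space under
#' row (sample) weights.
#'
#' @name variance-partition
NULL

#' Fraction of community inertia explained by constraints (CCA)
#'
#' @param table a [count_table()] (samples x taxa).
#' @param constraints data.frame/matrix of numeric explanatory columns.
#' @param adjusted also return the Ezekiel-adjusted fraction.
#' @return list: `fraction`, `adjusted`, `total_inertia`, `constrained_inertia`,
#'   `rank` (number of independent constraints used).
#' @export
cca_inertia <- function(table, constraints, adjusted = TRUE) {
  y <- unclass(as.matrix(table))
  y <- y[, colSums(y) > 0, drop = FALSE]
  if (any(rowSums(y) <= 0)) stop("zero-sum sample in community table")
  x <- as.matrix(as.data.frame(constraints))
  if (!is.numeric(x)) stop("constraints must be numeric")
  n <- nrow(y)
  if (nrow(x) != n) stop("constraints must match samples")
  if (ncol(x) >= n) stop("more constraints than samples allow")
  p <- y / sum(y)
  r <- rowSums(p); c <- colSums(p)
  # chi-square standardized residuals from independence
  q <- (p - outer(r, c)) / sqrt(outer(r, c))
  total <- sum(q^2)
  # weighted projection of q onto span(x): columns centred by row weights
  xw <- sweep(x, 2L, colSums(x * r), "-")            # weighted centring
  xs <- xw * sqrt(r)                                  # weight the metric
  qr_x <- qr(xs)
  rank <- qr_x$rank
  if (rank < ncol(xs))
    warning("dropping ", ncol(xs) - rank, " collinear constraint column(s)")
  constrained <- if (rank == 0L) 0 else sum(qr.fitted(qr_x, q)^2)
  frac <- constrained / total
  adj <- if (adjusted) {
    if (n - rank - 1 > 0) 1 - (1 - frac) * (n - 1) / (n - rank - 1) else NA_real_
  } else NA_real_
  list(fraction = frac, adjusted = adj, total_inertia = total,
       constrained_inertia = constrained, rank = rank)
}

#' Three-way variance partitioning (VPA)
#'
#' @param table a [count_table()].
#' @param block_a,block_b,block_c data.frames of numeric explanatory columns
#'   (conventionally productivity, diversity, soil).
#' @param adjusted partition adjusted (Ezekiel) fractions instead of raw.
#' @return A `vpa_result` list: unique fractions `a`, `b`, `c`; pairwise
#'   shared `ab`, `ac`, `bc`; triple shared `abc`; `total_explained`;
#'   `residual`; and the seven model fractions in `components`.
#' @export
vpa_three_way <- function(table, block_a, block_b, block_c, adjusted = FALSE) {
  blocks <- list(a = as.data.frame(block_a), b = as.data.frame(block_b),
                 c = as.data.frame(block_c))
  if (any(vapply(blocks, ncol, 0L) == 0L)) stop("empty explanatory block")
  frac <- function(bl) {
    res <- cca_inertia(table, do.call(cbind, unname(bl)), adjusted = adjusted)
    if (adjusted) res$adjusted else res$fraction
  }
  fa <- frac(blocks["a"]); fb <- frac(blocks["b"]); fc <- frac(blocks["c"])
  fab <- frac(blocks[c("a", "b")]); fac <- frac(blocks[c("a", "c")])
  fbc <- frac(blocks[c("b", "c")]); fabc <- frac(blocks)
  # inclusion-exclusion on explained fractions
  a <- fabc - fbc; b <- fabc - fac; c <- fabc - fab
  ab <- fac + fbc - fc - fabc
  ac <- fab + fbc - fb - fabc
  bc <- fab + fac - fa - fabc
  abc <- fabc - a - b - c - ab - ac - bc
  structure(list(a = a, b = b, c = c, ab = ab, ac = ac, bc = bc, abc = abc,
                 total_explained = fabc, residual = 1 - fabc,
                 adjusted = adjusted,
                 components = c(a = fa, b = fb, c = fc, ab = fab, ac = fac,
                                bc = fbc, abc = fabc)),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf(paste0("VPA (%s fractions): total explained %.1f%%\n",
                     "  unique: a=%.2f%% b=%.2f%% c=%.2f%%\n",
                     "  shared: ab=%.2f%% ac=%.2f%% bc=%.2f%% abc=%.2f%%\n"),
              if (x$adjusted) "adjusted" else "raw",
              100 * x$total_explained, 100 * x$a, 100 * x$b, 100 * x$c,
              100 * x$ab, 100 * x$ac, 100 * x$bc, 100 * x$abc))
  invisible(x)
}
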