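#' @keywords internal
#' @useDynLib graminet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' @importFrom stats cor cor.test sd var rnorm runif rbinom rmultinom rgamma
#'   kruskal.test p.adjust pnorm lm coef vcov pt quantile median dist aggregate
#'   setNames complete.cases rlnorm
#' @importFrom utils read.delim write.table combn head
NULL

# Derive a reproducible 32-bit child seed from a master seed and a stream tag.
# Every stochastic sub-step of the package draws its own child so that adding
# or reordering steps never perturbs unrelated streams.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0 + 13.0) %% 214748329)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Upper-triangle vectorization used throughout for pairwise (distance) data.
# Order is column-major over j > i: (1,2), (1,3), (2,3), (1,4), ... — the same
# order base R's lower.tri/upper.tri indexing produces; fixed and documented so
# pair-level fits are reproducible.
upper_vec <- function(m) m[upper.tri(m)]

# Index pairs corresponding to upper_vec order.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
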