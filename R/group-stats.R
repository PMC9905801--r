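#' Grassland-type group statistics
#'
#' Differences among grassland types are screened non-parametrically:
#' Kruskal-Wallis across types, then (if significant) pairwise Dunn tests with
#' Benjamini-Hochberg correction, summarized as compact letter displays
#' (groups sharing a letter are not significantly different at alpha).
#' Spearman rank correlation relates microbial alpha diversity to grass
#' diversity/productivity and soil variables. PERMANOVA partitions squared
#' Bray-Curtis distances among vs. within grassland types with a permutation
#' test.
#'
#' @name group-stats
NULL

#' Kruskal-Wallis with Dunn post-hoc and compact letters
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels (e.g. grassland types), same length.
#' @param alpha significance level for letter assignment (default 0.05).
#' @return list: `kw_p`, `summary` (group, n, mean, sd, letter), `pairwise`
#'   (Dunn z and BH-adjusted p per pair).
#' @export
kruskal_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 observations")
  lev <- names(tab)
  kw_p <- if (length(unique(values)) == 1L) 1 else
    suppressWarnings(kruskal.test(values, factor(groups))$p.value)
  if (is.na(kw_p)) kw_p <- 1
  pw <- dunn_pairwise(values, groups, lev)
  # only call pairwise differences when the omnibus test is significant
  sig <- if (kw_p < alpha) pw$p_adj < alpha else rep(FALSE, nrow(pw))
  letters <- compact_letters(lev, pw$g1, pw$g2, sig)
  summary <- data.frame(
    group = lev,
    n = as.integer(tab[lev]),
    mean = vapply(lev, function(g) mean(values[groups == g]), 0),
    sd = vapply(lev, function(g) sd(values[groups == g]), 0),
    letter = letters[lev],
    row.names = NULL)
  list(kw_p = kw_p, summary = summary, pairwise = pw)
}

# Dunn (1964) rank-sum z tests with tie correction, BH-adjusted.
dunn_pairwise <- function(values, groups, lev) {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- vapply(lev, function(g) mean(r[groups == g]), 0)
  ng <- vapply(lev, function(g) sum(groups == g), 0L)
  pairs <- t(combn(lev, 2L))
  z <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    se2 <- (n * (n + 1) / 12 - tie_corr) * (1 / ng[a] + 1 / ng[b])
    z[k] <- if (se2 > 0) (mean_rank[a] - mean_rank[b]) / sqrt(se2) else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(g1 = pairs[, 1L], g2 = pairs[, 2L], z = z, p = p,
             p_adj = p.adjust(p, "BH"))
}

# Insert-and-absorb compact letter display (Piepho-style): start with one
# letter column; for each significantly different pair sharing a column,
# duplicate the column, drop one member from each copy, then absorb columns
# contained in others.
compact_letters <- function(lev, g1, g2, sig) {
  cols <- list(setNames(rep(TRUE, length(lev)), lev))
  for (k in which(sig)) {
    a <- g1[k]; b <- g2[k]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[a] && col[b]) {
        c1 <- col; c1[a] <- FALSE
        c2 <- col; c2[b] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop any column whose members are a subset of another's
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(!cols[[i]] | cols[[j]]) && !identical(cols[[i]], cols[[j]]))
        keep[i] <- FALSE
      if (i < j && keep[i] && keep[j] && identical(cols[[i]], cols[[j]]))
        keep[j] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the first group they contain, label a, b, c, ...
  first <- vapply(cols, function(col) which(col)[1L], 0L)
  cols <- cols[order(first)]
  out <- vapply(lev, function(g)
    paste0(letters[which(vapply(cols, `[`, TRUE, g))], collapse = ""), "")
  setNames(out, lev)
}

#' Spearman correlation screen between two variable blocks
#'
#' @param x_block,y_block data.frames/matrices of numeric columns over the
#'   same samples.
#' @param adjust optional p adjustment across the screen (`"none"` default,
#'   matching raw significance stars; `"BH"` available).
#' @return list of matrices `rho`, `p`, `stars` (y columns x x columns).
#' @export
spearman_matrix <- function(x_block, y_block, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x_block <- as.data.frame(x_block); y_block <- as.data.frame(y_block)
  if (nrow(x_block) != nrow(y_block)) stop("blocks must share samples")
  if (nrow(x_block) < 4L) stop("need n >= 4 paired samples")
  rho <- p <- matrix(NA_real_, ncol(y_block), ncol(x_block),
                     dimnames = list(names(y_block), names(x_block)))
  for (i in seq_len(ncol(y_block))) for (j in seq_len(ncol(x_block))) {
    xv <- x_block[[j]]; yv <- y_block[[i]]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 4L || sd(xv[ok]) == 0 || sd(yv[ok]) == 0) next
    ct <- suppressWarnings(cor.test(xv[ok], yv[ok], method = "spearman"))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  if (adjust == "BH") p[] <- p.adjust(p, "BH")
  stars <- matrix(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "")),
                  nrow(p), ncol(p), dimnames = dimnames(p))
  list(rho = rho, p = p, stars = stars)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate ANOVA (Anderson 2001): pseudo-F from the
#' among/within partition of squared distances, p by permuting group labels,
#' with the add-one convention p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1).
#'
#' @param dm a [dist_matrix()].
#' @param groups group labels aligned with `dm` rows.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list: `f`, `r2`, `p`, `n_perm`, `singleton_groups` flag.
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  d2 <- unclass(dm)^2
  groups <- as.character(groups)
  n <- nrow(d2)
  stopifnot(length(groups) == n)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  singletons <- names(which(table(groups) == 1L))
  ss <- function(g) {
    # total SS = sum_{i<j} d2 / n ; within SS summed per group
    tot <- sum(d2[upper.tri(d2)]) / n
    wit <- 0
    for (l in unique(g)) {
      idx <- which(g == l)
      if (length(idx) > 1L)
        wit <- wit + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    c(tot = tot, wit = wit)
  }
  a <- length(lev)
  obs <- ss(groups)
  f_stat <- function(s) ((s["tot"] - s["wit"]) / (a - 1)) / (s["wit"] / (n - a))
  f_obs <- unname(f_stat(obs))
  r2 <- unname((obs["tot"] - obs["wit"]) / obs["tot"])
  perm_f <- with_seed(derive_seed(seed, "permanova"), {
    vapply(seq_len(n_perm), function(k) unname(f_stat(ss(sample(groups)))), 0)
  })
  p <- (sum(perm_f >= f_obs) + 1) / (n_perm + 1)
  list(f = f_obs, r2 = r2, p = p, n_perm = n_perm,
       singleton_groups = singletons)
}
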