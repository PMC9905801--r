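#' Distance-decay relationships
#'
#' Community dissimilarity (Bray-Curtis) is regressed on pairwise geographic
#' distance (great-circle, km) or on divergence in grass productivity,
#' diversity, or soil variables (Euclidean distance on z-scored variables).
#' Because the n(n-1)/2 pairs are not independent, slope significance is also
#' assessed by Mantel-style matrix permutation; cross-group slope contrasts
#' use a pooled regression with a group x predictor interaction.
#'
#' @name distance-decay
NULL

EARTH_RADIUS_KM <- 6371

#' Great-circle distance matrix (haversine, km)
#' @param frame a [sample_frame()] with latitude/longitude in decimal degrees.
#' @return A [dist_matrix()] with metric `"haversine_km"`.
#' @export
geographic_distance_matrix <- function(frame) {
  lat <- frame$latitude; lon <- frame$longitude
  if (anyNA(lat) || anyNA(lon)) stop("missing coordinates")
  phi <- lat * pi / 180; lam <- lon * pi / 180
  n <- length(phi)
  d <- matrix(0, n, n, dimnames = list(frame$sample_id, frame$sample_id))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    h <- sin((phi[js] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[js]) * sin((lam[js] - lam[i]) / 2)^2
    dk <- 2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
    d[i, js] <- dk; d[js, i] <- dk
  }
  dist_matrix(d, "haversine_km")
}

#' Euclidean divergence matrix over standardized variables
#' @param frame a [sample_frame()].
#' @param variables column names to include (z-scored before distances).
#' @return A [dist_matrix()] with metric `"euclidean_z"`.
#' @export
variable_divergence_matrix <- function(frame, variables) {
  miss <- setdiff(variables, names(frame))
  if (length(miss)) stop("variables not in frame: ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(frame)[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("variables must be numeric")
  keep <- apply(x, 2L, function(v) isTRUE(sd(v) > 0))
  if (!all(keep)) {
    warning("dropping zero-variance variable(s): ",
            paste(variables[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-constant variables left")
  z <- scale(x)
  d <- as.matrix(dist(z))
  dimnames(d) <- list(frame$sample_id, frame$sample_id)
  dist_matrix(d, "euclidean_z")
}

#' Fit a distance-decay regression
#'
#' OLS of the vectorized upper triangles: dissimilarity ~ predictor distance.
#' Reports both the naive OLS p and a Mantel-style permutation p (rows and
#' columns of the predictor matrix permuted jointly).
#'
#' @param community_dm community dissimilarity [dist_matrix()].
#' @param predictor_dm predictor [dist_matrix()] with the same labels.
#' @param group optional organism-group label stored in the fit.
#' @param log10_predictor set `TRUE` to regress on log10(predictor).
#' @param n_perm matrix permutations for the slope p (default 999).
#' @param seed permutation seed.
#' @return A `ddr_fit` list: `group`, `slope`, `intercept`, `r2`, `p_ols`,
#'   `p_perm`, `n_pairs`, plus the pair vectors `x`, `y`.
#' @export
fit_ddr <- function(community_dm, predictor_dm, group = "community",
                    log10_predictor = FALSE, n_perm = 999L, seed = 1L) {
  stopifnot(nrow(community_dm) == nrow(predictor_dm))
  if (!identical(rownames(community_dm), rownames(predictor_dm)))
    predictor_dm <- dm_subset(predictor_dm, rownames(community_dm))
  n <- nrow(community_dm)
  if (n < 4L) stop("need at least 4 samples")
  y <- upper_vec(unclass(community_dm))
  xm <- unclass(predictor_dm)
  if (log10_predictor) {
    if (any(xm[upper.tri(xm)] <= 0)) stop("log10 predictor needs positive distances")
    xm <- log10(xm); diag(xm) <- 0
  }
  x <- upper_vec(xm)
  if (sd(x) == 0) stop("predictor distances are constant; slope undefined")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  sm <- summary(fit)
  perm_stat <- with_seed(derive_seed(seed, "ddr"), {
    vapply(seq_len(n_perm), function(k) {
      o <- sample.int(n)
      xp <- upper_vec(xm[o, o])
      if (sd(xp) == 0) return(0)
      unname(coef(lm(y ~ xp))[2L])
    }, 0)
  })
  p_perm <- (sum(abs(perm_stat) >= abs(slope)) + 1) / (n_perm + 1)
  structure(list(group = group, slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r2 = sm$r.squared,
                 p_ols = sm$coefficients[2L, 4L],
                 p_perm = p_perm, n_pairs = length(y), x = x, y = y),
            class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf("DDR [%s]: slope %.4f, r2 %.3f, p(perm) %.4g over %d pairs\n",
              x$group, x$slope, x$r2, x$p_perm, x$n_pairs))
  invisible(x)
}

#' Pairwise slope contrasts across organism groups
#'
#' Pools the pair-level data of several [fit_ddr()] objects sharing one
#' predictor, fits dissimilarity ~ distance * group, and tests each pairwise
#' interaction contrast (difference in slopes) with BH correction.
#'
#' @param fits list of `ddr_fit` objects.
#' @return data.frame: `g1`, `g2`, `slope_diff`, `se`, `t`, `p`, `p_adj`.
#' @export
compare_slopes <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to contrast")
  grp <- vapply(fits, `[[`, "", "group")
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(x = f$x, y = f$y, g = f$group)))
  df$g <- factor(df$g, levels = grp)
  fit <- lm(y ~ x * g, data = df)
  b <- coef(fit); V <- vcov(fit)
  slope_of <- function(g) {
    v <- setNames(numeric(length(b)), names(b))
    v["x"] <- 1
    nm <- paste0("x:g", g)
    if (nm %in% names(b)) v[nm] <- 1
    v
  }
  pairs <- t(combn(grp, 2L))
  out <- data.frame(g1 = pairs[, 1L], g2 = pairs[, 2L],
                    slope_diff = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_)
  for (k in seq_len(nrow(pairs))) {
    cvec <- slope_of(pairs[k, 1L]) - slope_of(pairs[k, 2L])
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    out$slope_diff[k] <- est; out$se[k] <- se; out$t[k] <- tval
    out$p[k] <- 2 * pt(-abs(tval), df = fit$df.residual)
  }
  out$p_adj <- p.adjust(out$p, "BH")
  out
}
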