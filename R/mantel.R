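#' Mantel tests and network connectivity profiles
#'
#' Relates grass-microbe network connectivity to grass productivity,
#' diversity and soil variables. Each sample gets a connectivity score
#' (degree-weighted summed relative abundance of network taxa present in the
#' sample); Euclidean distances between scores give the connectivity matrix,
#' which is tested against variable-divergence matrices with Mantel and
#' partial Mantel permutation tests.
#'
#' @name mantel
NULL

#' Per-sample network connectivity profile
#'
#' Score(sample) = sum over network nodes of node degree x relative abundance
#' of that node's taxon in the sample (`weighted = FALSE` uses presence only:
#' the summed degree of network taxa present).
#'
#' @param net a `bipartite_network`.
#' @param tables named list of [count_table()]s resolving every node.
#' @param weighted weight degrees by relative abundance (default TRUE).
#' @return list: `scores` (named numeric per sample), `dm` (Euclidean
#'   [dist_matrix()] of scores), `empty_samples` (no network taxon present).
#' @export
sample_connectivity_profile <- function(net, tables, weighted = TRUE) {
  inc <- incidence_matrix(net)
  deg <- c(rowSums(inc), colSums(inc))
  names(deg) <- c(rownames(inc), colnames(inc))
  samples <- rownames(tables[[1L]])
  scores <- setNames(numeric(length(samples)), samples)
  found <- setNames(logical(length(deg)), names(deg))
  for (t in tables) {
    rel <- unclass(t) / rowSums(t)
    hit <- intersect(colnames(rel), names(deg))
    found[hit] <- TRUE
    if (!length(hit)) next
    w <- if (weighted) rel[samples, hit, drop = FALSE]
         else (rel[samples, hit, drop = FALSE] > 0) + 0
    scores <- scores + drop(w %*% deg[hit])
  }
  if (any(!found))
    stop("network node(s) unresolved in tables: ",
         paste(names(found)[!found][1:5], collapse = ", "))
  d <- as.matrix(dist(scores))
  dimnames(d) <- list(samples, samples)
  list(scores = scores, dm = dist_matrix(d, "connectivity_euclidean"),
       empty_samples = names(scores)[scores == 0])
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the vectorized upper triangles; p comes
#' from jointly permuting rows and columns of the second matrix,
#' p = (#\{|r_perm| >= |r_obs|\} + 1) / (n_perm + 1) two-sided, with the
#' one-tailed (greater) p also reported.
#'
#' @param dm_a,dm_b [dist_matrix()] objects with matching labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param tail `"two_sided"` (default) or `"greater"` for the returned `p`.
#' @return A `mantel_result` list: `r`, `p`, `p_greater`, `n_perm`,
#'   `controlled` (character(0) here).
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 999L, seed = 1L,
                        tail = c("two_sided", "greater")) {
  tail <- match.arg(tail)
  stopifnot(nrow(dm_a) == nrow(dm_b))
  n <- nrow(dm_a)
  if (n < 4L) stop("need at least 4 samples")
  a <- upper_vec(unclass(dm_a)); bmat <- unclass(dm_b)
  b <- upper_vec(bmat)
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, p_greater = NA_real_,
                          n_perm = n_perm, controlled = character(0)),
                     class = "mantel_result"))
  r_obs <- cor(a, b)
  perm_r <- with_seed(derive_seed(seed, "mantel"), {
    vapply(seq_len(n_perm), function(k) {
      o <- sample.int(n)
      cor(a, upper_vec(bmat[o, o]))
    }, 0)
  })
  p_two <- (sum(abs(perm_r) >= abs(r_obs)) + 1) / (n_perm + 1)
  p_gr <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p = if (tail == "greater") p_gr else p_two,
                 p_greater = p_gr, p_two_sided = p_two, n_perm = n_perm,
                 controlled = character(0)),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Partial Pearson correlation of the upper triangles of `dm_a` and `dm_b`
#' given `dm_control` (residual method); the permutation scheme permutes
#' `dm_b`'s labels and recomputes the partial statistic.
#'
#' @param dm_a,dm_b,dm_control [dist_matrix()] objects, matching labels.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param tail `"two_sided"` (default) or `"greater"`.
#' @return A `mantel_result`; `degenerate_control` flags a constant control
#'   matrix (the test then equals a plain Mantel test).
#' @export
partial_mantel_test <- function(dm_a, dm_b, dm_control, n_perm = 999L,
                                seed = 1L, tail = c("two_sided", "greater")) {
  tail <- match.arg(tail)
  n <- nrow(dm_a)
  if (n < 4L) stop("need at least 4 samples")
  a <- upper_vec(unclass(dm_a))
  bmat <- unclass(dm_b)
  cvec <- upper_vec(unclass(dm_control))
  degenerate <- sd(cvec) == 0
  pcor <- function(x, y, z) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    if (sd(z) == 0) return(cor(x, y))
    rxz <- cor(x, z); ryz <- cor(y, z); rxy <- cor(x, y)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r_obs <- pcor(a, upper_vec(bmat), cvec)
  if (is.na(r_obs))
    return(structure(list(r = NA_real_, p = NA_real_, p_greater = NA_real_,
                          n_perm = n_perm,
                          controlled = attr(dm_control, "metric"),
                          degenerate_control = degenerate),
                     class = "mantel_result"))
  perm_r <- with_seed(derive_seed(seed, "pmantel"), {
    vapply(seq_len(n_perm), function(k) {
      o <- sample.int(n)
      pcor(a, upper_vec(bmat[o, o]), cvec)
    }, 0)
  })
  perm_r <- perm_r[is.finite(perm_r)]
  p_two <- (sum(abs(perm_r) >= abs(r_obs)) + 1) / (length(perm_r) + 1)
  p_gr <- (sum(perm_r >= r_obs) + 1) / (length(perm_r) + 1)
  structure(list(r = r_obs, p = if (tail == "greater") p_gr else p_two,
                 p_greater = p_gr, p_two_sided = p_two, n_perm = n_perm,
                 controlled = attr(dm_control, "metric"),
                 degenerate_control = degenerate),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel%s: r = %.3f, p = %.4g (%d permutations)\n",
              if (length(x$controlled)) paste0(" | ", x$controlled) else "",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Connectivity vs. variables: the partial-Mantel screen
#'
#' For each listed variable, builds its single-variable divergence matrix and
#' runs a partial Mantel test of the network-connectivity matrix against it.
#' Productivity and diversity variables are controlled for the soil-variable
#' divergence; soil variables are controlled for the productivity divergence;
#' geographic distance is always added to the control (via a combined
#' control: the control distances are z-scored and summed).
#'
#' @param conn_dm connectivity [dist_matrix()] from
#'   [sample_connectivity_profile()].
#' @param frame aligned [sample_frame()] (plus grass alpha-diversity columns
#'   if diversity variables are tested).
#' @param variables named list of character vectors by group, e.g.
#'   `list(productivity = c("H","CD","S","FB","DB"), soil = c("pH","TN"))`.
#' @param geo_dm geographic [dist_matrix()] (always controlled when given).
#' @param n_perm,seed,tail passed to [partial_mantel_test()].
#' @return data.frame: `group`, `variable`, `r`, `p`.
#' @export
connectivity_mantel_screen <- function(conn_dm, frame, variables,
                                       geo_dm = NULL, n_perm = 999L,
                                       seed = 1L, tail = "two_sided") {
  stopifnot(is.list(variables), !is.null(names(variables)))
  z_upper <- function(dm) {
    v <- upper_vec(unclass(dm))
    if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  }
  control_matrix <- function(group) {
    other <- if (group == "soil") "productivity" else "soil"
    parts <- list()
    if (other %in% names(variables)) {
      vars <- intersect(variables[[other]], names(frame))
      if (length(vars))
        parts <- c(parts, list(variable_divergence_matrix(frame, vars)))
    }
    if (!is.null(geo_dm)) parts <- c(parts, list(geo_dm))
    if (!length(parts)) return(NULL)
    zsum <- Reduce(`+`, lapply(parts, z_upper))
    n <- nrow(conn_dm)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- zsum - min(zsum)  # shift non-negative
    m <- m + t(m)
    dist_matrix(m, "control_combined", labels = rownames(conn_dm))
  }
  out <- list()
  for (g in names(variables)) {
    ctrl <- control_matrix(g)
    for (v in intersect(variables[[g]], names(frame))) {
      if (sd(frame[[v]]) == 0) next
      vdm <- variable_divergence_matrix(frame, v)
      res <- if (is.null(ctrl))
        mantel_test(conn_dm, vdm, n_perm = n_perm,
                    seed = derive_seed(seed, paste0("scr", g, v)), tail = tail)
      else
        partial_mantel_test(conn_dm, vdm, ctrl, n_perm = n_perm,
                            seed = derive_seed(seed, paste0("scr", g, v)),
                            tail = tail)
      out[[length(out) + 1L]] <- data.frame(group = g, variable = v,
                                            r = res$r, p = res$p)
    }
  }
  do.call(rbind, out)
}
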