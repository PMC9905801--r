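#' Inter-domain ecological network construction
#'
#' The IDEN chain turns SparCC association matrices into bipartite
#' grass-microbe networks: (1) filter associations at |r| >= 0.3 and
#' p < 0.05; (2) deconvolve indirect, path-transitive influence so each
#' retained edge carries only its direct strength, removing edges whose
#' direct strength falls below the filter threshold; (3) prune edges better
#' explained by a shared environmental driver or by geographic distance
#' (LTED screen). Every pruned edge is logged with the triggering variable.
#'
#' @name iden
NULL

new_bipartite_network <- function(edges, plant_nodes, microbe_nodes,
                                  microbe_domains) {
  structure(list(edges = edges, plant_nodes = plant_nodes,
                 microbe_nodes = microbe_nodes,
                 microbe_domains = microbe_domains),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d grass x %d microbe nodes, %d edges\n",
              length(x$plant_nodes), length(x$microbe_nodes), nrow(x$edges)))
  invisible(x)
}

# drop nodes left without edges; keep node bookkeeping consistent
trim_network <- function(net) {
  keep_p <- intersect(net$plant_nodes, unique(net$edges$plant))
  keep_m <- intersect(net$microbe_nodes, unique(net$edges$microbe))
  net$plant_nodes <- keep_p
  net$microbe_nodes <- keep_m
  net$microbe_domains <- net$microbe_domains[keep_m]
  net
}

#' Threshold an association matrix into a bipartite network
#'
#' Keeps grass-microbe pairs with |r| >= `r_threshold` AND p < `p_threshold`
#' (threshold inclusive on r, exclusive on p).
#'
#' @param am an `assoc_matrix` with bootstrap p-values.
#' @param r_threshold correlation magnitude cutoff (default 0.3).
#' @param p_threshold significance cutoff (default 0.05).
#' @return A `bipartite_network`; nodes without retained edges are excluded.
#' @export
filter_associations <- function(am, r_threshold = 0.3, p_threshold = 0.05) {
  if (is.null(am$p)) stop("association matrix has no p-values; run bootstrap_pvalues()")
  keep <- abs(am$r) >= r_threshold & am$p < p_threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    plant = am$row_taxa[idx[, 1L]],
    microbe = am$col_taxa[idx[, 2L]],
    domain = rep(am$domain, nrow(idx)),
    r = am$r[idx], p = am$p[idx],
    direct_strength = am$r[idx],
    sign = ifelse(am$r[idx] >= 0, 1L, -1L),
    filtered_in = TRUE, deconvolved = FALSE, lted_pruned = FALSE,
    pruned_by = NA_character_,
    stringsAsFactors = FALSE)
  net <- new_bipartite_network(
    edges, plant_nodes = am$row_taxa, microbe_nodes = am$col_taxa,
    microbe_domains = setNames(rep(am$domain, length(am$col_taxa)),
                               am$col_taxa))
  trim_network(net)
}

#' Deconvolve direct from indirect association strengths
#'
#' Solves the transitivity fixed point G = S (+) (S.G): the observed total
#' association G between two nodes is the bounded combination of the direct
#' strength S and the influence along all two-step paths, where influence
#' along a path multiplies edge strengths and parallel contributions combine
#' with the bounded operator u (+) v = (u + v) / (1 + uv) (tanh addition).
#' Solved for S by damped fixed-point iteration from S = G.
#'
#' @param g symmetric matrix of observed total associations in (-1, 1),
#'   zero diagonal (or diagonal is ignored).
#' @param tol convergence tolerance on max absolute change (default 1e-6).
#' @param max_iter iteration cap (default 400).
#' @param damping step fraction toward the new iterate (default 0.5).
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation; identical semantics, used as a cross-check in tests).
#' @return list: `s` direct-strength matrix, `converged`, `iterations`.
#' @export
idirect_deconvolve <- function(g, tol = 1e-6, max_iter = 400L, damping = 0.5,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  g <- as.matrix(g)
  stopifnot(nrow(g) == ncol(g))
  if (engine == "cpp") {
    res <- .idirect_iterate_cpp(unname(g), tol, as.integer(max_iter), damping)
    if (!res$converged)
      warning("deconvolution did not converge in ", max_iter, " iterations")
    dimnames(res$s) <- dimnames(g)
    return(res[c("s", "converged", "iterations")])
  }
  clip <- function(x, lim = 0.99) { x[x > lim] <- lim; x[x < -lim] <- -lim; x }
  g <- clip(g); diag(g) <- 0
  D <- nrow(g)
  a_g <- atanh(g)                            # constant across iterations
  s <- g
  converged <- FALSE
  iter <- 0L
  lambda <- damping
  delta_prev <- Inf
  stalled <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # v_ij = (+)-combination over k != i, j of the influence along the
    # two-step path i - k - j (tanh of summed atanh path influences)
    v <- matrix(0, D, D)
    for (i in seq_len(D)) {
      nz <- which(s[i, ] != 0)               # paths start on an edge of i
      if (!length(nz)) next
      # echo correction: the influence carried from k to j must exclude the
      # part of g_kj that is itself induced through the focal edge (i, j),
      # i.e. the path k - i - j; otherwise two true edges sharing a
      # neighbour annihilate each other
      echo <- atanh(clip(outer(s[i, nz], s[i, ])))
      g_eff <- tanh(a_g[nz, , drop = FALSE] - echo)
      terms <- atanh(clip(s[i, nz] * g_eff))
      terms[cbind(seq_along(nz), nz)] <- 0   # k = j is not a path
      v[i, ] <- tanh(.colSums(terms, length(nz), D))
    }
    v[cbind(seq_len(D), seq_len(D))] <- 0
    # invert the (+) combination in additive (atanh) coordinates:
    # g = s (+) v  <=>  atanh g = atanh s + atanh v. Same-sign indirect
    # influence is capped at the observed total, so a fully-explained edge
    # shrinks to zero instead of flipping sign (which feeds back as
    # oscillation through the path terms).
    a_v <- atanh(clip(v))
    same <- sign(a_g) * sign(a_v) > 0
    a_v[same] <- sign(a_g[same]) * pmin(abs(a_v[same]), abs(a_g[same]))
    s_cand <- clip(tanh(a_g - a_v))
    s_cand[g == 0] <- 0    # direct strength only where a total is observed
    s_cand <- (s_cand + t(s_cand)) / 2       # keep the solution symmetric
    s_new <- (1 - lambda) * s + lambda * s_cand
    delta <- max(abs(s_new - s))
    if (delta > delta_prev) lambda <- max(lambda / 2, 0.02)  # tame oscillation
    stalled <- if (delta > 0.99 * delta_prev) stalled + 1L else 0L
    delta_prev <- delta
    s <- s_new
    if (delta < tol) { converged <- TRUE; break }
    if (stalled >= 25L && delta < 1e-3) break  # oscillating at numerical floor
  }
  if (!converged) warning("deconvolution did not converge in ", max_iter,
                          " iterations")
  diag(s) <- 0
  dimnames(s) <- dimnames(g)
  list(s = s, converged = converged, iterations = iter)
}

# subtract the k = j term v would otherwise include: handled above because
# diag(g) = 0 makes the k = j column term s_ij * g_jj = 0, and diag(s) = 0
# kills k = i. (kept as a note; no code needed)

#' Apply deconvolution to a filtered network
#'
#' Runs [idirect_deconvolve()] on the joint correlation submatrix over the
#' network's retained nodes and replaces each edge's weight by its direct
#' strength; edges whose direct strength drops below `r_threshold` are
#' removed and flagged.
#'
#' @param net a `bipartite_network` from [filter_associations()].
#' @param am the originating `assoc_matrix` (provides `r_full`).
#' @param r_threshold direct-strength retention cutoff (default 0.3).
#' @param max_iter optional iteration cap for the solver.
#' @return The updated network; removed edges are kept in `attr(, "removed")`.
#' @export
deconvolve_network <- function(net, am, r_threshold = 0.3, max_iter = NULL) {
  if (!nrow(net$edges)) return(net)
  nodes <- c(net$plant_nodes, net$microbe_nodes)
  g <- am$r_full[nodes, nodes]
  # indirect influence flows through the association NETWORK, not the dense
  # correlation matrix: sub-threshold entries (any block, including
  # grass-grass and microbe-microbe conduits) carry no path influence
  g[abs(g) < r_threshold] <- 0
  # direct strengths are compared with the 0.3 threshold, so 1e-5 precision
  # is ample; large nets cap the iteration budget
  if (is.null(max_iter)) max_iter <- if (nrow(g) > 250) 150L else 400L
  dec <- suppressWarnings(idirect_deconvolve(g, tol = 1e-5,
                                             max_iter = max_iter))
  s <- dec$s
  e <- net$edges
  e$direct_strength <- s[cbind(e$plant, e$microbe)]
  e$deconvolved <- TRUE
  drop <- abs(e$direct_strength) < r_threshold
  removed <- e[drop, , drop = FALSE]
  if (nrow(removed)) removed$pruned_by <- "indirect"
  net$edges <- e[!drop, , drop = FALSE]
  net <- trim_network(net)
  attr(net, "removed") <- rbind(attr(net, "removed"), removed)
  net
}

# abiotic factors plus sample-level grass biophysical covariates: a
# grass-species-microbe link that vanishes once a stand-level covariate
# (e.g. total cover) is controlled is environmental filtering, not a
# species-specific association
default_env_vars <- function(frame)
  intersect(c("pH", "CEC", "OM", "TN", "TP", "TC", "SMC", "MAT", "altitude",
              "CD", "S", "FB", "DB", "H"),
            names(frame))

#' Prune environmentally or geographically driven links (LTED screen)
#'
#' An edge is attributed to environmental filtering when both endpoints
#' correlate significantly (Spearman p < `p_threshold`) with the same
#' environmental variable with the same sign AND the endpoints' partial
#' correlation controlling that variable falls below `r_threshold`. The
#' geographic test is analogous with distance matrices: both endpoints'
#' abundance-difference matrices must Mantel-correlate significantly with
#' geographic distance and the pair's partial Mantel correlation controlling
#' geography must fall below `r_threshold`. Such edges are flagged
#' `lted_pruned`, logged with the triggering variable, and removed.
#'
#' @param net a `bipartite_network`.
#' @param tables named list of [count_table()]s resolving every network node
#'   (the grass table plus the relevant microbial tables).
#' @param frame a [sample_frame()] aligned with the tables.
#' @param geo_dm geographic [dist_matrix()] over the same samples.
#' @param env_vars environmental columns to screen (default: soil variables,
#'   MAT and altitude present in `frame`).
#' @param r_threshold partial-correlation retention cutoff (default 0.3).
#' @param p_threshold significance cutoff for driver correlations (0.05).
#' @param n_perm Mantel permutations for the geographic test (default 99).
#' @param seed integer seed for Mantel permutations.
#' @return The pruned network; pruned edges accumulate in `attr(, "removed")`.
#' @export
lted_prune <- function(net, tables, frame, geo_dm,
                       env_vars = default_env_vars(frame),
                       r_threshold = 0.3, p_threshold = 0.05,
                       n_perm = 99L, seed = 1L) {
  if (!nrow(net$edges)) return(net)
  rel <- lapply(tables, function(t) unclass(t) / rowSums(t))
  nodes <- c(net$plant_nodes, net$microbe_nodes)
  abund <- matrix(NA_real_, nrow(rel[[1L]]), length(nodes),
                  dimnames = list(rownames(rel[[1L]]), nodes))
  for (t in rel) {
    hit <- intersect(colnames(t), nodes)
    abund[, hit] <- t[, hit]
  }
  if (anyNA(abund))
    stop("network node(s) unresolved in tables: ",
         paste(nodes[colSums(is.na(abund)) > 0][1:5], collapse = ", "))
  env_vars <- intersect(env_vars, names(frame))
  env_vars <- env_vars[vapply(env_vars, function(v)
    !anyNA(frame[[v]]) && sd(frame[[v]]) > 0, TRUE)]
  nsamp <- nrow(abund)
  ranks <- apply(abund, 2L, rank)
  # per taxon x variable Spearman rho and p (t approximation, as cor.test)
  env_rho <- env_p <- matrix(NA_real_, length(nodes), length(env_vars),
                             dimnames = list(nodes, env_vars))
  for (v in env_vars) {
    rho <- drop(cor(ranks, rank(frame[[v]])))
    tv <- rho * sqrt((nsamp - 2) / pmax(1 - rho^2, 1e-12))
    env_rho[, v] <- rho
    env_p[, v] <- 2 * pt(-abs(tv), nsamp - 2)
  }
  # per-taxon geographic structure: Mantel of |abundance difference| vs geo
  geo_vec <- upper_vec(unclass(geo_dm))
  ip <- upper_pairs(nsamp)
  diff_vecs <- abs(abund[ip[, 1L], , drop = FALSE] -
                     abund[ip[, 2L], , drop = FALSE])
  perm_idx <- with_seed(derive_seed(seed, "lted_perm"), {
    lapply(seq_len(n_perm), function(k) sample.int(nsamp))
  })
  # permuted geo vectors reused for every taxon (valid: permuting one matrix)
  geo_mat <- unclass(geo_dm)
  geo_perms <- vapply(perm_idx, function(o) {
    geo_mat[o, o][cbind(ip[, 1L], ip[, 2L])]
  }, numeric(nrow(ip)))
  geo_r <- drop(cor(diff_vecs, geo_vec))
  perm_r <- cor(diff_vecs, geo_perms)              # taxa x n_perm
  geo_p <- (rowSums(abs(perm_r) >= abs(geo_r)) + 1) / (n_perm + 1)
  names(geo_r) <- names(geo_p) <- nodes
  e <- net$edges
  prune <- rep(FALSE, nrow(e))
  why <- rep(NA_character_, nrow(e))
  for (k in seq_len(nrow(e))) {
    pt_ <- e$plant[k]; mt <- e$microbe[k]
    for (v in env_vars) {
      if (env_p[pt_, v] < p_threshold && env_p[mt, v] < p_threshold &&
          sign(env_rho[pt_, v]) == sign(env_rho[mt, v])) {
        pr <- partial_spearman(abund[, pt_], abund[, mt], frame[[v]])
        if (is.finite(pr) && abs(pr) < r_threshold) {
          prune[k] <- TRUE; why[k] <- v; break
        }
      }
    }
    if (prune[k]) next
    # dispersal limitation: both endpoints distance-structured and the pair
    # correlation vanishes once geography is partialled out
    if (geo_p[pt_] < p_threshold && geo_p[mt] < p_threshold &&
        sign(geo_r[pt_]) == sign(geo_r[mt])) {
      a <- diff_vecs[, pt_]; b <- diff_vecs[, mt]
      rxz <- cor(a, geo_vec); ryz <- cor(b, geo_vec); rxy <- cor(a, b)
      pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      if (is.finite(pr) && abs(pr) < r_threshold) {
        prune[k] <- TRUE; why[k] <- "geographic_distance"
      }
    }
  }
  removed <- e[prune, , drop = FALSE]
  if (nrow(removed)) {
    removed$lted_pruned <- TRUE
    removed$pruned_by <- why[prune]
  }
  net$edges <- e[!prune, , drop = FALSE]
  net <- trim_network(net)
  attr(net, "removed") <- rbind(attr(net, "removed"), removed)
  net
}

# partial Spearman correlation of x and y controlling z (first-order
# partial of the three pairwise rank correlations; equals the rank-residual
# formulation)
partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (sd(rx) == 0 || sd(ry) == 0 || sd(rz) == 0) return(NA_real_)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 0) return(NA_real_)
  (rxy - rxz * ryz) / sqrt(den)
}

#' Run the full IDEN chain for one microbial domain
#'
#' SparCC correlation, bootstrap significance, threshold filtering,
#' deconvolution, and LTED pruning in the workflow order.
#'
#' @param grass_table grass [count_table()].
#' @param microbe_table microbial [count_table()] (same samples).
#' @param frame aligned [sample_frame()].
#' @param geo_dm geographic [dist_matrix()] (computed from `frame` if NULL).
#' @param r_threshold,p_threshold network thresholds (0.3 / 0.05).
#' @param n_inner,n_boot,boot_inner SparCC iteration counts.
#' @param lted_perm Mantel permutations inside the LTED screen.
#' @param deconv_iter iteration cap for the deconvolution solver (`NULL` =
#'   size-dependent default).
#' @param seed integer seed.
#' @return list: `network` (final), `assoc` (r + p), `stages` (edge counts
#'   after each stage).
#' @export
build_iden <- function(grass_table, microbe_table, frame, geo_dm = NULL,
                       r_threshold = 0.3, p_threshold = 0.05,
                       n_inner = 20L, n_boot = 100L, boot_inner = 5L,
                       lted_perm = 99L, deconv_iter = NULL, seed = 1L) {
  if (is.null(geo_dm)) geo_dm <- geographic_distance_matrix(frame)
  am <- sparcc_correlation(grass_table, microbe_table, n_inner = n_inner,
                           seed = seed)
  am <- bootstrap_pvalues(grass_table, microbe_table, am, n_boot = n_boot,
                          n_inner = boot_inner, seed = seed)
  net <- filter_associations(am, r_threshold, p_threshold)
  n_filtered <- nrow(net$edges)
  net <- deconvolve_network(net, am, r_threshold, max_iter = deconv_iter)
  n_deconv <- nrow(net$edges)
  net <- lted_prune(net, list(grass = grass_table, microbe = microbe_table),
                    frame, geo_dm, r_threshold = r_threshold,
                    p_threshold = p_threshold, n_perm = lted_perm, seed = seed)
  list(network = net, assoc = am,
       stages = c(filtered = n_filtered, deconvolved = n_deconv,
                  final = nrow(net$edges)))
}

#' Union of per-domain bipartite networks
#' @param nets list of `bipartite_network`s sharing the grass node set.
#' @return A combined `bipartite_network`.
#' @export
combine_networks <- function(nets) {
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  doms <- do.call(c, lapply(nets, `[[`, "microbe_domains"))
  net <- new_bipartite_network(
    edges,
    plant_nodes = unique(unlist(lapply(nets, `[[`, "plant_nodes"))),
    microbe_nodes = unique(unlist(lapply(nets, `[[`, "microbe_nodes"))),
    microbe_domains = doms[!duplicated(names(doms))])
  trim_network(net)
}

#' Export a bipartite network as an edge-list TSV
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a bipartite network as GraphML
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("plant", "microbe", "direct_strength")], directed = FALSE,
    vertices = data.frame(
      name = c(net$plant_nodes, net$microbe_nodes),
      type = c(rep(FALSE, length(net$plant_nodes)),
               rep(TRUE, length(net$microbe_nodes)))))
  g
}
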