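#' Bipartite topology, nestedness and stability
#'
#' Topology: connectance L/(m n), degree statistics, and bipartite clustering
#' (Latapy-style pairwise overlap). Nestedness: NODF in [0, 100]. Stability:
#' attack-tolerance curves (fraction of remaining nodes still linked as nodes
#' are removed randomly or by descending degree), robustness as the area
#' under that curve, vulnerability as the largest relative drop in global
#' efficiency caused by deleting one node, and degree-preserving
#' (checkerboard-swap) null ensembles for the robustness contrast.
#'
#' @name network-metrics
NULL

# binary incidence matrix (plants x microbes) from the edge list
incidence_matrix <- function(net) {
  m <- matrix(0L, length(net$plant_nodes), length(net$microbe_nodes),
              dimnames = list(net$plant_nodes, net$microbe_nodes))
  if (nrow(net$edges)) m[cbind(net$edges$plant, net$edges$microbe)] <- 1L
  m
}

network_from_incidence <- function(inc, domain = "bacteria") {
  idx <- which(inc > 0, arr.ind = TRUE)
  edges <- data.frame(
    plant = rownames(inc)[idx[, 1L]], microbe = colnames(inc)[idx[, 2L]],
    domain = rep(domain, nrow(idx)), r = rep(1, nrow(idx)),
    p = rep(0, nrow(idx)), direct_strength = rep(1, nrow(idx)),
    sign = rep(1L, nrow(idx)), filtered_in = rep(TRUE, nrow(idx)),
    deconvolved = rep(FALSE, nrow(idx)), lted_pruned = rep(FALSE, nrow(idx)),
    pruned_by = rep(NA_character_, nrow(idx)), stringsAsFactors = FALSE)
  new_bipartite_network(edges, rownames(inc), colnames(inc),
                        setNames(rep(domain, ncol(inc)), colnames(inc)))
}

#' Topological summary of a bipartite network
#'
#' @param net a `bipartite_network` with at least one edge.
#' @return list: `n_plants`, `n_microbes`, `n_edges`, `connectance`,
#'   `mean_degree`, `avg_clustering` (bipartite pairwise-overlap cc),
#'   `nestedness_nodf`.
#' @export
topology_summary <- function(net) {
  inc <- incidence_matrix(net)
  L <- sum(inc)
  if (!L) stop("empty network")
  m <- nrow(inc); n <- ncol(inc)
  list(n_plants = m, n_microbes = n, n_edges = L,
       connectance = L / (m * n),
       mean_degree = 2 * L / (m + n),
       avg_clustering = bipartite_clustering(inc),
       nestedness_nodf = nodf(net))
}

# Latapy et al. bipartite clustering: for each node, mean Jaccard overlap of
# its neighbourhood with every node of the same side sharing >= 1 neighbour;
# network coefficient = mean over nodes with at least one such pair.
bipartite_clustering <- function(inc) {
  side <- function(a) {
    # a: nodes x neighbours incidence for one side
    deg <- rowSums(a)
    keep <- deg > 0
    a <- a[keep, , drop = FALSE]; deg <- deg[keep]
    if (nrow(a) < 2L) return(NA_real_)
    shared <- a %*% t(a)
    uni <- outer(deg, deg, "+") - shared
    jac <- shared / pmax(uni, 1)
    cc <- vapply(seq_len(nrow(a)), function(i) {
      peers <- which(shared[i, ] > 0)
      peers <- setdiff(peers, i)
      if (!length(peers)) return(NA_real_)
      mean(jac[i, peers])
    }, 0)
    cc
  }
  vals <- c(side(inc), side(t(inc)))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

#' NODF nestedness (0-100)
#'
#' Mean of paired-overlap terms over all row pairs and all column pairs of
#' the binary incidence matrix. For an ordered pair (heavier, lighter) with
#' strictly decreasing degree, the term is the percentage of the lighter
#' node's partners also held by the heavier node; equal-degree pairs
#' contribute 0.
#'
#' @param net a `bipartite_network` (or a binary incidence matrix).
#' @return NODF value in [0, 100].
#' @export
nodf <- function(net) {
  inc <- if (inherits(net, "bipartite_network")) incidence_matrix(net)
         else (as.matrix(net) > 0) + 0L
  nodf_axis <- function(a) {
    deg <- rowSums(a)
    n <- nrow(a)
    if (n < 2L) return(numeric(0))
    overlap <- tcrossprod(a)          # shared partners per node pair
    up <- upper.tri(overlap)
    dmin <- outer(deg, deg, pmin)[up]
    equal <- outer(deg, deg, "==")[up]
    ifelse(equal | dmin == 0, 0, 100 * overlap[up] / dmin)
  }
  terms <- c(nodf_axis(inc), nodf_axis(t(inc)))
  if (!length(terms)) return(0)
  mean(terms)
}

#' Attack-tolerance simulation
#'
#' Removes nodes in steps of `step` (random order, averaged over `n_rep`
#' replicates, or by descending degree) and records the fraction of the
#' remaining nodes that still hold at least one edge. Robustness is the
#' trapezoidal area under this curve over removed fractions [0, 1]; the
#' fraction surviving at 50% removal is reported as a second summary.
#'
#' @param net a `bipartite_network`.
#' @param removal `"random"` or `"degree_descending"`.
#' @param step removed-fraction grid step (default 0.05).
#' @param n_rep random-removal replicates (default 100).
#' @param seed integer seed.
#' @return list: `curve` (data.frame fraction_removed, fraction_linked),
#'   `robustness`, `surviving_at_half`, `removal`.
#' @export
attack_tolerance <- function(net, removal = c("random", "degree_descending"),
                             step = 0.05, n_rep = 100L, seed = 1L) {
  removal <- match.arg(removal)
  inc <- incidence_matrix(net)
  nodes <- c(rownames(inc), colnames(inc))
  nn <- length(nodes)
  m <- nrow(inc)
  fracs <- seq(0, 1, by = step)
  # adjacency lists over the joint node indexing (plants 1..m, then microbes)
  eidx <- which(inc > 0, arr.ind = TRUE)
  adj <- vector("list", nn)
  for (u in seq_len(nn)) adj[[u]] <- integer(0)
  for (r in seq_len(nrow(eidx))) {
    a <- eidx[r, 1L]; b <- m + eidx[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg0 <- lengths(adj)
  checkpoints <- floor(fracs * nn)
  linked_after <- function(order_idx) {
    # incremental removal: maintain degrees and the count of remaining
    # nodes that still hold an edge; O(E) per replicate
    deg <- deg0
    alive <- rep(TRUE, nn)
    linked <- sum(deg > 0)
    out <- numeric(length(fracs))
    ci <- 1L
    for (step_k in 0:nn) {
      while (ci <= length(fracs) && checkpoints[ci] == step_k) {
        rem <- nn - step_k
        out[ci] <- if (rem == 0L) 0 else linked / rem
        ci <- ci + 1L
      }
      if (step_k == nn) break
      u <- order_idx[step_k + 1L]
      alive[u] <- FALSE
      if (deg[u] > 0) linked <- linked - 1L
      for (w in adj[[u]]) if (alive[w] && deg[w] > 0) {
        deg[w] <- deg[w] - 1L
        if (deg[w] == 0L) linked <- linked - 1L
      }
      deg[u] <- 0L
    }
    out
  }
  curve <- if (removal == "degree_descending") {
    deg <- c(rowSums(inc), colSums(inc))
    linked_after(order(-deg))
  } else {
    with_seed(derive_seed(seed, "attack"), {
      rowMeans(vapply(seq_len(n_rep),
                      function(r) linked_after(sample.int(nn)),
                      numeric(length(fracs))))
    })
  }
  rob <- sum(diff(fracs) * (head(curve, -1) + curve[-1]) / 2)
  list(curve = data.frame(fraction_removed = fracs, fraction_linked = curve),
       robustness = rob,
       surviving_at_half = curve[which.min(abs(fracs - 0.5))],
       removal = removal)
}

#' Network vulnerability via global efficiency
#'
#' Global efficiency E is the mean over unordered node pairs of the inverse
#' shortest-path length (0 for disconnected pairs); vulnerability is
#' max_i (E - E_i) / E where E_i is the efficiency after deleting node i.
#' Edges are treated as unweighted.
#'
#' @param net a `bipartite_network`.
#' @param max_candidates exact deletion is tried for every node up to this
#'   network size; above it only the `max_candidates` highest-degree nodes
#'   are deleted (the efficiency-maximising node is a hub in practice).
#' @return vulnerability in [0, 1] (0 for single-node networks).
#' @export
vulnerability <- function(net, max_candidates = 100L) {
  if (length(net$plant_nodes) + length(net$microbe_nodes) <= 1L) return(0)
  g <- as_igraph(net)
  nv <- igraph::vcount(g)
  if (nv <= 1L) return(0)
  eff <- function(gr) {
    n <- igraph::vcount(gr)
    if (n <= 1L) return(0)
    d <- igraph::distances(gr)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }
  e0 <- eff(g)
  if (e0 == 0) return(0)
  cand <- if (nv <= max_candidates) seq_len(nv) else
    order(igraph::degree(g), decreasing = TRUE)[seq_len(max_candidates)]
  drops <- vapply(cand, function(i)
    (e0 - eff(igraph::delete_vertices(g, i))) / e0, 0)
  max(drops)
}

# degree-preserving rewiring by checkerboard swaps: pick two edges (a, b),
# (c, d) with a != c, b != d and (a, d), (c, b) absent; swap. n_try defaults
# to 10x the edge count.
checkerboard_rewire <- function(inc, n_try = 10L * sum(inc), seed = 1L) {
  with_seed(seed, {
    a <- inc
    edges <- which(a == 1L, arr.ind = TRUE)
    n_swapped <- 0L
    for (t in seq_len(n_try)) {
      pick <- sample.int(nrow(edges), 2L)
      e1 <- edges[pick[1L], ]; e2 <- edges[pick[2L], ]
      if (e1[1L] != e2[1L] && e1[2L] != e2[2L] &&
          a[e1[1L], e2[2L]] == 0L && a[e2[1L], e1[2L]] == 0L) {
        a[e1[1L], e1[2L]] <- 0L; a[e2[1L], e2[2L]] <- 0L
        a[e1[1L], e2[2L]] <- 1L; a[e2[1L], e1[2L]] <- 1L
        edges[pick[1L], ] <- c(e1[1L], e2[2L])
        edges[pick[2L], ] <- c(e2[1L], e1[2L])
        n_swapped <- n_swapped + 1L
      }
    }
    list(incidence = a, n_swapped = n_swapped)
  })
}

#' Degree-preserving null ensemble for robustness
#'
#' Rewires the bipartite incidence by checkerboard swaps (two edges (a, b),
#' (c, d) with (a, d), (c, b) absent become (a, d), (c, b)), preserving every
#' node's degree exactly; `10 * n_edges` swap attempts per null. Robustness
#' of each null is compared with the empirical value.
#'
#' @param net a `bipartite_network` with >= 2 edges.
#' @param n_null ensemble size (default 100).
#' @param n_rep,step attack-tolerance settings passed through.
#' @param seed integer seed.
#' @return list: `empirical`, `null_distribution`, `p_greater`, `p_less`,
#'   `p_two_sided`, `degenerate` (TRUE when no swap was ever possible).
#' @export
null_model_ensemble <- function(net, n_null = 100L, n_rep = 50L, step = 0.05,
                                seed = 1L) {
  if (n_null < 1L) stop("n_null must be >= 1")
  inc <- incidence_matrix(net)
  if (sum(inc) < 2L) stop("need at least 2 edges")
  emp <- attack_tolerance(net, "random", step = step, n_rep = n_rep,
                          seed = derive_seed(seed, "emp"))$robustness
  nulls <- numeric(n_null)
  swapped_any <- FALSE
  for (b in seq_len(n_null)) {
    rw <- checkerboard_rewire(inc, seed = derive_seed(seed, paste0("null", b)))
    if (rw$n_swapped > 0L) swapped_any <- TRUE
    nulls[b] <- attack_tolerance(network_from_incidence(rw$incidence),
                                 "random", step = step, n_rep = n_rep,
                                 seed = derive_seed(seed, paste0("nullrob", b)))$robustness
  }
  p_ge <- (sum(nulls >= emp) + 1) / (n_null + 1)
  p_le <- (sum(nulls <= emp) + 1) / (n_null + 1)
  list(empirical = emp, null_distribution = nulls,
       p_greater = p_ge, p_less = p_le,
       p_two_sided = min(1, 2 * min(p_ge, p_le)),
       degenerate = !swapped_any)
}
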