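test_that("association filter applies both thresholds as documented", {
  r <- matrix(c(0.35, 0.29, 0.35, -0.5), 2, 2)
  p <- matrix(c(0.01, 0.001, 0.20, 0.04), 2, 2)
  net <- filter_associations(toy_assoc(r, p))
  kept <- paste(net$edges$plant, net$edges$microbe)
  expect_setequal(kept, c("g1 m1", "g2 m2"))   # r=0.29 and p=0.20 removed
  expect_identical(net$edges$sign[net$edges$plant == "g2"], -1L)
  # nodes without retained edges are excluded
  expect_setequal(net$plant_nodes, c("g1", "g2"))
  expect_setequal(net$microbe_nodes, c("m1", "m2"))
})

test_that("deconvolution leaves two-node networks alone and resolves chains", {
  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(idirect_deconvolve(two)$s[1, 2], 0.5, tolerance = 1e-6)
  chain <- matrix(c(0, .8, .64, .8, 0, .8, .64, .8, 0), 3, 3)
  d <- idirect_deconvolve(chain)
  expect_true(d$converged)
  expect_lt(abs(d$s[1, 3]), 0.3)          # induced link drops below filter
  expect_equal(d$s[1, 2], 0.8, tolerance = 0.05)
})

test_that("deconvolution solution satisfies its own fixed-point equation", {
  # independent oracle: plug the solution back into the stated operator
  # algebra and check the observed totals are reproduced
  residual <- function(g, s) {
    D <- nrow(g); upd <- matrix(0, D, D)
    clip <- function(x) pmin(pmax(x, -0.99), 0.99)
    for (i in 1:D) for (j in 1:D) {
      if (i == j || g[i, j] == 0) next
      acc <- 0
      for (k in 1:D) {
        if (k == i || k == j || s[i, k] == 0) next
        g_eff <- tanh(atanh(clip(g[k, j])) - atanh(clip(s[i, k] * s[i, j])))
        acc <- acc + atanh(clip(s[i, k] * g_eff))
      }
      v <- tanh(acc)
      ag <- atanh(clip(g[i, j])); av <- atanh(clip(v))
      if (sign(ag) * sign(av) > 0) av <- sign(ag) * min(abs(av), abs(ag))
      upd[i, j] <- tanh(ag - av)
    }
    # the solver symmetrizes each candidate, so the fixed point satisfies
    # the symmetrized equation
    upd <- (upd + t(upd)) / 2
    max(abs(upd[g != 0] - s[g != 0]))
  }
  set.seed(41)
  for (k in 1:5) {
    D <- 12
    g <- matrix(0, D, D)
    pick <- sample(which(upper.tri(g)), 18)
    g[pick] <- runif(18, -0.75, 0.75)
    g <- g + t(g)
    d <- suppressWarnings(idirect_deconvolve(g))
    if (d$converged) expect_lt(residual(g, d$s), 0.02)
  }
})

test_that("R and C++ deconvolution engines agree exactly", {
  set.seed(42)
  for (k in 1:4) {
    D <- 15
    g <- matrix(0, D, D)
    pick <- sample(which(upper.tri(g)), 25)
    g[pick] <- runif(25, -0.8, 0.8)
    g <- g + t(g)
    a <- suppressWarnings(idirect_deconvolve(g, engine = "cpp"))
    b <- suppressWarnings(idirect_deconvolve(g, engine = "r"))
    expect_equal(a$s, b$s, tolerance = 1e-12)
    expect_identical(a$iterations, b$iterations)
  }
})

test_that("star hubs survive deconvolution while induced leaf links attenuate", {
  D <- 6
  g <- matrix(0, D, D)
  g[1, 2:D] <- g[2:D, 1] <- 0.7
  for (a in 2:D) for (b in 2:D) if (a != b) g[a, b] <- 0.49
  d <- idirect_deconvolve(g)
  expect_lt(abs(d$s[2, 3]), 0.3)
  expect_gt(d$s[1, 2], 2 * abs(d$s[2, 3]))
})

test_that("LTED prunes environmentally driven links, keeps direct ones", {
  set.seed(43)
  n <- 40
  frame <- sample_frame(data.frame(
    sample_id = sprintf("s%02d", 1:n), latitude = seq(30, 36, length.out = n),
    longitude = seq(92, 100, length.out = n),
    pH = seq(6.5, 8.5, length.out = n) + rnorm(n, 0, 0.05)))
  # g1/m1 both track pH; g2/m2 share a private (non-environmental) driver
  shared <- rnorm(n, 0, 1.5)
  lat <- exp(cbind(g1 = scale(frame$pH)[, 1] + rnorm(n, 0, 0.5),
                   g2 = shared + rnorm(n, 0, 0.3),
                   f1 = rnorm(n), f2 = rnorm(n)))
  grass <- count_table(round(lat / rowSums(lat) * 2e4) + 1L, "grass",
                       samples = frame$sample_id)
  latm <- exp(cbind(m1 = scale(frame$pH)[, 1] + rnorm(n, 0, 0.5),
                    m2 = shared + rnorm(n, 0, 0.3),
                    m3 = rnorm(n), m4 = rnorm(n)))
  microbe <- count_table(round(latm / rowSums(latm) * 2e4) + 1L, "bacteria",
                         samples = frame$sample_id)
  edges <- data.frame(plant = c("g1", "g2"), microbe = c("m1", "m2"),
                      domain = "bacteria", r = 0.6, p = 0.001,
                      direct_strength = 0.6, sign = 1L, filtered_in = TRUE,
                      deconvolved = TRUE, lted_pruned = FALSE,
                      pruned_by = NA_character_)
  net <- graminet:::new_bipartite_network(
    edges, c("g1", "g2"), c("m1", "m2"),
    setNames(c("bacteria", "bacteria"), c("m1", "m2")))
  geo <- geographic_distance_matrix(frame)
  pruned <- lted_prune(net, list(grass = grass, microbe = microbe), frame,
                       geo, env_vars = "pH", n_perm = 99, seed = 1)
  kept <- paste(pruned$edges$plant, pruned$edges$microbe)
  expect_true("g2 m2" %in% kept)
  expect_false("g1 m1" %in% kept)
  expect_identical(attr(pruned, "removed")$pruned_by, "pH")
  # empty network passes through untouched
  empty <- graminet:::new_bipartite_network(edges[0, ], character(0),
                                            character(0), character(0))
  expect_identical(nrow(lted_prune(empty, list(grass = grass), frame,
                                   geo)$edges), 0L)
})

test_that("edge lists and GraphML export round-trip node and edge counts", {
  inc <- matrix(c(1, 1, 0, 1), 2, 2,
                dimnames = list(c("p1", "p2"), c("m1", "m2")))
  net <- net_from_inc(inc)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 3L)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gg), 4L)
  expect_equal(igraph::ecount(gg), 3L)
})
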