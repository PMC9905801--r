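rand_dm <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n)
  rownames(pts) <- paste0("s", 1:n)
  dist_matrix(as.matrix(dist(pts)), "euclidean")
}

test_that("mantel statistic is exact on self-comparison and NA on constants", {
  dm <- rand_dm(10, 61)
  res <- mantel_test(dm, dm, n_perm = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 100, tolerance = 1e-12)
  const <- dist_matrix(matrix(1, 10, 10) - diag(10), "const",
                       labels = rownames(dm))
  expect_true(is.na(mantel_test(dm, const)$r))
})

test_that("mantel permutation p matches exhaustive enumeration at n = 5", {
  dm_a <- rand_dm(5, 62)
  dm_b <- rand_dm(5, 63)
  a <- graminet:::upper_vec(unclass(dm_a))
  bmat <- unclass(dm_b)
  r_obs <- cor(a, graminet:::upper_vec(bmat))
  perms <- gtools_permutations(5)
  rs <- apply(perms, 1, function(o)
    cor(a, graminet:::upper_vec(bmat[o, o])))
  p_exact <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  res <- mantel_test(dm_a, dm_b, n_perm = 9999, seed = 2)
  expect_lt(abs(res$p - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2e-3)
})

test_that("partial mantel removes a perfect confound and degrades gracefully", {
  dm_a <- rand_dm(12, 64)
  ctrl <- rand_dm(12, 65)
  # near-copy of the control (exact equality makes the partial r 0/0)
  set.seed(70)
  jit <- unclass(ctrl) + as.matrix(dist(rnorm(12, 0, 1e-4)))
  diag(jit) <- 0
  near <- dist_matrix(jit, "near", labels = rownames(ctrl))
  res <- partial_mantel_test(dm_a, near, ctrl, n_perm = 99, seed = 1)
  expect_lt(abs(res$r), 0.05)
  # constant control reduces to the plain Mantel r
  const <- dist_matrix(matrix(1, 12, 12) - diag(12), "const",
                       labels = rownames(dm_a))
  pm <- partial_mantel_test(dm_a, ctrl, const, n_perm = 99, seed = 1)
  expect_true(pm$degenerate_control)
  expect_equal(pm$r, mantel_test(dm_a, ctrl, n_perm = 9)$r, tolerance = 1e-12)
  # swapping a and b keeps r; swapping b and control changes it
  dm_b <- rand_dm(12, 66); dm_c <- rand_dm(12, 67)
  r1 <- partial_mantel_test(dm_a, dm_b, dm_c, n_perm = 9)$r
  r2 <- partial_mantel_test(dm_b, dm_a, dm_c, n_perm = 9)$r
  r3 <- partial_mantel_test(dm_a, dm_c, dm_b, n_perm = 9)$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1, r3, tolerance = 1e-6)))
})

test_that("connectivity profile matches hand computation and compositional invariance", {
  # 2 samples, 3 taxa, 2 edges: g1-m1, g1-m2 -> deg(g1)=2, deg(m1)=deg(m2)=1
  inc <- matrix(1, 1, 2, dimnames = list("g1", c("m1", "m2")))
  net <- net_from_inc(inc)
  grass <- count_table(matrix(c(10L, 10L,
                                5L, 15L), 2, 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"), c("g1", "g2"))),
                       "grass")
  microbe <- count_table(matrix(c(4L, 4L, 2L,
                                  2L, 6L, 2L), 2, 3, byrow = TRUE,
                                dimnames = list(c("s1", "s2"),
                                                c("m1", "m2", "m3"))),
                         "bacteria")
  prof <- sample_connectivity_profile(net, list(grass, microbe))
  s1 <- 2 * 10 / 20 + 1 * 4 / 10 + 1 * 4 / 10
  s2 <- 2 * 5 / 20 + 1 * 2 / 10 + 1 * 6 / 10
  expect_equal(unname(prof$scores), c(s1, s2), tolerance = 1e-12)
  expect_equal(prof$dm["s1", "s2"], abs(s1 - s2), tolerance = 1e-12)
  # doubling all counts changes nothing (relative abundances)
  prof2 <- sample_connectivity_profile(
    net, list(count_table(unclass(grass) * 2L, "grass"),
              count_table(unclass(microbe) * 2L, "bacteria")))
  expect_equal(prof2$scores, prof$scores, tolerance = 1e-12)
  # identical composition everywhere -> all-zero distance matrix
  same <- count_table(matrix(rep(c(3L, 7L), each = 2), 2, 2,
                             dimnames = list(c("s1", "s2"), c("g1", "g2"))),
                      "grass")
  samem <- count_table(matrix(rep(c(5L, 5L, 5L), each = 2), 2, 3,
                              dimnames = list(c("s1", "s2"),
                                              c("m1", "m2", "m3"))),
                       "bacteria")
  prof3 <- sample_connectivity_profile(net, list(same, samem))
  expect_true(all(unclass(prof3$dm) == 0))
})

test_that("connectivity screen returns a Table-2-shaped frame", {
  set.seed(68)
  n <- 16
  frame <- sample_frame(data.frame(
    sample_id = sprintf("s%02d", 1:n), latitude = runif(n, 30, 36),
    longitude = runif(n, 92, 100), CD = runif(n, 40, 100),
    DB = runif(n, 50, 250), pH = runif(n, 6.5, 8.5)))
  conn <- rand_dm(n, 69)
  attr(conn, "metric") <- "connectivity"
  dimnames(conn) <- list(frame$sample_id, frame$sample_id)
  res <- connectivity_mantel_screen(
    conn, frame, variables = list(productivity = c("CD", "DB"), soil = "pH"),
    geo_dm = geographic_distance_matrix(frame), n_perm = 49, seed = 1)
  expect_setequal(res$variable, c("CD", "DB", "pH"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(abs(res$r) <= 1))
})
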