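test_that("alpha diversity indices match closed forms", {
  ct <- count_table(matrix(c(25L, 25L, 25L, 25L,
                             100L, 0L, 0L, 0L,
                             96L, 1L, 1L, 2L), 3, 4, byrow = TRUE,
                           dimnames = list(c("even", "mono", "skew"),
                                           paste0("t", 1:4))), "bacteria")
  a <- alpha_diversity(ct)
  expect_equal(a["even", "shannon"], log(4), tolerance = 1e-12)
  expect_equal(a["even", "pielou"], 1, tolerance = 1e-12)
  expect_equal(a["mono", "shannon"], 0)
  expect_equal(a["mono", "margalef"], 0)
  expect_true(is.na(a["mono", "pielou"]))  # undefined for S = 1, not 0
  expect_equal(a["even", "richness"], 4)
  # margalef (S - 1)/log N with S = 5, N = 100
  ct5 <- count_table(matrix(c(96L, 1L, 1L, 1L, 1L), 1, 5,
                            dimnames = list("s", paste0("t", 1:5))), "fungi")
  expect_equal(alpha_diversity(ct5)$margalef, 4 / log(100), tolerance = 1e-12)
})

test_that("rarefaction subsamples to depth, drops shallow samples, keeps taxa subset", {
  ct <- count_table(matrix(c(6000L, 3000L, 1000L,
                             500L, 300L, 200L,
                             4000L, 0L, 1000L), 3, 3, byrow = TRUE,
                           dimnames = list(c("deep1", "shallow", "deep2"),
                                           c("t1", "t2", "t3"))), "fungi")
  rr <- rarefy_table(ct, 5000, seed = 42)
  expect_identical(rr$dropped, "shallow")
  expect_true(all(rowSums(rr$table) == 5000))
  # no taxon appears that was absent before
  expect_true(all(rr$table[, "t2"][rownames(rr$table) == "deep2"] == 0))
  # sample exactly at depth is returned unchanged
  ct2 <- count_table(matrix(c(3L, 2L), 1, 2,
                            dimnames = list("s", c("a", "b"))), "fungi")
  expect_identical(unclass(rarefy_table(ct2, 5, seed = 1)$table)[1, ],
                   c(a = 3L, b = 5L - 3L))
  # same seed -> identical draw
  expect_identical(unclass(rarefy_table(ct, 5000, seed = 7)$table),
                   unclass(rarefy_table(ct, 5000, seed = 7)$table))
})

test_that("rarefaction draws have the hypergeometric expectation", {
  ct <- count_table(matrix(c(700L, 300L), 1, 2,
                           dimnames = list("s", c("a", "b"))), "bacteria")
  draws <- vapply(1:200, function(k)
    unclass(rarefy_table(ct, 100, seed = k)$table)[1, 1], 0L)
  # mean ~ depth * 0.7, sampling without replacement
  expect_equal(mean(draws), 70, tolerance = 0.05 * 70)
})

test_that("Bray-Curtis matches hand values and vegan", {
  m <- matrix(c(2, 2,
                1, 3,
                0, 4), 3, 2, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("t1", "t2")))
  bc <- bray_curtis_matrix(count_table(m, "grass"))
  expect_equal(bc["x", "y"], 0.25, tolerance = 1e-12)
  expect_equal(bc["x", "x"], 0)
  # disjoint samples -> 1
  md <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("a", "b"), c("t", "u")))
  expect_equal(bray_curtis_matrix(count_table(md, "grass"))["a", "b"], 1)
  skip_if_not_installed("vegan")
  set.seed(5)
  r <- matrix(rpois(60, 20), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  expect_equal(unclass(bray_curtis_matrix(count_table(r, "fungi"))),
               as.matrix(vegan::vegdist(r, "bray")), tolerance = 1e-10,
               ignore_attr = TRUE)
  # zero-sum sample is an error
  expect_error(bray_curtis_matrix(rbind(r[1:2, ], zero = 0)), "zero-sum")
})

test_that("shannon is taxon-order invariant and BC is label-permutation invariant", {
  set.seed(9)
  m <- matrix(rpois(40, 15) + 1L, 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  ct <- count_table(m, "bacteria")
  perm <- sample(ncol(m))
  a1 <- alpha_diversity(ct)
  a2 <- alpha_diversity(count_table(m[, perm], "bacteria"))
  expect_equal(a1$shannon, a2$shannon, tolerance = 1e-12)
  o <- sample(nrow(m))
  b1 <- unclass(bray_curtis_matrix(ct))[o, o]
  b2 <- unclass(bray_curtis_matrix(count_table(m[o, ], "bacteria")))
  expect_equal(b1, b2, tolerance = 1e-12, ignore_attr = TRUE)
})
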