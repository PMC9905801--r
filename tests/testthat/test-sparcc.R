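# exact 3-component basis-variance solve from the log-ratio variance matrix:
# w1 = (t12 + t13 - t23)/2 etc., then rho from the SparCC identity
sparcc3_oracle <- function(frac) {
  lf <- log(frac)
  tv <- function(i, j) var(lf[, i] - lf[, j])
  t12 <- tv(1, 2); t13 <- tv(1, 3); t23 <- tv(2, 3)
  w <- c((t12 + t13 - t23) / 2, (t12 + t23 - t13) / 2, (t13 + t23 - t12) / 2)
  r <- function(i, j, tij) (w[i] + w[j] - tij) / (2 * sqrt(w[i] * w[j]))
  c(r(1, 2, t12), r(1, 3, t13), r(2, 3, t23))
}

test_that("single-pass SparCC equals the exact 3-component solve", {
  set.seed(31)
  counts <- matrix(rpois(30 * 3, 50) + 1L, 30, 3,
                   dimnames = list(paste0("s", 1:30), c("g1", "m1", "m2")))
  g <- count_table(counts[, 1, drop = FALSE], "grass")
  m <- count_table(counts[, 2:3], "bacteria")
  am <- sparcc_correlation(g, m, resample = FALSE, pseudocount = 0,
                           exclusion_threshold = 1)  # no exclusions
  frac <- counts / rowSums(counts)
  oracle <- sparcc3_oracle(frac)
  expect_equal(am$r_full["g1", "m1"], oracle[1], tolerance = 1e-10)
  expect_equal(am$r_full["g1", "m2"], oracle[2], tolerance = 1e-10)
  expect_equal(am$r_full["m1", "m2"], oracle[3], tolerance = 1e-10)
})

test_that("perfectly dependent components approach correlation 1", {
  set.seed(32)
  base <- exp(rnorm(40, 3, 1.5))
  lat <- cbind(a = base, b = base * 2, c = exp(rnorm(40, 3, 1.5)),
               d = exp(rnorm(40, 3, 1.5)))
  counts <- round(lat / rowSums(lat) * 1e6)
  rownames(counts) <- paste0("s", 1:40)
  g <- count_table(counts[, 1, drop = FALSE], "grass")
  m <- count_table(counts[, 2:4], "bacteria")
  am <- sparcc_correlation(g, m, resample = FALSE, pseudocount = 0)
  expect_gt(am$r["a", "b"], 0.95)
})

test_that("SparCC is invariant to per-sample scaling (compositionality)", {
  set.seed(33)
  counts <- matrix(rpois(20 * 5, 40) + 1L, 20, 5,
                   dimnames = list(paste0("s", 1:20), paste0("t", 1:5)))
  g <- count_table(counts[, 1:2], "grass")
  m <- count_table(counts[, 3:5], "fungi")
  r1 <- sparcc_correlation(g, m, resample = FALSE, pseudocount = 0)$r
  scaled <- counts
  scaled[3, ] <- scaled[3, ] * 7L
  scaled[11, ] <- scaled[11, ] * 3L
  r2 <- sparcc_correlation(count_table(scaled[, 1:2], "grass"),
                           count_table(scaled[, 3:5], "fungi"),
                           resample = FALSE, pseudocount = 0)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("independent components rarely exceed the 0.3 filter magnitude", {
  set.seed(34)
  n <- 50
  lat <- exp(matrix(rnorm(n * 23, 0, 1), n, 23))
  counts <- t(apply(lat, 1, function(x) rmultinom(1, 3e4, x / sum(x))))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("t", 1:23))
  g <- count_table(counts[, 1:8], "grass")
  m <- count_table(counts[, 9:23], "archaea")
  am <- sparcc_correlation(g, m, n_inner = 10, seed = 1)
  expect_gte(mean(abs(am$r) < 0.3), 0.95)
})

test_that("bootstrap p-values detect a planted association at the floor", {
  set.seed(35)
  n <- 50
  shared <- rnorm(n, 0, 2)
  lat <- exp(cbind(g1 = shared, g2 = rnorm(n), m1 = shared + rnorm(n, 0, 0.05),
                   m2 = rnorm(n), m3 = rnorm(n)))
  counts <- round(lat / rowSums(lat) * 5e4) + 1L
  rownames(counts) <- paste0("s", 1:n)
  g <- count_table(counts[, 1:2], "grass")
  m <- count_table(counts[, 3:5], "bacteria")
  am <- sparcc_correlation(g, m, n_inner = 5, seed = 1)
  am <- bootstrap_pvalues(g, m, am, n_boot = 50, n_inner = 2, seed = 1)
  expect_equal(am$p["g1", "m1"], 1 / 51, tolerance = 1e-12)
  expect_gt(am$r["g1", "m1"], 0.5)
  expect_warning(bootstrap_pvalues(g, m, am, n_boot = 10, n_inner = 1, seed = 1),
                 "resolution")
})

test_that("same seed reproduces SparCC exactly", {
  set.seed(36)
  counts <- matrix(rpois(60, 30) + 1L, 12, 5,
                   dimnames = list(paste0("s", 1:12), paste0("t", 1:5)))
  g <- count_table(counts[, 1:2], "grass")
  m <- count_table(counts[, 3:5], "fungi")
  a1 <- sparcc_correlation(g, m, n_inner = 5, seed = 9)$r
  a2 <- sparcc_correlation(g, m, n_inner = 5, seed = 9)$r
  expect_identical(a1, a2)
})
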