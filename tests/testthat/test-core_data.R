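test_that("count tables round-trip through TSV in both orientations", {
  ct <- toy_table("archaea")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f1)
  back <- read_count_table(f1, "archaea")
  expect_identical(unclass(back), unclass(ct))
  expect_identical(attr(back, "domain"), "archaea")
  # taxa-rows orientation normalizes to samples x taxa
  f2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(taxon = colnames(ct), t(unclass(ct)), check.names = FALSE)
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_count_table(f2, "archaea", orientation = "taxa_rows")
  expect_identical(unclass(back2), unclass(ct))
  # a second write -> read round-trips bit-identically
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(back2, f3)
  expect_identical(readLines(f1), readLines(f3))
})

test_that("count table validation rejects bad input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(count_table(m, "fungi"), "duplicate sample")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_table(m2, "fungi"), "non-negative")
  expect_error(count_table(matrix(0, 1, 1, dimnames = list("a", "x")),
                           "fungi"), "positive total")
})

test_that("sample frames validate ranges and schema", {
  df <- data.frame(sample_id = "s1", latitude = 34, longitude = 99, CD = 105)
  expect_error(sample_frame(df), "CD")
  expect_error(sample_frame(data.frame(sample_id = "s1", latitude = 99.5,
                                       longitude = 0)), "latitude")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tlatitude", f)  # missing longitude, no rows
  expect_error(read_sample_frame(f))
  # column names match case-insensitively
  df2 <- data.frame(Sample_ID = "s1", LATITUDE = 34, Longitude = 99, ph = 7)
  sf <- sample_frame(df2)
  expect_true(all(c("sample_id", "latitude", "longitude", "pH") %in% names(sf)))
})

test_that("generated landscape frame has the study shape and round-trips", {
  frame <- generate_landscape(generator_config(seed = 11))
  expect_equal(nrow(frame), 48L)
  expect_setequal(unique(frame$grassland_type), c("ASM", "AM", "AS", "TS"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_frame(frame, f)
  back <- read_sample_frame(f)
  expect_equal(back$pH, frame$pH, tolerance = 1e-12)
  expect_identical(back$sample_id, frame$sample_id)
})

test_that("align_bundle intersects, sorts, reports drops, and is idempotent", {
  t1 <- count_table(matrix(1:6, 3, 2, dimnames = list(c("C", "A", "B"),
                                                      c("x", "y"))), "grass")
  t2 <- count_table(matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"),
                                                      c("u", "v"))), "fungi")
  frame <- sample_frame(data.frame(sample_id = c("A", "B", "C", "D"),
                                   latitude = 30:33, longitude = 90:93))
  b <- align_bundle(list(g = t1, f = t2), frame)
  expect_identical(rownames(b$tables$g), c("B", "C"))
  expect_identical(rownames(b$tables$f), c("B", "C"))
  expect_identical(b$frame$sample_id, c("B", "C"))
  expect_identical(b$dropped$g, "A")
  b2 <- align_bundle(b$tables, b$frame)
  expect_identical(b2$tables, b$tables)
  expect_identical(b2$frame$sample_id, b$frame$sample_id)
  t3 <- count_table(matrix(1:2, 1, 2, dimnames = list("Z", c("x", "y"))),
                    "grass")
  expect_error(align_bundle(list(t1, t3), frame), "alignment")
})

test_that("dist_matrix enforces symmetry, zero diagonal, non-negativity", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(dist_matrix(m, "test"), "dist_matrix")
  m2 <- m; m2[1, 2] <- 2
  expect_error(dist_matrix(m2, "test"), "symmetric")
  m3 <- m; diag(m3) <- 1
  expect_error(dist_matrix(m3, "test"), "diagonal")
  expect_error(dist_matrix(-m, "test"), "non-negative")
})
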