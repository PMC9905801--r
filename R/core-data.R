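#' Count tables, sample metadata and distance matrices
#'
#' A `count_table` is a non-negative integer matrix of samples (rows) by taxa
#' (columns) carrying a `domain` tag (`archaea`, `bacteria`, `fungi` or
#' `grass`). A `sample_frame` is a validated per-sample metadata data.frame
#' (coordinates, soil chemistry, grass biophysical variables, grassland type).
#' A `dist_matrix` is a labelled symmetric zero-diagonal matrix with a named
#' metric. These three containers are shared by every downstream stage.
#'
#' @name core-data
NULL

DOMAINS <- c("archaea", "bacteria", "fungi", "grass")
GRASSLAND_TYPES <- c("ASM", "AM", "AS", "TS")

#' Construct and validate a count table
#'
#' @param counts numeric matrix, samples x taxa, non-negative integers.
#' @param domain one of `"archaea"`, `"bacteria"`, `"fungi"`, `"grass"`.
#' @param samples,taxa optional identifier vectors; default to dimnames.
#' @return A validated `count_table` (matrix with class and `domain` attribute).
#' @export
count_table <- function(counts, domain, samples = rownames(counts),
                        taxa = colnames(counts)) {
  domain <- match.arg(domain, DOMAINS)
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(counts)))
  dimnames(counts) <- list(as.character(samples), as.character(taxa))
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count_table needs at least 1 sample and 1 taxon")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon identifiers in count table")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (any(rowSums(counts) <= 0))
    stop("all samples must have positive total counts")
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  structure(counts, domain = domain, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d samples x %d taxa, total %s reads\n",
              attr(x, "domain"), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

ct_domain <- function(x) attr(x, "domain")

# keep class/domain when subsetting by sample or taxon
#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, domain = attr(x, "domain"),
            class = c("count_table", "matrix", "array"))
}

#' Read a tab-separated count table
#'
#' One header row, one label column. `orientation = "taxa_rows"` files are
#' transposed so the result is always samples x taxa.
#'
#' @param path file path of a TSV table.
#' @param domain domain tag for the table.
#' @param orientation `"samples_rows"` (default) or `"taxa_rows"`.
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, domain,
                             orientation = c("samples_rows", "taxa_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count table needs a label column plus data")
  labels <- as.character(raw[[1L]])
  if (anyDuplicated(labels))
    stop("duplicate labels in first column of ", path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count table ", path)
  rownames(m) <- labels
  if (orientation == "taxa_rows") m <- t(m)
  count_table(m, domain = domain)
}

#' Write a count table as TSV (samples x taxa)
#' @param x a [count_table()].
#' @param path output file path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SF_REQUIRED <- c("sample_id", "latitude", "longitude")
SF_NUMERIC <- c("latitude", "longitude", "altitude", "MAT", "pH", "CEC", "OM",
                "TN", "TP", "TC", "SMC", "H", "CD", "S", "FB", "DB")

#' Construct and validate a sample metadata frame
#'
#' Required columns: `sample_id`, `latitude`, `longitude`. Recognised optional
#' columns: `site_id`, `grassland_type` (ASM/AM/AS/TS), `altitude`, `MAT`,
#' soil variables `pH`, `CEC`, `OM`, `TN`, `TP`, `TC`, `SMC`, and grass
#' variables `H`, `CD`, `S`, `FB`, `DB`. Missing optional columns stay absent.
#'
#' @param df a data.frame of per-sample metadata.
#' @return A validated `sample_frame` data.frame keyed by `sample_id`.
#' @export
sample_frame <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("sample frame is empty")
  names(df) <- canonical_sf_names(names(df))
  miss <- setdiff(SF_REQUIRED, names(df))
  if (length(miss))
    stop("sample frame missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample frame")
  for (v in intersect(SF_NUMERIC, names(df))) df[[v]] <- as.numeric(df[[v]])
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  if ("CD" %in% names(df) && any(df$CD < 0 | df$CD > 100, na.rm = TRUE))
    stop("CD (cover, %) out of [0, 100]")
  if ("SMC" %in% names(df) && any(df$SMC < 0 | df$SMC > 100, na.rm = TRUE))
    stop("SMC (moisture, %) out of [0, 100]")
  if ("S" %in% names(df) &&
      any(df$S < 0 | abs(df$S - round(df$S)) > 1e-8, na.rm = TRUE))
    stop("S (species count) must be a non-negative integer")
  if ("grassland_type" %in% names(df)) {
    df$grassland_type <- as.character(df$grassland_type)
    bad <- setdiff(unique(df$grassland_type), GRASSLAND_TYPES)
    if (length(bad)) stop("unknown grassland type(s): ", paste(bad, collapse = ", "))
  }
  rownames(df) <- df$sample_id
  class(df) <- c("sample_frame", "data.frame")
  df
}

# case-insensitive match of incoming headers onto canonical names
canonical_sf_names <- function(nms) {
  canon <- c(SF_REQUIRED, "site_id", "grassland_type", SF_NUMERIC)
  hit <- match(tolower(nms), tolower(canon))
  ifelse(is.na(hit), nms, canon[hit])
}

#' Read a sample metadata TSV
#' @param path TSV file with a header row; column names matched case-insensitively.
#' @return A validated [sample_frame()].
#' @export
read_sample_frame <- function(path) {
  raw <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse sample frame: ",
                                           conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < length(SF_REQUIRED))
    stop("sample frame at ", path, " is empty or lacks required columns")
  sample_frame(raw)
}

#' Write a sample frame as TSV
#' @param x a [sample_frame()].
#' @param path output file path.
#' @export
write_sample_frame <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a labelled distance matrix
#'
#' @param values square symmetric non-negative matrix with zero diagonal.
#' @param metric metric name (e.g. `"bray_curtis"`, `"haversine_km"`).
#' @param labels optional label vector; defaults to dimnames.
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(values, metric, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(diag(values))) > 1e-10) stop("distance matrix diagonal must be zero")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(values < -1e-12)) stop("distances must be non-negative")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix [%s]: %d samples\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}

dm_subset <- function(dm, labels) {
  dist_matrix(unclass(dm)[labels, labels, drop = FALSE], attr(dm, "metric"))
}

#' Align count tables and metadata on shared samples
#'
#' Restricts each table and the sample frame to the intersection of sample ids
#' and imposes one deterministic (lexicographic) sample ordering everywhere.
#' Fungal sample loss is handled per-domain downstream: alignment here is of
#' whichever tables are passed together.
#'
#' @param tables named list of [count_table()] objects.
#' @param frame a [sample_frame()].
#' @return A list with `tables`, `frame`, and `dropped` (per-table dropped ids).
#' @export
align_bundle <- function(tables, frame) {
  if (!length(tables)) stop("no count tables supplied")
  common <- Reduce(intersect, c(lapply(tables, rownames), list(frame$sample_id)))
  if (!length(common)) stop("alignment error: no samples shared by all inputs")
  common <- sort(common)  # lexicographic: deterministic across runs
  dropped <- lapply(tables, function(t) setdiff(rownames(t), common))
  dropped$frame <- setdiff(frame$sample_id, common)
  tables <- lapply(tables, function(t) t[common, , drop = FALSE])
  frame <- frame[common, , drop = FALSE]
  class(frame) <- c("sample_frame", "data.frame")
  list(tables = tables, frame = frame, dropped = dropped)
}
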