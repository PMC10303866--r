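#' Read a binned contact matrix
#'
#' Two dialects are supported: `"dense"` (whitespace-separated n x n matrix)
#' and `"triplet"` (rows `bin_i bin_j count` with 0-based bin indices storing
#' the upper triangle only; symmetry is materialized on read).
#'
#' @param path input file.
#' @param bins [genome_bins()] table defining the matrix dimension.
#' @param dialect `"triplet"` or `"dense"`.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bins, dialect = c("triplet", "dense")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  n <- nrow(bins)
  if (dialect == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop("dense matrix is ", nrow(m), "x", ncol(m), " but bins define ", n)
    return(contact_matrix(m, bins))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- matrix(0, n, n)
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(f) != 3 || anyNA(suppressWarnings(as.numeric(f))))
      stop("malformed triplet row at line ", k, ": '", lines[k], "'")
    i <- as.integer(f[1]); j <- as.integer(f[2]); v <- as.numeric(f[3])
    if (i < 0 || j < 0 || i >= n || j >= n)
      stop("bin index out of range at line ", k, ": (", i, ",", j,
           ") for ", n, " bins")
    if (v < 0) stop("negative count at line ", k)
    m[i + 1, j + 1] <- m[i + 1, j + 1] + v
    if (i != j) m[j + 1, i + 1] <- m[j + 1, i + 1] + v
  }
  contact_matrix(m, bins)
}

#' Write a contact matrix
#'
#' The triplet dialect writes the upper triangle only (zero entries skipped);
#' the dense dialect writes the full matrix, tab-separated.
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param dialect `"triplet"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, dialect = c("triplet", "dense")) {
  dialect <- match.arg(dialect)
  if (dialect == "dense") {
    utils::write.table(m$counts, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                       format(m$counts[idx], digits = 17, trim = TRUE,
                              scientific = FALSE)), path)
  }
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' One value per bin; `NA` values are encoded as absent rows. Coordinates are
#' 0-based half-open, matching the internal convention.
#'
#' @param values numeric vector, one entry per bin (`NA` allowed).
#' @param bins [genome_bins()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(values, bins, path) {
  if (length(values) != nrow(bins))
    stop("track has ", length(values), " values for ", nrow(bins), " bins")
  keep <- !is.na(values)
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s", bins$chrom[keep],
                     bins$start[keep], bins$end[keep],
                     vapply(values[keep], format, character(1), digits = 17,
                            trim = TRUE, drop0trailing = TRUE)), path)
  invisible(path)
}

#' Read a bedGraph track onto a bin table
#'
#' @param path bedGraph file.
#' @param bins [genome_bins()] table; rows are matched by (chrom, start).
#' @return numeric vector, one value per bin, `NA` where absent.
#' @export
read_track <- function(path, bins) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  key <- sprintf("%s:%.0f", bins$chrom, bins$start)
  out <- rep(NA_real_, nrow(bins))
  hit <- match(sprintf("%s:%.0f", df$chrom, df$start), key)
  if (anyNA(hit)) stop("bedGraph interval not on the bin grid")
  out[hit] <- df$value
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  df <- intervals[, cols, drop = FALSE]
  df$start <- sprintf("%.0f", df$start)
  df$end <- sprintf("%.0f", df$end)
  utils::write.table(df, path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `score` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t")
  names(df) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(df))]
  df
}

#' Read a nucleus image from TIFF
#'
#' @param path TIFF file (2D, grayscale).
#' @param pixel_size physical pixel size in um/pixel (config-supplied; the
#'   imaging-system pixel size is not embedded in the fixtures).
#' @param nucleus_mask,exclusion_mask optional logical matrices; defaults are
#'   all-true / all-false.
#' @return a [nucleus_image()].
#' @export
read_nucleus_image <- function(path, pixel_size,
                               nucleus_mask = NULL, exclusion_mask = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  if (any(px < 0)) stop("negative intensities in image")
  nucleus_image(px, pixel_size, nucleus_mask, exclusion_mask)
}

#' Write a nucleus image as TIFF
#' @param img a [nucleus_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_nucleus_image <- function(img, path) {
  px <- img$intensity
  px <- px / max(px, 1e-12)  # readTIFF/writeTIFF exchange [0,1] floats
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a fluorescence trace CSV
#'
#' Expected layout: a header line `# pre_bleach_frames: <k>` followed by a
#' CSV with columns `time`, `bleached`, `reference`.
#'
#' @param path CSV file.
#' @return a [fluor_trace()].
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  pre <- NA_integer_
  skip <- 0
  if (grepl("^#", first)) {
    mt <- regmatches(first, regexec("pre_bleach_frames:\\s*([0-9]+)", first))[[1]]
    if (length(mt) == 2) pre <- as.integer(mt[2])
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip)
  need <- c("time", "bleached", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (is.na(pre)) stop("trace CSV lacks '# pre_bleach_frames:' header")
  fluor_trace(df$time, df$bleached, df$reference, pre)
}

#' Write a fluorescence trace CSV
#' @param trace a [fluor_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pre_bleach_frames: %d", trace$pre_bleach_count), con)
  utils::write.csv(data.frame(time = trace$times, bleached = trace$bleached,
                              reference = trace$reference),
                   con, row.names = FALSE)
  invisible(path)
}
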