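#' Construct a genome bin table
#'
#' Bins are 0-based half-open `[start, end)` intervals, contiguous and
#' non-overlapping within a chromosome, of uniform size except possibly the
#' last bin of each chromosome. The `bin` column is a dense 0-based index
#' across the whole table.
#'
#' @param chroms character vector of chromosome names, one per chromosome.
#' @param chrom_sizes integer vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return a `data.frame` of class `genome_bins` with columns
#'   `chrom`, `start`, `end`, `bin`.
#' @examples
#' genome_bins("chr1", 1e6, 150e3)
#' @export
genome_bins <- function(chroms, chrom_sizes, bin_size) {
  stopifnot(length(chroms) == length(chrom_sizes), bin_size >= 1,
            all(chrom_sizes >= 1))
  pieces <- lapply(seq_along(chroms), function(i) {
    starts <- seq(0, chrom_sizes[i] - 1, by = bin_size)
    data.frame(chrom = chroms[i], start = starts,
               end = pmin(starts + bin_size, chrom_sizes[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  class(out) <- c("genome_bins", "data.frame")
  out
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins on %d chromosome(s), bin size %s bp\n",
              nrow(x), length(unique(x$chrom)),
              format(bin_size_of(x), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Bin width of a bin table
#'
#' The uniform bin size (mode of `end - start`; the terminal bin of each
#' chromosome may be shorter).
#' @param bins a `genome_bins` table.
#' @return bin size in bp.
#' @export
bin_size_of <- function(bins) {
  w <- bins$end - bins$start
  as.numeric(names(sort(table(w), decreasing = TRUE))[1])
}

validate_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "bin") %in% names(bins)))
  if (!identical(as.integer(bins$bin), seq_len(nrow(bins)) - 1L))
    stop("bin index must be dense 0..n-1")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins must be sorted within chromosome ", ch)
    if (any(b$start[-1] != b$end[-nrow(b)]))
      stop("bins must be contiguous within chromosome ", ch)
  }
  invisible(bins)
}
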