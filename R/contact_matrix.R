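#' Contact matrix container
#'
#' A symmetric binned Hi-C contact matrix bundled with its bin table and,
#' after balancing, per-bin ICE weights. Masked bins (low coverage) carry
#' `NA` weights and are excluded from all downstream statistics.
#'
#' @param counts symmetric non-negative numeric matrix, one row/column per bin.
#' @param bins a [genome_bins()] table with `nrow(bins) == nrow(counts)`.
#' @param weights optional per-bin balancing weights (`NA` = masked).
#' @param balanced logical; `TRUE` once [ice_balance()] has been applied.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bins, weights = NULL, balanced = FALSE) {
  counts <- as.matrix(counts)
  validate_bins(bins)
  if (nrow(counts) != nrow(bins))
    stop("dimension mismatch: ", nrow(counts), " matrix rows vs ",
         nrow(bins), " bins")
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8 * max(1, max(abs(counts), na.rm = TRUE)))
    stop("contact matrix must be symmetric")
  if (any(counts < 0, na.rm = TRUE)) stop("contact counts must be non-negative")
  if (!is.null(weights) && length(weights) != nrow(counts))
    stop("weights length must equal number of bins")
  structure(list(counts = counts, bins = bins,
                 bin_size = bin_size_of(bins),
                 weights = weights, balanced = balanced),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins (%s bp), total %.4g, %s\n",
              nrow(x$counts), ncol(x$counts),
              format(x$bin_size, big.mark = ","), sum(x$counts),
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Total contact count of a matrix
#' @param m a `contact_matrix`.
#' @return sum of all entries.
#' @export
total_contacts <- function(m) sum(m$counts)

#' Indices of unmasked (valid) bins
#' @param m a `contact_matrix`.
#' @return integer vector of 1-based valid bin indices.
#' @export
valid_bins <- function(m) {
  if (is.null(m$weights)) seq_len(nrow(m$counts)) else which(!is.na(m$weights))
}

#' Scale a contact matrix to a target total
#'
#' Multiplies all counts so the matrix total equals `target_total`, the
#' library-size step used before comparing conditions (e.g. matrices
#' normalized to 160 million contacts before differencing).
#'
#' @param m a `contact_matrix`.
#' @param target_total desired total contact count.
#' @return rescaled `contact_matrix`.
#' @export
normalize_total <- function(m, target_total) {
  tot <- sum(m$counts)
  if (tot <= 0) stop("cannot normalize a matrix with zero total")
  stopifnot(target_total > 0)
  m$counts <- m$counts * (target_total / tot)
  m
}

#' Entrywise difference of two contact matrices
#'
#' Signed differential map `a - b` on commonly valid bins; pairs involving a
#' bin masked in either input are `NA`. Inputs should be normalized to the
#' same total first (see [normalize_total()]).
#'
#' @param a,b `contact_matrix` objects on identical bins.
#' @return matrix of signed differences.
#' @export
differential_matrix <- function(a, b) {
  if (!isTRUE(all.equal(a$bins$start, b$bins$start)) ||
      !identical(a$bins$chrom, b$bins$chrom))
    stop("bin tables do not align")
  d <- a$counts - b$counts
  bad <- union(setdiff(seq_len(nrow(d)), valid_bins(a)),
               setdiff(seq_len(nrow(d)), valid_bins(b)))
  if (length(bad)) { d[bad, ] <- NA_real_; d[, bad] <- NA_real_ }
  d
}
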