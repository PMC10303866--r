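#' Photobleaching correction against the reference ROI
#'
#' Divides the bleached-ROI intensity by the reference-ROI intensity
#' relative to its pre-bleach mean, removing signal loss caused by
#' acquisition itself. The corrected trace's reference channel is the
#' constant 1.
#'
#' @param trace a [fluor_trace()].
#' @return corrected [fluor_trace()].
#' @export
correct_photobleaching <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  pre <- seq_len(trace$pre_bleach_count)
  ref0 <- mean(trace$reference[pre])
  if (any(trace$reference <= 0)) {
    bad <- which(trace$reference <= 0)[1]
    stop("non-positive reference intensity at frame ", bad)
  }
  corr <- trace$bleached / (trace$reference / ref0)
  fluor_trace(trace$times, pmax(corr, 1e-12),
              rep(1, length(trace$times)), trace$pre_bleach_count)
}

#' Normalize a FRAP trace to pre-bleach 1 and post-bleach 0
#'
#' Affine map sending the mean pre-bleach intensity to 1 and the first
#' post-bleach intensity to 0 (the standard FRAP normalization after
#' photobleaching correction).
#'
#' @param trace a [fluor_trace()] (ideally photobleaching-corrected).
#' @return list: `times`, `values` (normalized), `pre_bleach_count`.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  pre <- seq_len(trace$pre_bleach_count)
  top <- mean(trace$bleached[pre])
  bottom <- trace$bleached[trace$pre_bleach_count + 1]
  if (abs(top - bottom) < 1e-12)
    stop("degenerate normalization: pre-bleach mean equals first post-bleach value")
  list(times = trace$times,
       values = (trace$bleached - bottom) / (top - bottom),
       pre_bleach_count = trace$pre_bleach_count)
}

#' Normalize an iFRAP trace to the first pre-bleach frame
#'
#' @param trace a [fluor_trace()].
#' @return list: `times`, `values`, `pre_bleach_count`.
#' @export
normalize_ifrap <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  first <- trace$bleached[1]
  if (first <= 0) stop("first pre-bleach value must be positive")
  list(times = trace$times, values = trace$bleached / first,
       pre_bleach_count = trace$pre_bleach_count)
}

#' Fit a double-exponential recovery
#'
#' Least squares of `A*(1 - exp(-t/tauA)) + B*(1 - exp(-t/tauB))` on
#' post-bleach points (`t >= 0`), with `A, B` bounded in `[0, 1.5]` and
#' time constants in `(0, 1e5]` s. Components are reordered so
#' `tauA <= tauB`; the residence time is the slower constant `tauB`.
#' Initialization: `tauB` from a log-linear fit of the recovery deficit
#' over the last third of the trace, `tauA = tauB / 10`, amplitudes from
#' the plateau split. When the two constants differ by less than 2x the
#' fit is flagged `poorly_separated`; a vanishing fast component is
#' flagged `degenerate`.
#'
#' @param times time points in seconds (0 = first post-bleach frame).
#' @param values normalized recovery values.
#' @return list of class `frap_fit`: `A`, `B`, `tauA`, `tauB`,
#'   `residence_time`, `rss`, `converged`, `degenerate`,
#'   `poorly_separated`.
#' @export
fit_double_exponential <- function(times, values) {
  keep <- times >= 0
  t <- times[keep]; y <- values[keep]
  if (length(t) < 8) stop("insufficient data: need >= 8 post-bleach points")
  plateau <- mean(y[t >= stats::quantile(t, 0.8)])
  make_result <- function(A, B, tauA, tauB, rss, converged,
                          degenerate = FALSE) {
    if (tauA > tauB) { tmp <- tauA; tauA <- tauB; tauB <- tmp
                       tmp <- A; A <- B; B <- tmp }
    structure(list(A = A, B = B, tauA = tauA, tauB = tauB,
                   residence_time = tauB, rss = rss, converged = converged,
                   degenerate = degenerate || A < 1e-3 || B < 1e-3,
                   poorly_separated = tauB / max(tauA, 1e-12) < 2),
              class = "frap_fit")
  }
  if (max(abs(y)) < 1e-9)
    return(make_result(0, 0, 1, 1, 0, TRUE, degenerate = TRUE))
  # init: slow constant from a log-linear fit to the tail deficit, plus a
  # log-spaced multi-start grid (the tail fit degenerates when recovery is
  # complete well before the end of the trace)
  tail_idx <- t >= stats::quantile(t, 2 / 3)
  deficit <- pmax(plateau * 1.05 - y[tail_idx], 1e-9)
  lf <- stats::lm(log(deficit) ~ t[tail_idx])
  tauB0 <- -1 / stats::coef(lf)[2]
  cand <- max(t) / c(100, 30, 10, 3, 1)
  if (is.finite(tauB0) && tauB0 > 0)
    cand <- c(min(max(tauB0, min(diff(t[t > min(t)]))), 1e5), cand)
  fit <- NULL
  for (tb in cand) {
    f1 <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-t / tauA)) + B * (1 - exp(-t / tauB)),
        data = data.frame(t = t, y = y),
        start = list(A = max(plateau / 2, 0.01), B = max(plateau / 2, 0.01),
                     tauA = tb / 10, tauB = tb),
        lower = c(A = 0, B = 0, tauA = 1e-6, tauB = 1e-6),
        upper = c(A = 1.5, B = 1.5, tauA = 1e5, tauB = 1e5),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f1) &&
        (is.null(fit) || sum(stats::resid(f1)^2) < sum(stats::resid(fit)^2)))
      fit <- f1
  }
  if (is.null(fit)) {
    # single-exponential fallback, flagged as a degenerate second component
    sf <- tryCatch(
      minpack.lm::nlsLM(y ~ B * (1 - exp(-t / tauB)),
                        data = data.frame(t = t, y = y),
                        start = list(B = max(plateau, 0.01), tauB = tauB0),
                        lower = c(B = 0, tauB = 1e-6),
                        upper = c(B = 1.5, tauB = 1e5)),
      error = function(e) NULL)
    if (is.null(sf))
      return(make_result(0, plateau, 1, tauB0, NA_real_, FALSE,
                         degenerate = TRUE))
    cf <- stats::coef(sf)
    return(make_result(0, cf[["B"]], cf[["tauB"]] / 10, cf[["tauB"]],
                       sum(stats::resid(sf)^2), TRUE, degenerate = TRUE))
  }
  cf <- stats::coef(fit)
  make_result(cf[["A"]], cf[["B"]], cf[["tauA"]], cf[["tauB"]],
              sum(stats::resid(fit)^2), TRUE)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap_fit: A %.3g (tauA %.3g s), B %.3g (tauB %.3g s), residence %.3g s%s\n",
    x$A, x$tauA, x$B, x$tauB, x$residence_time,
    if (x$degenerate) " [degenerate]"
    else if (x$poorly_separated) " [poorly separated]" else ""))
  invisible(x)
}

#' Fit a FRAP trace end to end
#'
#' [correct_photobleaching()] then [normalize_frap()] then
#' [fit_double_exponential()].
#'
#' @param trace a [fluor_trace()].
#' @return a `frap_fit`.
#' @export
fit_frap_trace <- function(trace) {
  nz <- normalize_frap(correct_photobleaching(trace))
  fit_double_exponential(nz$times, nz$values)
}

#' Pointwise mean and SD over traces on a common time grid
#'
#' @param traces list of normalized traces (each a list with `times` and
#'   `values` on identical grids).
#' @return data.frame: `time`, `mean`, `sd`, `n`.
#' @export
aggregate_traces <- function(traces) {
  if (length(traces) < 2) stop("need >= 2 traces")
  t0 <- traces[[1]]$times
  for (tr in traces[-1])
    if (!isTRUE(all.equal(tr$times, t0)))
      stop("time grids do not align across traces")
  V <- sapply(traces, function(tr) tr$values)
  data.frame(time = t0, mean = rowMeans(V), sd = apply(V, 1, stats::sd),
             n = length(traces))
}
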