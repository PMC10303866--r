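#' Parameters for the FRAP / iFRAP trace generator
#'
#' FRAP mode inverts the analysis model: after the bleach the normalized
#' recovery follows `F(t) = A*(1 - exp(-t/tauA)) + B*(1 - exp(-t/tauB))`,
#' modulated by a per-frame acquisition photobleaching decay shared with
#' the reference channel. iFRAP mode produces the unbleached-region decay
#' `a*exp(-t/ifrap_tau) + ifrap_plateau` with `a = 1 - ifrap_plateau`, so
#' the first pre-bleach frame is 1 before noise.
#'
#' @param A,B recovery amplitudes (dimensionless, `A + B <= 1`).
#' @param tauA,tauB recovery time constants in seconds; reordered so
#'   `tauA <= tauB`.
#' @param dt frame interval, seconds.
#' @param n_pre,n_post pre- and post-bleach frame counts (`n_pre >= 1`).
#' @param acquisition_bleach_rate per-frame fractional intensity loss from
#'   imaging itself (applied to both channels).
#' @param noise_sd additive Gaussian noise sd on normalized intensities.
#' @param mode `"frap"` or `"ifrap"`.
#' @param ifrap_tau iFRAP decay time constant, seconds.
#' @param ifrap_plateau iFRAP long-time plateau (1 = stably bound limit).
#' @param seed RNG seed.
#' @return an object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(A = 0.3, B = 0.5, tauA = 2, tauB = 30, dt = 1,
                            n_pre = 3, n_post = 300,
                            acquisition_bleach_rate = 0, noise_sd = 0,
                            mode = c("frap", "ifrap"),
                            ifrap_tau = 200, ifrap_plateau = 0.7,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (n_pre < 1) stop("n_pre must be >= 1 (normalization needs pre-bleach frames)")
  stopifnot(A >= 0, B >= 0, A + B <= 1, tauA > 0, tauB > 0, dt > 0,
            n_post >= 2, acquisition_bleach_rate >= 0,
            acquisition_bleach_rate < 1, noise_sd >= 0,
            ifrap_tau > 0, ifrap_plateau >= 0, ifrap_plateau <= 1)
  if (tauA > tauB) { tmp <- tauA; tauA <- tauB; tauB <- tmp
                     tmp <- A; A <- B; B <- tmp }
  structure(list(A = A, B = B, tauA = tauA, tauB = tauB, dt = dt,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 noise_sd = noise_sd, mode = mode, ifrap_tau = ifrap_tau,
                 ifrap_plateau = ifrap_plateau, seed = as.integer(seed)),
            class = "frap_sim_params")
}

#' Closed-form biexponential FRAP recovery
#'
#' `A*(1 - exp(-t/tauA)) + B*(1 - exp(-t/tauB))` for `t >= 0`, 0 before.
#' @param t time in seconds (0 = first post-bleach frame).
#' @param A,B,tauA,tauB model parameters.
#' @return recovery values.
#' @export
frap_recovery <- function(t, A, B, tauA, tauB) {
  ifelse(t < 0, 0, A * (1 - exp(-t / tauA)) + B * (1 - exp(-t / tauB)))
}

#' Simulate a FRAP trace
#'
#' @param params a [frap_sim_params()] with `mode = "frap"`.
#' @return a [fluor_trace()]; time 0 is the first post-bleach frame and
#'   pre-bleach frames carry negative times.
#' @export
simulate_frap_trace <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  if (params$mode != "frap") stop("params mode must be 'frap'")
  p <- params
  local_seed(p$seed)
  k <- seq_len(p$n_pre + p$n_post) - 1          # global frame index
  t <- (k - p$n_pre) * p$dt                     # t = 0 at first post frame
  decay <- (1 - p$acquisition_bleach_rate)^k
  signal <- ifelse(t < 0, 1, frap_recovery(t, p$A, p$B, p$tauA, p$tauB))
  bleached <- signal * decay
  reference <- decay
  if (p$noise_sd > 0) {
    bleached <- bleached + stats::rnorm(length(t), 0, p$noise_sd)
    reference <- reference + stats::rnorm(length(t), 0, p$noise_sd)
  }
  eps <- 1e-6
  fluor_trace(t, pmax(bleached, eps), pmax(reference, eps), p$n_pre)
}

#' Simulate an iFRAP trace
#'
#' The unbleached-region signal decays as `a*exp(-t/ifrap_tau) + plateau`
#' with `a = 1 - plateau`; pre-bleach frames sit at 1.
#'
#' @param params a [frap_sim_params()] with `mode = "ifrap"`.
#' @return a [fluor_trace()] (reference channel mirrors the acquisition
#'   bleach decay).
#' @export
simulate_ifrap_trace <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  if (params$mode != "ifrap") stop("params mode must be 'ifrap'")
  p <- params
  local_seed(p$seed)
  k <- seq_len(p$n_pre + p$n_post) - 1
  t <- (k - p$n_pre) * p$dt
  a <- 1 - p$ifrap_plateau
  signal <- ifelse(t < 0, 1, a * exp(-t / p$ifrap_tau) + p$ifrap_plateau)
  decay <- (1 - p$acquisition_bleach_rate)^k
  bleached <- signal * decay
  reference <- decay
  if (p$noise_sd > 0) {
    bleached <- bleached + stats::rnorm(length(t), 0, p$noise_sd)
    reference <- reference + stats::rnorm(length(t), 0, p$noise_sd)
  }
  eps <- 1e-6
  fluor_trace(t, pmax(bleached, eps), pmax(reference, eps), p$n_pre)
}
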