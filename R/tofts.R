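#' Population arterial input function (biexponential)
#'
#' Weinmann-type biexponential plasma concentration following a bolus of
#' dose D mmol per kg body weight:
#' Cp(t) = D * (a1 exp(-m1 t) + a2 exp(-m2 t)) for t past the onset, 0 before.
#' Time is measured in seconds; the rate constants are per minute internally.
#'
#' @param times_s numeric vector of sample times (s).
#' @param onset_s bolus arrival time (s).
#' @param dose dose in mmol/kg.
#' @param a1,a2 amplitudes (kg/L).
#' @param m1,m2 decay rates (1/min).
#' @return plasma concentration (mmol/L) at `times_s`.
#' @export
aif_biexponential <- function(times_s, onset_s = 60, dose = 0.1,
                              a1 = 3.99, m1 = 0.144, a2 = 4.78, m2 = 0.0111) {
  tm <- pmax(times_s - onset_s, 0) / 60  # minutes past onset
  ifelse(times_s > onset_s,
         dose * (a1 * exp(-m1 * tm) + a2 * exp(-m2 * tm)), 0)
}

# Convolution integral g_kep(t) = int_0^t Cp(tau) exp(-kep (t - tau)) dtau
# (kep in 1/min, t in seconds), computed by the exponential-kernel recursion
# that is exact when Cp is piecewise linear between samples. Returns a matrix
# when kep is a vector: rows = times, cols = kep values.
tofts_kernel <- function(aif, times_s, kep) {
  n <- length(times_s)
  if (n < 2) stop("need at least 2 time points")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (length(aif) != n) stop("aif and times lengths differ")
  tm <- times_s / 60
  dt <- diff(tm)
  k <- as.numeric(kep)
  out <- matrix(0, n, length(k))
  g <- numeric(length(k))
  for (i in seq_len(n - 1)) {
    h <- dt[i]
    c0 <- aif[i]; c1 <- aif[i + 1]
    e <- exp(-k * h)
    # int_0^h (c0 + (c1-c0) s/h) exp(-k (h - s)) ds, exact for linear Cp;
    # series limit h(c0+c1)/2 - k h^2 (2 c0 + c1)/6 guards k -> 0
    small <- k * h <= 1e-8
    inc <- (c1 - e * c0) / k - (c1 - c0) * (1 - e) / (k * k * h)
    if (any(small))
      inc[small] <- h * (c0 + c1) / 2 - k[small] * h * h * (2 * c0 + c1) / 6
    g <- g * e + inc
    out[i + 1, ] <- g
  }
  out
}

#' Two-compartment Tofts forward model
#'
#' Tissue contrast concentration
#' Ct(t) = Ktrans * int_0^t Cp(tau) exp(-kep (t - tau)) dtau, kep = Ktrans/Ve.
#' The convolution uses an exponential-kernel recursion that is exact for an
#' AIF that is piecewise linear between frames, so the forward model and the
#' fit built on it are mutually consistent.
#'
#' @param ktrans transfer constant (1/min), >= 0.
#' @param ve extravascular extracellular volume fraction, in (0, 1].
#' @param aif plasma concentration sampled at `times_s` (mmol/L), or a function
#'   of time in seconds.
#' @param times_s strictly increasing sample times (s).
#' @return tissue concentration (mmol/L) at `times_s`.
#' @export
tofts_forward <- function(ktrans, ve, aif, times_s) {
  if (ktrans < 0) stop("ktrans must be >= 0")
  if (ve <= 0 || ve > 1) stop("ve must be in (0, 1]")
  if (is.function(aif)) aif <- aif(times_s)
  if (ktrans == 0) return(numeric(length(times_s)))
  kep <- ktrans / ve
  drop(ktrans * tofts_kernel(aif, times_s, kep))
}
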