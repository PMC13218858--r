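# Periodized orthogonal discrete wavelet transform with the Daubechies-5
# (10-tap) filter pair. Periodization keeps the transform orthonormal, so
# sub-band energies sum exactly to the signal energy - the property the
# EMG energy features rely on. A 320-sample (10 s at 32 Hz) window divides
# 2^6 cleanly down to 5 coefficients at level 6.

DB5_DEC_LO <- c(0.0033357252854737712, -0.012580751999081999,
                -0.006241490212798274, 0.07757149384004572,
                -0.032244869584638375, -0.24229488706638203,
                0.13842814590132074, 0.7243085284377729,
                0.6038292697971896, 0.16010239797419293)
DB5_DEC_HI <- c(-0.16010239797419293, 0.6038292697971896,
                -0.7243085284377729, 0.13842814590132074,
                0.24229488706638203, -0.032244869584638375,
                -0.07757149384004572, -0.006241490212798274,
                0.012580751999081999, 0.0033357252854737712)

dwt_step_per <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  half <- n %/% 2L
  out <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    out[k] <- sum(filt * x[idx])
  }
  out
}

#' 6-level db5 wavelet decomposition (periodized)
#'
#' @param x Numeric vector whose length is divisible by 64.
#' @param levels Number of decomposition levels (default 6).
#' @return Named list of coefficient vectors `d1` (finest, upper half of
#'   the spectrum) through `d6` and the approximation `a6`.
#' @export
dwt_db5 <- function(x, levels = 6) {
  n <- length(x)
  if (n %% (2^levels) != 0) {
    stop("signal length must be divisible by 2^levels for periodized DWT")
  }
  out <- list()
  a <- x
  for (lev in seq_len(levels)) {
    d <- dwt_step_per(a, DB5_DEC_HI)
    a <- dwt_step_per(a, DB5_DEC_LO)
    out[[paste0("d", lev)]] <- d
  }
  out[[paste0("a", levels)]] <- a
  out
}
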