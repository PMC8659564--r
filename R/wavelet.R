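# Orthogonal wavelet filter banks. sym8 (Symlet, 8 vanishing moments) is the
# only filter shipped: it is the near-symmetric Daubechies variant whose
# level-8 approximation acts as a smooth amplitude envelope of rectified sEMG.
# Coefficients are the published 16-tap sym8 decomposition low-pass filter;
# the remaining three filters follow from the standard quadrature-mirror
# relations.
.SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
  0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
  0.48135965125837221, 0.77718575170052351, 0.36444189483533086,
  -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
  0.0038087520138906151, -0.014952258337048231, -0.00030292051472413308,
  0.0018899503327594609
)

wavelet_filters <- function(wavelet = "sym8") {
  if (!identical(wavelet, "sym8")) {
    stop("unsupported wavelet '", wavelet, "': only 'sym8' is available",
         call. = FALSE)
  }
  lo <- .SYM8_DEC_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)          # QMF: hi[m] = (-1)^(m+1) lo[L-1-m]
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), length = L)
}

# One level of the periodized orthogonal DWT (length n must be even).
# Convention (matches PyWavelets mode = "periodization"):
#   cA[k] = sum_m lo[m] x[(2k + L/2 - m) mod n],  k = 0..n/2-1
.dwt_per <- function(x, filt) {
  n <- length(x)
  L <- filt$length
  y_lo <- numeric(n)
  y_hi <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (m in 0:(L - 1L)) {
    xs <- x[((idx0 - m) %% n) + 1L]
    y_lo <- y_lo + filt$dec_lo[m + 1L] * xs
    y_hi <- y_hi + filt$dec_hi[m + 1L] * xs
  }
  keep <- ((seq_len(n %/% 2L) - 1L) * 2L + L %/% 2L) %% n + 1L
  list(cA = y_lo[keep], cD = y_hi[keep])
}

# Inverse of .dwt_per: x[j] = sum_k cA[k] rec_lo[(j - 2k + L/2 - 1) mod n] + ...
.idwt_per <- function(cA, cD, filt) {
  n <- 2L * length(cA)
  L <- filt$length
  up <- numeric(n)
  up[seq(1L, n, by = 2L)] <- cA
  up_d <- numeric(n)
  up_d[seq(1L, n, by = 2L)] <- cD
  x <- numeric(n)
  idx0 <- seq_len(n) - 1L
  shift <- L %/% 2L - 1L
  for (m in 0:(L - 1L)) {
    sel <- ((idx0 + shift - m) %% n) + 1L
    x <- x + filt$rec_lo[m + 1L] * up[sel] + filt$rec_hi[m + 1L] * up_d[sel]
  }
  x
}

#' Level-`level` wavelet approximation of a signal
#'
#' Decomposes `signal` with a multilevel discrete wavelet transform, zeroes
#' every detail band, and reconstructs, returning a smooth approximation of
#' the original length. At level 8 the approximation band is roughly
#' \eqn{[0, f_s/2^9]}, which turns a rectified sEMG trace into an amplitude
#' envelope while discarding the noise-like detail content.
#'
#' Boundaries are handled by reflecting the tail of the signal up to the next
#' multiple of \eqn{2^{level}} and running a periodized orthogonal filter
#' bank; the output is truncated back to the input length. When the input
#' length is already a multiple of \eqn{2^{level}} the operator is an exact
#' orthogonal projection onto the approximation space (and hence idempotent
#' to machine precision).
#'
#' @param signal Numeric vector.
#' @param wavelet Wavelet name; only `"sym8"` is shipped.
#' @param level Decomposition depth (default 8).
#' @return Numeric vector, same length as `signal`.
#' @examples
#' x <- sin(2 * pi * seq(0, 4, length.out = 2048)) + rnorm(2048, sd = 0.5)
#' a <- dwt_approximation(x, "sym8", 8)
#' @export
dwt_approximation <- function(signal, wavelet = "sym8", level = 8L) {
  filt <- wavelet_filters(wavelet)
  level <- as.integer(level)
  stopifnot(level >= 1L)
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  n0 <- length(signal)
  block <- 2L^level
  if (n0 < block) {
    warning("signal shorter than 2^level (", n0, " < ", block,
            "); padding by reflection")
  }
  n <- max(block, as.integer(ceiling(n0 / block)) * block)
  pad <- n - n0
  x <- if (pad > 0L) c(signal, rev(signal)[seq_len(pad)]) else signal
  details <- vector("list", level)
  for (l in seq_len(level)) {
    d <- .dwt_per(x, filt)
    x <- d$cA
    details[[l]] <- length(d$cD)  # only lengths needed: details are zeroed
  }
  for (l in rev(seq_len(level))) {
    x <- .idwt_per(x, numeric(details[[l]]), filt)
  }
  x[seq_len(n0)]
}
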