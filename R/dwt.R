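# Multi-level 1-D discrete wavelet transform (Mallat pyramid) with
# half-sample symmetric boundary extension. Conventions (extension,
# downsampling phase, coefficient lengths floor((n+L-1)/2), inverse
# trimming) follow the standard ones of mainstream DWT libraries so that
# coefficient vectors are directly comparable across implementations.

# Orthogonal filter banks at double precision (dec_lo, dec_hi, rec_lo,
# rec_hi), Daubechies and symlet families.
.wavelet_bank <- list(
  haar = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)),
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.2241438680420134,
               0.8365163037378079, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.8365163037378079,
               -0.2241438680420134, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.8365163037378079,
               0.2241438680420134, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.2241438680420134,
               0.8365163037378079, -0.48296291314453416)),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852,
               0.030841381835560764, -0.18703481171909309,
               -0.027983769416859854, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157,
               -0.6308807679298589, -0.027983769416859854,
               0.18703481171909309, 0.030841381835560764,
               -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157,
               0.6308807679298589, -0.027983769416859854,
               -0.18703481171909309, 0.030841381835560764,
               0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852,
               0.030841381835560764, 0.18703481171909309,
               -0.027983769416859854, -0.6308807679298589,
               0.7148465705529157, -0.2303778133088965)),
  sym4 = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851,
               0.49761866763201545, 0.8037387518059161,
               0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.012603967262037833,
               0.09921954357684722, 0.29785779560527736,
               -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333),
    rec_lo = c(0.0322231006040427, -0.012603967262037833,
               -0.09921954357684722, 0.29785779560527736,
               0.8037387518059161, 0.49761866763201545,
               -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(-0.07576571478927333, 0.02963552764599851,
               0.49761866763201545, -0.8037387518059161,
               0.29785779560527736, 0.09921954357684722,
               -0.012603967262037833, -0.0322231006040427))
)

#' Available wavelets and their filter banks
#'
#' @param wavelet Wavelet name: one of `"haar"`, `"db2"`, `"db4"`,
#'   `"sym4"`.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` filter
#'   vectors.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  if (!wavelet %in% names(.wavelet_bank)) {
    fw_stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                    paste(names(.wavelet_bank), collapse = ", ")),
            "fragwave_parameter_error")
  }
  .wavelet_bank[[wavelet]]
}

# half-sample symmetric extension by L-1 samples on each side
symm_extend <- function(x, L) {
  n <- length(x)
  if (L <= 1) return(x)
  k <- L - 1L
  if (k > n) {  # reflect repeatedly for very short signals
    x_ext <- x
    while (length(x_ext) < k + n + k) x_ext <- c(rev(x), x_ext, rev(x))
    mid <- (length(x_ext) - n) %/% 2
    return(x_ext[(mid - k + 1):(mid + n + k)])
  }
  c(x[k:1], x, x[n:(n - k + 1)])
}

dwt_step <- function(x, filt) {
  L <- length(filt$dec_lo)
  n <- length(x)
  ext <- symm_extend(x, L)
  out_len <- (n + L - 1L) %/% 2L
  rl <- rev(filt$dec_lo)
  rh <- rev(filt$dec_hi)
  cA <- numeric(out_len)
  cD <- numeric(out_len)
  for (i in seq_len(out_len)) {
    seg <- ext[(2L * i):(2L * i + L - 1L)]
    cA[i] <- sum(seg * rl)
    cD[i] <- sum(seg * rh)
  }
  list(cA = cA, cD = cD)
}

idwt_step <- function(cA, cD, filt, out_len) {
  L <- length(filt$rec_lo)
  la <- length(cA)
  stopifnot(length(cD) == la)
  up <- function(c) {
    u <- numeric(2L * la - 1L)
    u[seq(1L, by = 2L, length.out = la)] <- c
    u
  }
  y <- convolve(up(cA), rev(filt$rec_lo), type = "open") +
    convolve(up(cD), rev(filt$rec_hi), type = "open")
  if (L > 2) y <- y[(L - 1L):(length(y) - (L - 2L))]
  y[seq_len(min(out_len, length(y)))]
}

#' Maximum useful decomposition level
#'
#' `floor(log2(n / (L - 1)))` for signal length `n` and filter length
#' `L` (1 level for the length-2 Haar filter per doubling).
#'
#' @param n Signal length.
#' @param wavelet Wavelet name.
#' @return Integer level (>= 0).
#' @export
dwt_max_level <- function(n, wavelet = "db4") {
  L <- length(wavelet_filters(wavelet)$dec_lo)
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

#' Per-level coefficient lengths
#'
#' Applies the recurrence `n_k = floor((n_{k-1} + L - 1) / 2)`.
#'
#' @param n Signal length.
#' @param wavelet Wavelet name.
#' @param level Decomposition depth.
#' @return Integer vector of coefficient lengths
#'   `c(cA_level, cD_level, ..., cD_1)`.
#' @export
dwt_coeff_lengths <- function(n, wavelet = "db4", level) {
  L <- length(wavelet_filters(wavelet)$dec_lo)
  lens <- integer(level)
  cur <- n
  for (k in seq_len(level)) {
    cur <- (cur + L - 1L) %/% 2L
    lens[k] <- cur
  }
  c(lens[level], rev(lens))
}

#' Multi-level discrete wavelet decomposition
#'
#' @param x Numeric signal.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @param level Decomposition depth, or `"max"` for the deepest
#'   admissible level.
#' @return List of class `wavedec`: `cA` (deepest approximation), `cD`
#'   (details, deepest first), `wavelet`, `level`, `n` (original
#'   length).
#' @export
wavedec <- function(x, wavelet = "db4", level = "max") {
  filt <- wavelet_filters(wavelet)
  n <- length(x)
  maxlev <- dwt_max_level(n, wavelet)
  if (identical(level, "max")) level <- maxlev
  assert_scalar_number(level, "level", 1)
  if (level > maxlev) {
    fw_stop(sprintf("level %d exceeds maximum %d for length %d and wavelet %s",
                    level, maxlev, n, wavelet),
            "fragwave_parameter_error")
  }
  if (n < length(filt$dec_lo)) {
    fw_stop("signal shorter than the wavelet filter",
            "fragwave_parameter_error")
  }
  cDs <- vector("list", level)
  cur <- as.numeric(x)
  for (k in seq_len(level)) {
    st <- dwt_step(cur, filt)
    cDs[[k]] <- st$cD
    cur <- st$cA
  }
  structure(list(cA = cur, cD = rev(cDs), wavelet = wavelet,
                 level = as.integer(level), n = n),
            class = "wavedec")
}

#' Inverse multi-level wavelet transform
#'
#' Perfect reconstruction: `waverec(wavedec(x))` recovers `x` to
#' floating-point accuracy.
#'
#' @param dec A `wavedec` object.
#' @return Numeric vector of length `dec$n`.
#' @export
waverec <- function(dec) {
  stopifnot(inherits(dec, "wavedec"))
  filt <- wavelet_filters(dec$wavelet)
  a <- dec$cA
  lev <- dec$level
  for (k in seq_len(lev)) {
    d <- dec$cD[[k]]
    # target length: the coefficient length one level up, or n at the top
    out_len <- if (k < lev) length(dec$cD[[k + 1L]]) else dec$n
    if (length(a) == length(d) + 1L) a <- a[seq_len(length(d))]
    a <- idwt_step(a, d, filt, out_len)
  }
  a
}
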