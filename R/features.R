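#' Discrete wavelet transform configuration
#'
#' @param wavelet Wavelet name (see [wavelet_filters()]); default
#'   `"db4"`.
#' @param level Decomposition depth or `"max"` (default) for the
#'   deepest admissible level.
#' @param boundary Boundary extension mode; only `"symmetric"`
#'   (half-sample reflection) is implemented.
#' @return Object of class `dwt_config`.
#' @export
dwt_config <- function(wavelet = "db4", level = "max",
                       boundary = "symmetric") {
  wavelet_filters(wavelet)  # validates the name
  if (!identical(boundary, "symmetric")) {
    fw_stop("only the 'symmetric' boundary mode is implemented",
            "fragwave_parameter_error")
  }
  structure(list(wavelet = wavelet, level = level, boundary = boundary),
            class = "dwt_config")
}

#' DWT coefficient features of a fragment-size profile
#'
#' Concatenates the deepest-level approximation coefficients followed by
#' detail coefficients from deepest to shallowest, the standard flat
#' layout of a multi-level decomposition. The length is fixed for a
#' fixed configuration and signal length (227 for the default db4
#' full-depth transform of a length-200 PMF).
#'
#' @param profile An [fs_profile] or plain numeric signal.
#' @param config A [dwt_config()].
#' @return Named numeric vector (`cA<level>_<i>`, `cD<k>_<i>`).
#' @export
dwt_features <- function(profile, config = dwt_config()) {
  x <- if (inherits(profile, "fs_profile")) profile$values else
    as.numeric(profile)
  dec <- wavedec(x, wavelet = config$wavelet, level = config$level)
  parts <- c(list(dec$cA), dec$cD)
  labs <- c(sprintf("cA%d", dec$level),
            sprintf("cD%d", rev(seq_len(dec$level))))
  nm <- unlist(lapply(seq_along(parts), function(i) {
    sprintf("%s_%02d", labs[i], seq_along(parts[[i]]) - 1L)
  }))
  setNames(unlist(parts), nm)
}

#' Engineered benchmark features of a fragment-size profile
#'
#' The three features of the baseline classifier:
#' \describe{
#'   \item{short_long_ratio}{mass in the short interval 100-150 bp over
#'     mass in the long interval 151-220 bp, exploiting the excess of
#'     short tumor-derived fragments;}
#'   \item{mean_fs_above_p80}{mean fragment size over sizes whose PMF
#'     value exceeds the 80th percentile of PMF values (peak-location
#'     shift); with `weighted = TRUE`, the PMF-weighted mean instead;}
#'   \item{area_right_of_166}{PMF mass strictly right of the theoretical
#'     166-bp mono-nucleosomal peak (skewness).}
#' }
#'
#' @param profile An [fs_profile] whose range contains 100-220 bp.
#' @param weighted Use a PMF-weighted mean for `mean_fs_above_p80`.
#' @return Named numeric vector of the three features.
#' @section Errors: a zero denominator in the short/long ratio signals
#'   an error of class `fragwave_undefined_feature`.
#' @export
benchmark_features <- function(profile, weighted = FALSE) {
  stopifnot(inherits(profile, "fs_profile"))
  s <- profile$sizes
  v <- profile$values
  if (s[1] > 100 || s[length(s)] < 220) {
    fw_stop("profile range must contain [100, 220] bp",
            "fragwave_parameter_error")
  }
  short <- sum(v[s >= 100 & s <= 150])
  long <- sum(v[s >= 151 & s <= 220])
  if (long == 0) {
    fw_stop("short/long ratio undefined: no mass in 151-220 bp",
            "fragwave_undefined_feature")
  }
  p80 <- quantile(v, 0.8, names = FALSE)
  sel <- v > p80
  if (!any(sel)) sel <- v >= p80  # constant profiles: fall back to ties
  mean_fs <- if (weighted) sum(s[sel] * v[sel]) / sum(v[sel]) else
    mean(s[sel])
  c(short_long_ratio = short / long,
    mean_fs_above_p80 = mean_fs,
    area_right_of_166 = sum(v[s > 166]))
}

#' Named fragment-size regions for ablation analysis
#'
#' Default boundaries partition the 51-250 bp range into the five
#' regions used for importance analysis. The boundaries are package
#' defaults (the regions are conventionally named but not standardized)
#' and fully configurable.
#'
#' @param left_oscillatory,right_oscillatory,mode,slope,tail Inclusive
#'   bp intervals.
#' @return Named list of intervals, class `ablation_regions`.
#' @export
ablation_regions <- function(left_oscillatory = c(51, 100),
                             right_oscillatory = c(101, 150),
                             mode = c(151, 180),
                             slope = c(181, 220),
                             tail = c(221, 250)) {
  regs <- list(left_oscillatory = left_oscillatory,
               right_oscillatory = right_oscillatory,
               mode = mode, slope = slope, tail = tail)
  for (nm in names(regs)) assert_range(regs[[nm]], nm)
  structure(regs, class = "ablation_regions")
}

#' Zero out one region of a profile
#'
#' Sets PMF values inside the named region to 0 and leaves the rest
#' untouched; the signal is deliberately not renormalized, so the
#' downstream DWT acts on the raw modified signal.
#'
#' @param profile An [fs_profile].
#' @param region Region name, one of `names(regions)`.
#' @param regions An [ablation_regions()] list.
#' @return An [fs_profile] (unchecked: values need not sum to 1) with
#'   attribute `ablated` naming the region.
#' @export
ablate_region <- function(profile, region, regions = ablation_regions()) {
  stopifnot(inherits(profile, "fs_profile"))
  if (!region %in% names(regions)) {
    fw_stop(sprintf("unknown region '%s'; known: %s", region,
                    paste(names(regions), collapse = ", ")),
            "fragwave_parameter_error")
  }
  iv <- regions[[region]]
  v <- profile$values
  v[profile$sizes >= iv[1] & profile$sizes <= iv[2]] <- 0
  out <- fs_profile(v, size_range = profile$size_range,
                    source_id = profile$source_id, check = FALSE)
  attr(out, "ablated") <- region
  out
}

#' Build a feature matrix from profiles
#'
#' @param profiles List of [fs_profile] objects.
#' @param kind `"dwt"` (wavelet coefficients), `"pmf"` (raw PMF) or
#'   `"benchmark"` (the three engineered features).
#' @param config [dwt_config()] used when `kind = "dwt"`.
#' @return Numeric matrix, one row per profile.
#' @export
featurize_profiles <- function(profiles, kind = c("dwt", "pmf", "benchmark"),
                               config = dwt_config()) {
  kind <- match.arg(kind)
  rows <- switch(kind,
    dwt = lapply(profiles, dwt_features, config = config),
    pmf = lapply(profiles, function(p) setNames(p$values,
                                                paste0("pmf_", p$sizes))),
    benchmark = lapply(profiles, benchmark_features))
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, function(p) p$source_id %||% "",
                        character(1))
  m
}
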