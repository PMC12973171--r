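#' Parameters of the synthetic fragment-size distribution model
#'
#' Defines a parametric fragment-size probability mass function with the
#' qualitative structure of real cfDNA size distributions: a dominant
#' mono-nucleosomal mode near 166 bp, a sub-mode (shoulder) near 145 bp,
#' an oscillatory component with ~10-bp period restricted to the short
#' (sub-150 bp) region, and a tumor-fraction-dependent shift of
#' probability mass toward short fragments. The mixture is built from
#' non-negative components and renormalized, so the resulting PMF is a
#' valid probability vector for any admissible parameter values. All
#' numeric defaults are model fixtures chosen to resemble published
#' healthy cfDNA profiles; they are not estimates of any cohort.
#'
#' The cancer signal is a convex contamination: with
#' `delta = tumor_fraction * short_shift_mass`, the class PMF is
#' `(1 - delta) * healthy + delta * short`, where `short` is the healthy
#' PMF restricted to sizes below 150 bp and renormalized. Hence
#' `tumor_fraction = 0` reproduces the healthy model exactly, and any
#' positive tumor fraction strictly increases the cumulative mass below
#' 150 bp.
#'
#' @param mode_center Center of the dominant mode (bp).
#' @param mode_width Gaussian width of the dominant mode (bp).
#' @param mode_weight Mixture weight of the dominant mode.
#' @param shoulder_center Center of the di-nucleosome-shadow shoulder
#'   sub-mode (bp).
#' @param shoulder_width Gaussian width of the shoulder (bp).
#' @param shoulder_weight Mixture weight of the shoulder.
#' @param oscillation_period Period of the short-range oscillation (bp).
#' @param oscillation_amplitude Mixture weight of the oscillatory
#'   component (dimensionless, >= 0; 0 disables the oscillation).
#' @param oscillation_range Interval (bp) carrying the oscillation.
#' @param oscillation_decay Exponential damping rate of the oscillation
#'   envelope away from the upper end of `oscillation_range` (per bp).
#' @param tumor_fraction Fraction of tumor-derived fragments in [0, 1].
#' @param short_shift_mass Probability mass moved below 150 bp per unit
#'   tumor fraction, in [0, 1].
#' @return An object of class `profile_model_params`.
#' @seealso [make_class_pmf()]
#' @export
profile_model_params <- function(mode_center = 166, mode_width = 9,
                                 mode_weight = 0.60,
                                 shoulder_center = 145, shoulder_width = 7,
                                 shoulder_weight = 0.15,
                                 oscillation_period = 10,
                                 oscillation_amplitude = 0.25,
                                 oscillation_range = c(51, 150),
                                 oscillation_decay = 0.02,
                                 tumor_fraction = 0,
                                 short_shift_mass = 0.15) {
  assert_scalar_number(mode_center, "mode_center", 1)
  assert_scalar_number(mode_width, "mode_width", 1e-6)
  assert_scalar_number(mode_weight, "mode_weight", 0)
  assert_scalar_number(shoulder_center, "shoulder_center", 1)
  assert_scalar_number(shoulder_width, "shoulder_width", 1e-6)
  assert_scalar_number(shoulder_weight, "shoulder_weight", 0)
  assert_scalar_number(oscillation_period, "oscillation_period", 1e-6)
  assert_scalar_number(oscillation_amplitude, "oscillation_amplitude", 0)
  assert_range(oscillation_range, "oscillation_range")
  assert_scalar_number(oscillation_decay, "oscillation_decay", 0)
  assert_scalar_number(tumor_fraction, "tumor_fraction", 0, 1)
  assert_scalar_number(short_shift_mass, "short_shift_mass", 0, 1)
  if (mode_weight + shoulder_weight + oscillation_amplitude <= 0) {
    fw_stop("at least one mixture component must have positive weight",
            "fragwave_parameter_error")
  }
  structure(list(mode_center = mode_center, mode_width = mode_width,
                 mode_weight = mode_weight,
                 shoulder_center = shoulder_center,
                 shoulder_width = shoulder_width,
                 shoulder_weight = shoulder_weight,
                 oscillation_period = oscillation_period,
                 oscillation_amplitude = oscillation_amplitude,
                 oscillation_range = as.numeric(oscillation_range),
                 oscillation_decay = oscillation_decay,
                 tumor_fraction = tumor_fraction,
                 short_shift_mass = short_shift_mass),
            class = "profile_model_params")
}

#' Evaluate the synthetic class PMF on a size range
#'
#' @param params A [profile_model_params()] object.
#' @param size_range Inclusive fragment-size interval (bp), default
#'   `c(51, 250)`.
#' @return An [fs_profile] of length `diff(size_range) + 1`.
#' @export
make_class_pmf <- function(params, size_range = c(51, 250)) {
  if (!inherits(params, "profile_model_params")) {
    fw_stop("`params` must be created by profile_model_params()",
            "fragwave_parameter_error")
  }
  assert_range(size_range, "size_range")
  sizes <- seq(size_range[1], size_range[2])

  # each mixture component is normalized to unit mass on the range,
  # so the weights are interpretable as mixture fractions
  comp <- function(x) {
    s <- sum(x)
    if (s > 0) x / s else x
  }
  mode_c <- comp(dnorm(sizes, params$mode_center, params$mode_width))
  shld_c <- comp(dnorm(sizes, params$shoulder_center, params$shoulder_width))

  osc <- numeric(length(sizes))
  in_osc <- sizes >= params$oscillation_range[1] &
    sizes <= params$oscillation_range[2]
  if (params$oscillation_amplitude > 0 && any(in_osc)) {
    l <- sizes[in_osc]
    hi <- params$oscillation_range[2]
    envelope <- exp(-params$oscillation_decay * (hi - l))
    phase <- 2 * pi * (l - hi) / params$oscillation_period
    osc[in_osc] <- envelope * (1 + cos(phase)) / 2
    osc <- comp(osc)
  }

  healthy <- params$mode_weight * mode_c +
    params$shoulder_weight * shld_c +
    params$oscillation_amplitude * osc
  healthy <- healthy / sum(healthy)

  delta <- params$tumor_fraction * params$short_shift_mass
  values <- healthy
  if (delta > 0) {
    short <- healthy * (sizes < 150)
    if (sum(short) == 0) {
      fw_stop("size_range contains no sizes below 150 bp to shift mass into",
              "fragwave_parameter_error")
    }
    short <- short / sum(short)
    values <- (1 - delta) * healthy + delta * short
  }
  values <- values / sum(values)
  fs_profile(values, size_range = size_range,
             source_id = sprintf("model_tf%.3f", params$tumor_fraction))
}
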