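#' Fragment-size profile (probability mass function)
#'
#' An `fs_profile` holds a probability mass function over an inclusive
#' fragment-size range, by default 51-250 bp (length 200), the unit
#' signal classified by the method.
#'
#' @param values Numeric vector of probabilities, one per size in
#'   `seq(size_range[1], size_range[2])`.
#' @param size_range Inclusive size interval (bp).
#' @param source_id Optional sample or subsample identifier.
#' @param check Validate non-negativity and unit sum (default `TRUE`).
#'   Internal callers that construct intentionally non-normalized
#'   signals (e.g. region ablation) disable the check.
#' @return An object of class `fs_profile` with fields `sizes`, `values`,
#'   `size_range`, `source_id`.
#' @export
fs_profile <- function(values, size_range = c(51, 250), source_id = NULL,
                       check = TRUE) {
  assert_range(size_range, "size_range")
  sizes <- seq(size_range[1], size_range[2])
  values <- as.numeric(values)
  if (length(values) != length(sizes)) {
    fw_stop(sprintf("profile length %d does not match size range [%d, %d] (length %d)",
                    length(values), size_range[1], size_range[2], length(sizes)),
            "fragwave_parameter_error")
  }
  if (check) {
    if (any(!is.finite(values)) || any(values < 0)) {
      fw_stop("profile values must be finite and non-negative",
              "fragwave_parameter_error")
    }
    if (abs(sum(values) - 1) > 1e-9) {
      fw_stop("profile values must sum to 1 within 1e-9",
              "fragwave_parameter_error")
    }
  }
  structure(list(sizes = sizes, values = values,
                 size_range = as.integer(size_range),
                 source_id = source_id),
            class = "fs_profile")
}

#' @export
print.fs_profile <- function(x, ...) {
  cat(sprintf("<fs_profile> %s sizes %d-%d bp, mode at %d bp\n",
              x$source_id %||% "", x$size_range[1], x$size_range[2],
              x$sizes[which.max(x$values)]))
  invisible(x)
}

#' Compute a fragment-size PMF from a size histogram
#'
#' Normalizes fragment counts over an inclusive size range:
#' `PMF(l) = N_l / sum_{j=k}^{m} N_j`. Histogram entries outside the
#' range are ignored; sizes absent from the histogram get probability 0.
#'
#' @param counts Either a named numeric vector (names are fragment sizes
#'   in bp) or a [binned_counts] object (summed over bins).
#' @param size_range Inclusive size interval (bp), default `c(51, 250)`.
#' @param source_id Optional identifier attached to the profile.
#' @return An [fs_profile].
#' @section Errors: if no fragment falls inside `size_range`, an error of
#'   class `fragwave_empty_profile` is signaled so callers can widen
#'   sampling.
#' @examples
#' p <- compute_pmf(c(`100` = 2, `166` = 6, `200` = 2))
#' p$values[p$sizes == 166]  # 0.6
#' @export
compute_pmf <- function(counts, size_range = c(51, 250), source_id = NULL) {
  assert_range(size_range, "size_range")
  if (inherits(counts, "binned_counts")) {
    if (is.null(source_id)) source_id <- counts$sample_id
    counts <- colSums(counts$counts)
  }
  if (is.null(names(counts))) {
    fw_stop("`counts` must be a named vector (names = fragment sizes) or a binned_counts object",
            "fragwave_parameter_error")
  }
  sz <- as.integer(names(counts))
  if (anyNA(sz)) {
    fw_stop("histogram names must be integer fragment sizes",
            "fragwave_parameter_error")
  }
  sizes <- seq(size_range[1], size_range[2])
  keep <- sz >= size_range[1] & sz <= size_range[2]
  vals <- numeric(length(sizes))
  if (any(keep)) {
    idx <- sz[keep] - size_range[1] + 1L
    vals[idx] <- vals[idx] + as.numeric(counts[keep])
  }
  total <- sum(vals)
  if (total <= 0) {
    fw_stop(sprintf("no fragments inside size range [%d, %d]",
                    size_range[1], size_range[2]),
            "fragwave_empty_profile")
  }
  fs_profile(vals / total, size_range = size_range, source_id = source_id)
}

#' Stack a list of profiles into a matrix
#'
#' @param profiles List of [fs_profile] objects sharing one size range.
#' @return Numeric matrix, one row per profile, columns named by size.
#' @export
profiles_to_matrix <- function(profiles) {
  if (!length(profiles)) fw_stop("empty profile list", "fragwave_parameter_error")
  rng <- profiles[[1]]$size_range
  ok <- vapply(profiles, function(p) all(p$size_range == rng), logical(1))
  if (!all(ok)) fw_stop("profiles have differing size ranges",
                        "fragwave_parameter_error")
  m <- do.call(rbind, lapply(profiles, function(p) p$values))
  colnames(m) <- as.character(profiles[[1]]$sizes)
  rownames(m) <- vapply(profiles, function(p) p$source_id %||% "",
                        character(1))
  m
}

#' Write / read a profile as a two-column TSV (size, probability)
#'
#' @param profile An [fs_profile].
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  data.table::fwrite(data.table::data.table(size = profile$sizes,
                                            probability = profile$values),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param source_id Identifier for the re-read profile.
#' @export
read_profile_tsv <- function(path, source_id = NULL) {
  d <- data.table::fread(path, sep = "\t")
  fs_profile(d$probability, size_range = range(d$size), source_id = source_id)
}
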