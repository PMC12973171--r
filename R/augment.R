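#' Build disjoint fragment subsamples for one patient
#'
#' The data-augmentation core: genomic bins are drawn uniformly at
#' random without replacement from the patient's not-yet-used bin pool;
#' for each subsample, whole bins accumulate until the in-range fragment
#' count reaches `min_fragments`, and the subsample PMF is computed from
#' the pooled histogram. Because subsamples are built from disjoint sets
#' of whole bins, no fragment is ever reused between subsamples of the
#' same patient.
#'
#' @param counts A [binned_counts] object for one sample.
#' @param n_subsamples Odd number of subsamples to build (3 or 5 in
#'   practice).
#' @param min_fragments Minimum in-range fragments per subsample
#'   (default 1e6, the smoothness floor used with real WGS data;
#'   synthetic runs scale this down together with the generated
#'   coverage).
#' @param size_range PMF size range, default `c(51, 250)`.
#' @param seed Integer seed; the augmentation is bit-reproducible given
#'   the seed.
#' @param label Optional class label stored with the set.
#' @param patient_id Patient identifier (defaults to the sample id).
#' @return Object of class `subsample_set`: `patient_id`, `label`,
#'   `profiles` (list of [fs_profile]), `provenance` (per-subsample bin
#'   ids, fragment totals, seed), `n_subsamples`.
#' @section Errors: an even `n_subsamples` raises a parameter error;
#'   insufficient coverage raises an error of class
#'   `fragwave_coverage_error` whose message names the achievable
#'   maximum number of subsamples.
#' @export
make_subsamples <- function(counts, n_subsamples, min_fragments = 1e6,
                            size_range = c(51, 250), seed = 1L,
                            label = NULL, patient_id = NULL) {
  stopifnot(inherits(counts, "binned_counts"))
  assert_scalar_number(n_subsamples, "n_subsamples", 1)
  if (!is_odd(as.integer(n_subsamples))) {
    fw_stop("`n_subsamples` must be odd so that majority votes cannot tie",
            "fragwave_parameter_error")
  }
  assert_scalar_number(min_fragments, "min_fragments", 1)
  assert_range(size_range, "size_range")
  patient_id <- patient_id %||% counts$sample_id

  sizes <- as.integer(colnames(counts$counts))
  in_range <- sizes >= size_range[1] & sizes <= size_range[2]
  bin_totals <- rowSums(counts$counts[, in_range, drop = FALSE])
  total <- sum(bin_totals)
  max_n <- floor(total / min_fragments)
  if (max_n < n_subsamples) {
    fw_stop(sprintf(paste0("insufficient coverage for %d subsamples of >= %s ",
                           "fragments (total in-range %s); at most %d ",
                           "subsample(s) achievable"),
                    n_subsamples, format(min_fragments, big.mark = ","),
                    format(total, big.mark = ","), max_n),
            "fragwave_coverage_error")
  }

  n_bins <- nrow(counts$counts)
  result <- withr::with_seed(as.integer(seed), {
    pool <- sample.int(n_bins)  # uniform order; consumed left to right
    ptr <- 1L
    subs <- vector("list", n_subsamples)
    for (s in seq_len(n_subsamples)) {
      used <- integer(0)
      got <- 0
      while (got < min_fragments) {
        if (ptr > n_bins) {
          fw_stop(sprintf(paste0("bin pool exhausted after %d complete ",
                                 "subsample(s); at most %d achievable at ",
                                 "min_fragments = %s"),
                          s - 1L, s - 1L,
                          format(min_fragments, big.mark = ",")),
                  "fragwave_coverage_error")
        }
        b <- pool[ptr]
        ptr <- ptr + 1L
        used <- c(used, b)
        got <- got + bin_totals[b]
      }
      subs[[s]] <- list(rows = used, fragments = got)
    }
    subs
  })

  bin_ids <- as.integer(rownames(counts$counts))
  profiles <- vector("list", n_subsamples)
  provenance <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    rows <- result[[s]]$rows
    hist <- colSums(counts$counts[rows, , drop = FALSE])
    sid <- sprintf("%s_sub%d", patient_id, s)
    profiles[[s]] <- compute_pmf(hist, size_range, source_id = sid)
    provenance[[s]] <- list(subsample_id = sid,
                            bin_ids = sort(bin_ids[rows]),
                            fragments = result[[s]]$fragments,
                            seed = as.integer(seed))
  }
  structure(list(patient_id = patient_id, label = label,
                 profiles = profiles, provenance = provenance,
                 n_subsamples = as.integer(n_subsamples)),
            class = "subsample_set")
}

#' @export
print.subsample_set <- function(x, ...) {
  cat(sprintf("<subsample_set> patient %s (%s): %d subsamples\n",
              x$patient_id, x$label %||% "?", x$n_subsamples))
  invisible(x)
}

#' Plan per-patient subsample counts for a cohort
#'
#' Cancer patients get 5 subsamples (3 where coverage only permits 3);
#' healthy patients get a deterministic mix of 3s and 5s, assigned in
#' sorted patient-id order, chosen so the augmented class totals are as
#' close to balance as the arithmetic allows. Counts are always odd so
#' majority votes cannot tie; a patient whose coverage cannot support
#' the target degrades to the largest odd achievable count.
#'
#' @param cohort A `fragment_cohort`, or a list with elements `counts`
#'   (named list of [binned_counts]) and `metadata`.
#' @param cancer_target Subsamples per cancer patient (default 5).
#' @param healthy_choices Candidate counts for healthy patients
#'   (default `c(3, 5)`).
#' @param min_fragments Minimum in-range fragments per subsample.
#' @param size_range PMF size range used for coverage accounting.
#' @return Named integer vector: subsample count per patient id.
#' @export
plan_cohort_subsampling <- function(cohort, cancer_target = 5,
                                    healthy_choices = c(3, 5),
                                    min_fragments = 1e6,
                                    size_range = c(51, 250)) {
  md <- cohort$metadata
  counts <- cohort$counts
  stopifnot(all(md$sample_id %in% names(counts)))
  cap <- vapply(md$sample_id, function(sid) {
    x <- counts[[sid]]
    sizes <- as.integer(colnames(x$counts))
    in_range <- sizes >= size_range[1] & sizes <= size_range[2]
    floor(sum(x$counts[, in_range]) / min_fragments)
  }, numeric(1))
  largest_odd <- function(k) ifelse(k %% 2 == 0, pmax(k - 1, 0), k)

  plan <- setNames(integer(nrow(md)), md$patient_id)
  is_cancer <- md$class == "cancer"
  plan[is_cancer] <- pmin(cancer_target, largest_odd(cap[is_cancer]))
  plan[is_cancer] <- pmax(plan[is_cancer], 0L)

  lo <- min(healthy_choices); hi <- max(healthy_choices)
  n_h <- sum(!is_cancer)
  cancer_total <- sum(plan[is_cancer])
  # number of healthy patients bumped from lo to hi for near-balance
  k_hi <- if (n_h > 0 && hi > lo) {
    max(0, min(n_h, round((cancer_total - lo * n_h) / (hi - lo))))
  } else 0
  h_ids <- sort(md$patient_id[!is_cancer])
  h_plan <- setNames(rep(as.integer(lo), n_h), h_ids)
  if (k_hi > 0) h_plan[seq_len(k_hi)] <- as.integer(hi)
  h_plan <- pmin(h_plan, largest_odd(cap[match(h_ids, md$patient_id)]))
  plan[h_ids] <- pmax(h_plan, 0L)
  plan
}

#' Augment a whole cohort into labelled subsample profiles
#'
#' Applies [make_subsamples()] to every patient under a per-patient
#' plan, collecting all profiles and their labels into a design table.
#'
#' @param cohort A `fragment_cohort`.
#' @param plan Named vector from [plan_cohort_subsampling()], or a
#'   single odd count applied to all patients.
#' @param min_fragments,size_range Passed to [make_subsamples()].
#' @param seed Base augmentation seed; patient i uses `seed + i`.
#' @return List of class `augmented_set`: `profiles` (list of
#'   [fs_profile]), `info` (data.frame: subsample_id, patient_id, class,
#'   flowcell), `sets` (the per-patient `subsample_set`s).
#' @export
augment_cohort <- function(cohort, plan, min_fragments = 1e6,
                           size_range = c(51, 250), seed = 1L) {
  md <- cohort$metadata
  if (length(plan) == 1L && is.null(names(plan))) {
    plan <- setNames(rep(as.integer(plan), nrow(md)), md$patient_id)
  }
  sets <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    pid <- md$patient_id[i]
    sets[[i]] <- make_subsamples(cohort$counts[[md$sample_id[i]]],
                                 n_subsamples = plan[[pid]],
                                 min_fragments = min_fragments,
                                 size_range = size_range,
                                 seed = as.integer(seed) + i,
                                 label = md$class[i], patient_id = pid)
  }
  names(sets) <- md$patient_id
  profiles <- unlist(lapply(sets, function(s) s$profiles),
                     recursive = FALSE, use.names = FALSE)
  info <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(subsample_id = vapply(s$provenance, `[[`, "",
                                     "subsample_id"),
               patient_id = s$patient_id, class = s$label,
               flowcell = if ("flowcell" %in% names(md)) md$flowcell[i]
                          else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(info) <- NULL
  structure(list(profiles = profiles, info = info, sets = sets),
            class = "augmented_set")
}

#' Write an augmented design matrix as TSV
#'
#' One row per subsample: `subsample_id`, `patient_id`, `class`,
#' `flowcell`, then the PMF columns.
#'
#' @param augmented An `augmented_set` from [augment_cohort()].
#' @param path Output TSV path.
#' @export
write_design_matrix <- function(augmented, path) {
  m <- profiles_to_matrix(augmented$profiles)
  d <- cbind(augmented$info, as.data.frame(m, check.names = FALSE))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
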