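#' Specification of a synthetic cfDNA cohort
#'
#' Describes the structure of a generated cohort: numbers of healthy and
#' cancer patients (one pre-treatment sample per patient), the number of
#' 1-Mb bins covered per sample, the mean fragment yield per bin with a
#' negative-binomial dispersion mimicking coverage variation between
#' flowcells, and a round-robin flowcell labelling scheme.
#'
#' @param n_healthy,n_cancer Patient counts per class (positive).
#' @param bins_per_sample Number of genomic bins covered per sample.
#' @param fragments_per_bin Mean fragment count per bin.
#' @param dispersion Negative-binomial size parameter of the per-bin
#'   fragment counts (larger = less over-dispersed).
#' @param n_flowcells Number of flowcell labels cycled over patients.
#' @param bin_size Genomic bin width in bp (default 1e6).
#' @param size_range Fragment-size support of the class PMFs (bp).
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy, n_cancer, bins_per_sample = 50,
                        fragments_per_bin = 4000, dispersion = 8,
                        n_flowcells = 2, bin_size = 1e6,
                        size_range = c(51, 250), seed = 1L) {
  assert_scalar_number(n_healthy, "n_healthy", 1)
  assert_scalar_number(n_cancer, "n_cancer", 1)
  assert_scalar_number(bins_per_sample, "bins_per_sample", 1)
  assert_scalar_number(fragments_per_bin, "fragments_per_bin", 1)
  assert_scalar_number(dispersion, "dispersion", 1e-6)
  assert_scalar_number(n_flowcells, "n_flowcells", 1)
  assert_range(size_range, "size_range")
  assert_scalar_number(seed, "seed")
  structure(list(n_healthy = as.integer(n_healthy),
                 n_cancer = as.integer(n_cancer),
                 bins_per_sample = as.integer(bins_per_sample),
                 fragments_per_bin = fragments_per_bin,
                 dispersion = dispersion,
                 n_flowcells = as.integer(n_flowcells),
                 bin_size = bin_size,
                 size_range = as.integer(size_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cfDNA cohort
#'
#' Draws, for every patient, per-bin fragment totals from a negative
#' binomial (mean `fragments_per_bin`, size `dispersion`) and per-bin
#' size histograms multinomially from the patient's class PMF
#' ([make_class_pmf()]). The output has the same shape as real ingested
#' data: one [binned_counts] per sample plus a metadata table with
#' `patient_id`, `sample_id`, `class`, `flowcell`.
#'
#' @param spec A [cohort_spec()].
#' @param healthy_params,cancer_params Class fragment-size models:
#'   either [profile_model_params()] objects (evaluated with
#'   [make_class_pmf()] on the spec's size range) or explicit
#'   [fs_profile] PMFs on that range. The cancer default carries
#'   `tumor_fraction = 0.3`.
#' @return Object of class `fragment_cohort`: list with `counts` (named
#'   list of [binned_counts]), `metadata` (data.frame), `bins`
#'   (`genome_bins`), and the generating `spec`/parameters.
#' @examples
#' co <- generate_cohort(cohort_spec(3, 3, bins_per_sample = 5,
#'                                   fragments_per_bin = 500, seed = 42))
#' table(co$metadata$class)
#' @export
generate_cohort <- function(spec,
                            healthy_params = profile_model_params(),
                            cancer_params = profile_model_params(tumor_fraction = 0.3)) {
  if (!inherits(spec, "cohort_spec")) {
    fw_stop("`spec` must be created by cohort_spec()",
            "fragwave_parameter_error")
  }
  bins <- build_bins(data.frame(chrom = "chrS",
                                length = spec$bins_per_sample * spec$bin_size),
                     bin_size = spec$bin_size)
  as_class_pmf <- function(p) {
    if (inherits(p, "fs_profile")) {
      if (!all(p$size_range == spec$size_range)) {
        fw_stop("explicit class PMF must live on the spec's size range",
                "fragwave_parameter_error")
      }
      p
    } else {
      make_class_pmf(p, spec$size_range)
    }
  }
  pmf_h <- as_class_pmf(healthy_params)
  pmf_c <- as_class_pmf(cancer_params)
  n <- spec$n_healthy + spec$n_cancer
  metadata <- data.frame(
    patient_id = c(sprintf("H%03d", seq_len(spec$n_healthy)),
                   sprintf("C%03d", seq_len(spec$n_cancer))),
    class = rep(c("healthy", "cancer"), c(spec$n_healthy, spec$n_cancer)),
    stringsAsFactors = FALSE
  )
  metadata$sample_id <- metadata$patient_id
  # round-robin within class keeps flowcell strata balanced across classes
  fc_idx <- c(seq_len(spec$n_healthy), seq_len(spec$n_cancer))
  metadata$flowcell <- sprintf("FC%d", (fc_idx - 1L) %% spec$n_flowcells + 1L)

  counts <- withr::with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      pmf <- if (metadata$class[i] == "cancer") pmf_c else pmf_h
      bin_totals <- rnbinom(nrow(bins), mu = spec$fragments_per_bin,
                            size = spec$dispersion)
      m <- matrix(0L, nrow = nrow(bins), ncol = length(pmf$sizes),
                  dimnames = list(as.character(bins$bin_id),
                                  as.character(pmf$sizes)))
      pos <- which(bin_totals > 0)
      if (length(pos)) {
        for (k in seq_along(pos)) {
          m[pos[k], ] <- as.integer(rmultinom(1, bin_totals[pos[k]],
                                              pmf$values))
        }
      }
      binned_counts(metadata$sample_id[i], m,
                    size_window = spec$size_range, bins = bins)
    })
  })
  names(counts) <- metadata$sample_id
  structure(list(counts = counts, metadata = metadata, bins = bins,
                 spec = spec, healthy_params = healthy_params,
                 cancer_params = cancer_params),
            class = "fragment_cohort")
}

#' @export
print.fragment_cohort <- function(x, ...) {
  cat(sprintf("<fragment_cohort> %d healthy + %d cancer patients, %d bins/sample\n",
              x$spec$n_healthy, x$spec$n_cancer, x$spec$bins_per_sample))
  invisible(x)
}

#' Write a cohort (or one sample) as a per-fragment TSV table
#'
#' Expands the per-bin histograms into one row per fragment with columns
#' `sample_id`, `chrom`, `start` (0-based, deterministically spread
#' within the bin), `fragment_length`. Round-trips through
#' [ingest_table()].
#'
#' @param cohort A `fragment_cohort` or a single [binned_counts].
#' @param path Output TSV path.
#' @export
write_fragment_table <- function(cohort, path) {
  counts <- if (inherits(cohort, "fragment_cohort")) cohort$counts
            else list(cohort)
  rows <- lapply(counts, function(x) {
    if (is.null(x$bins)) fw_stop("counts carry no bin definitions",
                                 "fragwave_input_error")
    nz <- which(x$counts > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    bid <- as.integer(rownames(x$counts)[nz[, 1]])
    size <- as.integer(colnames(x$counts)[nz[, 2]])
    cnt <- x$counts[nz]
    b <- x$bins[match(bid, x$bins$bin_id), ]
    reps <- rep(seq_along(cnt), cnt)
    width <- b$end - b$start
    # spread starts deterministically inside the bin
    offset <- unlist(lapply(cnt, function(k) seq_len(k) - 1L),
                     use.names = FALSE)
    data.table::data.table(
      sample_id = x$sample_id,
      chrom = b$chrom[reps],
      start = b$start[reps] + (offset * 37L) %% pmax(width[reps], 1),
      fragment_length = size[reps])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' Emit a minimal paired-end SAM/BAM for one synthetic sample
#'
#' Writes properly paired alignments (flags 99/147, MAPQ 60, TLEN set to
#' the fragment length) so that the BAM ingest path can be exercised
#' end-to-end on synthetic data. Requires fragment length >= read
#' length.
#'
#' @param sample A [binned_counts] with bin definitions attached.
#' @param path Output path; `.sam` written directly, `.bam` converted
#'   and indexed via Rsamtools.
#' @param read_length Read length used for the alignment records.
#' @return The path to the written SAM or BAM.
#' @export
write_sample_bam <- function(sample, path, read_length = 25) {
  stopifnot(inherits(sample, "binned_counts"), !is.null(sample$bins))
  bins <- sample$bins
  chrom_len <- tapply(bins$end, bins$chrom, max)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                   as.integer(chrom_len)))
  nz <- which(sample$counts > 0, arr.ind = TRUE)
  bid <- as.integer(rownames(sample$counts)[nz[, 1]])
  size <- as.integer(colnames(sample$counts)[nz[, 2]])
  cnt <- sample$counts[nz]
  b <- bins[match(bid, bins$bin_id), ]
  reps <- rep(seq_along(cnt), cnt)
  offset <- unlist(lapply(cnt, function(k) seq_len(k) - 1L),
                   use.names = FALSE)
  width <- b$end - b$start
  start0 <- b$start[reps] + (offset * 37L) %% pmax(width[reps], 1)
  len <- size[reps]
  if (any(len < read_length)) {
    fw_stop("fragment lengths below read_length; lower `read_length`",
            "fragwave_parameter_error")
  }
  ord <- order(b$chrom[reps], start0)
  start0 <- start0[ord]; len <- len[ord]; ch <- b$chrom[reps][ord]
  qname <- sprintf("frag%06d", seq_along(start0))
  pos1 <- start0 + 1L
  mpos1 <- start0 + len - read_length + 1L
  seqs <- strrep("A", read_length)
  cig <- sprintf("%dM", read_length)
  r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                qname, ch, pos1, cig, mpos1, len, seqs)
  r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                qname, ch, mpos1, cig, pos1, -len, seqs)
  recs <- as.vector(rbind(r1, r2))
  if (grepl("\\.bam$", path)) {
    sam <- sub("\\.bam$", ".sam", path)
    writeLines(c(hdr, recs), sam)
    out <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    out
  } else {
    writeLines(c(hdr, recs), path)
    path
  }
}
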