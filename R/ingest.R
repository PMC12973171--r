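#' Per-bin fragment-size histograms for one sample
#'
#' A `binned_counts` object stores, for one sample, an integer histogram
#' of fragment sizes per genomic bin over a fixed storage window
#' (default 1-1000 bp; WGS resolves cfDNA fragments up to about 1 kb).
#' PMF windowing to the analysis range happens downstream in
#' [compute_pmf()].
#'
#' @param sample_id Sample identifier.
#' @param counts Integer matrix, rows = bins (rownames = `bin_id`),
#'   columns = fragment sizes (colnames = size in bp).
#' @param size_window Inclusive stored size interval (bp).
#' @param bins Optional `genome_bins` the rows refer to.
#' @return Object of class `binned_counts` with fields `sample_id`,
#'   `counts`, `size_window`, `bins`, `total_fragments`.
#' @export
binned_counts <- function(sample_id, counts, size_window = c(1, 1000),
                          bins = NULL) {
  assert_range(size_window, "size_window")
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    fw_stop("counts must be non-negative integers", "fragwave_input_error")
  }
  if (is.null(colnames(counts))) {
    fw_stop("count matrix must have fragment sizes as column names",
            "fragwave_input_error")
  }
  structure(list(sample_id = sample_id, counts = counts,
                 size_window = as.integer(size_window), bins = bins,
                 total_fragments = sum(counts)),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> sample %s: %d bins, %s fragments, sizes %d-%d bp\n",
              x$sample_id, nrow(x$counts),
              format(x$total_fragments, big.mark = ","),
              x$size_window[1], x$size_window[2]))
  invisible(x)
}

empty_count_matrix <- function(bins, size_window) {
  sizes <- seq(size_window[1], size_window[2])
  m <- matrix(0L, nrow = nrow(bins), ncol = length(sizes),
              dimnames = list(as.character(bins$bin_id),
                              as.character(sizes)))
  m
}

tabulate_fragments <- function(bin_id, size, bins, size_window) {
  m <- empty_count_matrix(bins, size_window)
  keep <- !is.na(bin_id) & size >= size_window[1] & size <= size_window[2]
  if (any(keep)) {
    ri <- match(bin_id[keep], bins$bin_id)
    ci <- size[keep] - size_window[1] + 1L
    tab <- table(factor(ri, levels = seq_len(nrow(bins))),
                 factor(ci, levels = seq_len(ncol(m))))
    m[] <- m + as.integer(tab)
  }
  attr(m, "n_dropped") <- sum(!keep)
  m
}

#' Extract binned fragment-size counts from a paired-end BAM
#'
#' Each properly paired, primary, non-duplicate pair with mapping
#' quality at least `min_mapq` on its leftmost read contributes one
#' fragment: size = absolute template length (TLEN), assigned to the bin
#' containing the leftmost mapped coordinate (0-based). Each pair is
#' counted exactly once by keeping only records with positive TLEN.
#'
#' @param path Path to a BAM file.
#' @param bins A `genome_bins` object ([build_bins()]).
#' @param min_mapq Minimum mapping quality of the leftmost read
#'   (default 20).
#' @param size_window Stored fragment-size window, default `c(1, 1000)`.
#' @return A [binned_counts] object (`sample_id` = file base name).
#' @export
ingest_bam <- function(path, bins, min_mapq = 20, size_window = c(1, 1000)) {
  if (!file.exists(path)) {
    fw_stop(sprintf("BAM file not found: %s", path), "fragwave_input_error")
  }
  stopifnot(inherits(bins, "genome_bins"))
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "mapq", "isize"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(rec$pos) == 0) {
    warning("no properly paired records in ", path,
            "; returning empty counts")
    m <- empty_count_matrix(bins, size_window)
    return(binned_counts(basename_noext(path), m, size_window, bins))
  }
  keep <- !is.na(rec$isize) & rec$isize > 0 &
    (!is.na(rec$mapq) & rec$mapq >= min_mapq)
  chrom <- as.character(rec$rname[keep])
  start0 <- rec$pos[keep] - 1L          # BAM pos is 1-based
  size <- abs(rec$isize[keep])
  bid <- assign_bins(bins, chrom, start0)
  m <- tabulate_fragments(bid, size, bins, size_window)
  attr(m, "n_dropped") <- NULL
  binned_counts(basename_noext(path), m, size_window, bins)
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Extract binned fragment-size counts from a fragment table
#'
#' Reads a TSV with columns `sample_id`, `chrom`, `start` (0-based) and
#' `fragment_length`, and aggregates it exactly as [ingest_bam()] does.
#' Rows with sizes outside the storage window are dropped; the number of
#' dropped rows is reported via a message and an `n_dropped` attribute.
#'
#' @param path Path to the TSV fragment table.
#' @param bins A `genome_bins` object.
#' @param size_window Stored fragment-size window, default `c(1, 1000)`.
#' @return A named list of [binned_counts], one per `sample_id` in the
#'   table (order of first appearance).
#' @export
ingest_table <- function(path, bins, size_window = c(1, 1000)) {
  if (!file.exists(path)) {
    fw_stop(sprintf("fragment table not found: %s", path),
            "fragwave_input_error")
  }
  stopifnot(inherits(bins, "genome_bins"))
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  if (nrow(d) == 0) {
    warning("empty fragment table: ", path)
    return(structure(list(), names = character(0)))
  }
  need <- c("sample_id", "chrom", "start", "fragment_length")
  if (!all(need %in% names(d))) {
    fw_stop(sprintf("fragment table must have columns: %s",
                    paste(need, collapse = ", ")),
            "fragwave_input_error")
  }
  start <- suppressWarnings(as.numeric(d$start))
  flen <- suppressWarnings(as.numeric(d$fragment_length))
  bad <- which(is.na(start) | is.na(flen) | flen <= 0 | start < 0)
  if (length(bad)) {
    fw_stop(sprintf("malformed rows in %s at line(s): %s", path,
                    paste(head(bad + 1L, 10), collapse = ", ")),
            "fragwave_input_error")
  }
  out <- list()
  for (sid in unique(d$sample_id)) {
    sel <- d$sample_id == sid
    bid <- assign_bins(bins, d$chrom[sel], start[sel])
    m <- tabulate_fragments(bid, as.integer(flen[sel]), bins, size_window)
    nd <- attr(m, "n_dropped")
    attr(m, "n_dropped") <- NULL
    if (nd > 0) {
      message(sprintf("sample %s: dropped %d fragment(s) outside window [%d, %d] or bins",
                      sid, nd, size_window[1], size_window[2]))
    }
    bc <- binned_counts(sid, m, size_window, bins)
    attr(bc, "n_dropped") <- nd
    out[[sid]] <- bc
  }
  out
}

#' Write / read binned counts as a compact long-format TSV
#'
#' Columns `sample_id`, `bin_id`, `size`, `count`; zero cells omitted.
#'
#' @param counts A [binned_counts] object or list of them.
#' @param path File path.
#' @export
write_binned_counts <- function(counts, path) {
  if (inherits(counts, "binned_counts")) counts <- list(counts)
  rows <- lapply(counts, function(x) {
    nz <- which(x$counts > 0, arr.ind = TRUE)
    data.table::data.table(
      sample_id = x$sample_id,
      bin_id = as.integer(rownames(x$counts)[nz[, 1]]),
      size = as.integer(colnames(x$counts)[nz[, 2]]),
      count = x$counts[nz])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @rdname write_binned_counts
#' @param bins `genome_bins` the cached counts refer to.
#' @param size_window Stored size window of the cache.
#' @export
read_binned_counts <- function(path, bins, size_window = c(1, 1000)) {
  d <- data.table::fread(path, sep = "\t")
  out <- list()
  for (sid in unique(d$sample_id)) {
    s <- d[d$sample_id == sid]
    m <- empty_count_matrix(bins, size_window)
    ri <- match(s$bin_id, bins$bin_id)
    ci <- s$size - size_window[1] + 1L
    ok <- !is.na(ri) & ci >= 1 & ci <= ncol(m)
    m[cbind(ri[ok], ci[ok])] <- s$count[ok]
    out[[sid]] <- binned_counts(sid, m, size_window, bins)
  }
  out
}
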