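#' hg19 autosome lengths
#'
#' Chromosome lengths (bp) of the 22 human autosomes in the hg19/GRCh37
#' assembly, as a two-column data frame suitable for [build_bins()].
#'
#' @return `data.frame` with columns `chrom`, `length`.
#' @export
hg19_autosome_lengths <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
               171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
               135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
               90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
               48129895L, 51304566L),
    stringsAsFactors = FALSE
  )
}

#' Tile chromosomes into fixed-size non-overlapping bins
#'
#' Produces the deterministic tiling used to aggregate fragments: equal
#' intervals of `bin_size` bp (default 1 Mb), half-open `[start, end)` in
#' 0-based coordinates, with a possibly shorter terminal bin per
#' chromosome.
#'
#' @param chromosome_lengths `data.frame` with columns `chrom` and
#'   `length` (bp), e.g. [hg19_autosome_lengths()].
#' @param bin_size Bin width in bp (default 1e6).
#' @param chroms Optional subset of chromosomes to tile.
#' @return A `genome_bins` object: `data.frame` with columns `chrom`,
#'   `start`, `end`, `bin_id` (1-based integer) and attribute `bin_size`.
#' @examples
#' build_bins(data.frame(chrom = "chrS", length = 2.5e6))
#' @export
build_bins <- function(chromosome_lengths, bin_size = 1e6, chroms = NULL) {
  if (!is.data.frame(chromosome_lengths) || nrow(chromosome_lengths) == 0 ||
      !all(c("chrom", "length") %in% names(chromosome_lengths))) {
    fw_stop("`chromosome_lengths` must be a non-empty data.frame with columns chrom, length",
            "fragwave_input_error")
  }
  if (!is.null(chroms)) {
    chromosome_lengths <-
      chromosome_lengths[chromosome_lengths$chrom %in% chroms, , drop = FALSE]
    if (nrow(chromosome_lengths) == 0) {
      fw_stop("no chromosomes left after subsetting", "fragwave_input_error")
    }
  }
  assert_scalar_number(bin_size, "bin_size", 1)
  if (any(chromosome_lengths$length <= 0)) {
    fw_stop("chromosome lengths must be positive", "fragwave_input_error")
  }
  pieces <- lapply(seq_len(nrow(chromosome_lengths)), function(i) {
    len <- chromosome_lengths$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chromosome_lengths$chrom[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_id <- seq_len(nrow(bins))
  structure(bins, bin_size = bin_size, class = c("genome_bins", "data.frame"))
}

#' Assign fragment start coordinates to bins
#'
#' Total on qualifying input: every 0-based start inside a tiled
#' chromosome falls in exactly one half-open bin; starts on unknown
#' chromosomes or beyond the chromosome end get `NA`.
#'
#' @param bins A `genome_bins` object.
#' @param chrom Character vector of chromosome names.
#' @param start 0-based start coordinates.
#' @return Integer vector of `bin_id`s (NA where unassignable).
#' @export
assign_bins <- function(bins, chrom, start) {
  stopifnot(inherits(bins, "genome_bins"))
  out <- rep(NA_integer_, length(start))
  for (ch in unique(chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    sel <- which(chrom == ch)
    pos <- start[sel]
    idx <- findInterval(pos, b$start)
    ok <- idx >= 1 & pos >= 0 & pos < b$end[pmax(idx, 1L)]
    out[sel[ok]] <- b$bin_id[idx[ok]]
  }
  out
}

#' Write / read bin definitions as BED
#'
#' Plain 3+1-column BED (0-based half-open), `name` column carrying the
#' bin id.
#'
#' @param bins A `genome_bins` object.
#' @param path File path.
#' @export
write_bins_bed <- function(bins, path) {
  stopifnot(inherits(bins, "genome_bins"))
  data.table::fwrite(data.table::data.table(
    chrom = bins$chrom, start = as.integer(bins$start),
    end = as.integer(bins$end), name = paste0("bin_", bins$bin_id)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bins_bed
#' @param bin_size Bin size attribute to restore (default: modal width).
#' @export
read_bins_bed <- function(path, bin_size = NULL) {
  d <- data.table::fread(path, sep = "\t", header = FALSE)
  bins <- data.frame(chrom = as.character(d[[1]]), start = d[[2]],
                     end = d[[3]], stringsAsFactors = FALSE)
  bins$bin_id <- seq_len(nrow(bins))
  if (is.null(bin_size)) {
    w <- bins$end - bins$start
    bin_size <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  }
  structure(bins, bin_size = bin_size, class = c("genome_bins", "data.frame"))
}
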