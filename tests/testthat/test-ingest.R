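test_that("bin tiling follows half-open fixed-width arithmetic", {
  b <- build_bins(data.frame(chrom = "chr1", length = 2.5e6))
  expect_equal(b$start, c(0, 1e6, 2e6))
  expect_equal(b$end, c(1e6, 2e6, 2.5e6))

  b1 <- build_bins(data.frame(chrom = "chrX", length = 4e5))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$end, 4e5)

  expect_error(build_bins(data.frame()), class = "fragwave_input_error")
})

test_that("hg19 autosome bin count matches per-chromosome ceiling arithmetic", {
  lens <- hg19_autosome_lengths()
  oracle <- sum(ceiling(lens$length / 1e6))  # direct arithmetic
  expect_equal(nrow(build_bins(lens)), oracle)
})

test_that("bin assignment is total on covered coordinates and half-open at edges", {
  b <- build_bins(data.frame(chrom = c("chr1", "chr2"),
                             length = c(2.5e6, 1.2e6)))
  got <- assign_bins(b, c("chr1", "chr1", "chr1", "chr2", "chr2", "chr9"),
                     c(0, 999999, 1000000, 0, 1199999, 5))
  expect_equal(got, c(1L, 1L, 2L, 4L, 5L, NA))
  # beyond chromosome end -> NA
  expect_true(is.na(assign_bins(b, "chr2", 1.3e6)))
})

test_that("bins round-trip through BED", {
  b <- build_bins(data.frame(chrom = c("chrA", "chrB"),
                             length = c(3.2e6, 9e5)), bin_size = 1e6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bins_bed(b, path)
  b2 <- read_bins_bed(path)
  expect_equal(b2$chrom, b$chrom)
  expect_equal(b2$start, b$start)
  expect_equal(b2$end, b$end)
})

test_that("fragment tables are windowed, validated, and round-trip exactly", {
  bins <- build_bins(data.frame(chrom = "chrS", length = 2e6))
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("sample_id\tchrom\tstart\tfragment_length",
               "S1\tchrS\t100\t100",
               "S1\tchrS\t200\t300"), path)
  got <- suppressMessages(ingest_table(path, bins, size_window = c(51, 250)))
  expect_equal(got$S1$total_fragments, 1)
  expect_equal(attr(got$S1, "n_dropped"), 1)

  writeLines("sample_id\tchrom\tstart\tfragment_length", path)
  expect_warning(empty <- ingest_table(path, bins), "empty")
  expect_length(empty, 0)

  writeLines(c("sample_id\tchrom\tstart\tfragment_length",
               "S1\tchrS\t100\t166",
               "S1\tchrS\tnot_a_number\t166"), path)
  expect_error(ingest_table(path, bins), "line",
               class = "fragwave_input_error")

  # synthetic cohort -> table -> counts round trip
  co <- tiny_cohort(n_healthy = 2, n_cancer = 2, seed = 9,
                    bins_per_sample = 4, fragments_per_bin = 300)
  write_fragment_table(co, path)
  back <- ingest_table(path, co$bins, size_window = c(51, 250))
  for (sid in names(co$counts)) {
    expect_identical(unname(back[[sid]]$counts),
                     unname(co$counts[[sid]]$counts))
  }
})

test_that("counts caches round-trip through the long TSV format", {
  co <- tiny_cohort(n_healthy = 2, n_cancer = 1, seed = 5,
                    bins_per_sample = 3, fragments_per_bin = 200)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_binned_counts(co$counts, path)
  back <- read_binned_counts(path, co$bins, size_window = c(51, 250))
  for (sid in names(co$counts)) {
    expect_identical(unname(back[[sid]]$counts),
                     unname(co$counts[[sid]]$counts))
  }
})

make_sam <- function(path, records,
                     sq = "@SQ\tSN:chrS\tLN:2000000") {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, records), path)
}

pair_records <- function(qname, pos1, tlen, mapq = 60, rl = 25) {
  mpos <- pos1 + tlen - rl
  c(sprintf("%s\t99\tchrS\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*",
            qname, pos1, mapq, rl, mpos, tlen, strrep("A", rl)),
    sprintf("%s\t147\tchrS\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*",
            qname, mpos, mapq, rl, pos1, -tlen, strrep("A", rl)))
}

test_that("BAM ingest counts each proper pair once and honors the MAPQ filter", {
  bins <- build_bins(data.frame(chrom = "chrS", length = 2e6))
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- c(pair_records("f1", 101, 166), pair_records("f2", 501, 166),
            pair_records("f3", 901, 166),
            pair_records("low", 1201, 180, mapq = 5))
  make_sam(sam, recs)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)

  bc <- ingest_bam(bam, bins, min_mapq = 20)
  expect_equal(bc$total_fragments, 3)
  expect_equal(unname(bc$counts["1", "166"]), 3L)
  expect_equal(sum(bc$counts[, "180"]), 0L)

  # lowering the threshold admits the filtered pair
  bc2 <- ingest_bam(bam, bins, min_mapq = 0)
  expect_equal(bc2$total_fragments, 4)
})

test_that("a BAM without proper pairs yields empty counts with a warning", {
  bins <- build_bins(data.frame(chrom = "chrS", length = 2e6))
  sam <- withr::local_tempfile(fileext = ".sam")
  # flag 0: mapped, unpaired
  make_sam(sam, sprintf("u1\t0\tchrS\t100\t60\t25M\t*\t0\t0\t%s\t*",
                        strrep("A", 25)))
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  expect_warning(bc <- ingest_bam(bam, bins), "no properly paired")
  expect_equal(bc$total_fragments, 0)
})

test_that("BAM and table ingest agree, and synthetic BAM emission round-trips", {
  co <- tiny_cohort(n_healthy = 1, n_cancer = 1, seed = 21,
                    bins_per_sample = 3, fragments_per_bin = 400)
  s <- co$counts[[1]]
  bam <- file.path(withr::local_tempdir(), paste0(s$sample_id, ".bam"))
  write_sample_bam(s, bam)
  got <- ingest_bam(bam, co$bins, size_window = c(51, 250))
  expect_identical(unname(got$counts), unname(s$counts))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(s, tsv)
  via_table <- ingest_table(tsv, co$bins, size_window = c(51, 250))[[1]]
  expect_identical(unname(via_table$counts), unname(got$counts))
})
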