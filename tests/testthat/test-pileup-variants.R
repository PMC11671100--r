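# Phred 30 and 10 as quality characters
Q30 <- "?"
Q10 <- "+"

test_that("read extraction honours flags, whitelists and empty input", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- c(
    vapply(1:9, function(i) {
      sam_read(sprintf("r%d", i), 100L + i, "A", Q30,
               sprintf("BC%d", (i %% 3) + 1))
    }, character(1)),
    sam_read("rdup", 200L, "A", Q30, "BC1", flag = 1024L),   # duplicate
    sam_read("rsec", 201L, "A", Q30, "BC1", flag = 256L),    # secondary
    sam_read("rsup", 202L, "A", Q30, "BC1", flag = 2048L)    # supplementary
  )
  write_toy_sam(sam, recs)
  reads <- extract_mito_reads(sam)
  expect_equal(nrow(reads), 9L)                  # 12 records, 3 filtered
  expect_setequal(unique(reads$barcode), c("BC1", "BC2", "BC3"))

  wl <- extract_mito_reads(sam, valid_barcodes = c("BC1", "BC2"))
  expect_setequal(unique(wl$barcode), c("BC1", "BC2"))

  empty <- withr::local_tempfile(fileext = ".sam")
  write_toy_sam(empty, character(0))
  expect_equal(nrow(extract_mito_reads(empty)), 0L)
})

test_that("contig aliases are resolved and missing contigs are an error", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_toy_sam(sam, sam_read("r1", 5L, "ACGTA", strrep(Q30, 5), "BC1",
                              contig = "MT"), contig = "MT")
  reads <- extract_mito_reads(sam)
  expect_equal(nrow(reads), 5L)
  expect_equal(reads$pos, 5:9)
  expect_error(extract_mito_reads(sam, contig = "chr1"), "not found")
})

test_that("barcodes can be recovered from read names", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- sprintf("CELLA_%d\t0\tchrM\t%d\t60\t1M\t*\t0\t0\tA\t%s", 1:4, 10:13, Q30)
  write_toy_sam(sam, recs)
  expect_error(extract_mito_reads(sam), "no barcode_regex")
  reads <- extract_mito_reads(sam, barcode_regex = "^(CELL[A-Z]+)_")
  expect_equal(unique(reads$barcode), "CELLA")
})

test_that("pileup tallies bases, filters on quality and conserves counts", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # 10 reads over position 3107 (ref A): 8 x A, 2 x C
  recs <- c(
    vapply(1:8, function(i) sam_read(sprintf("a%d", i), 3107L, "A", Q30,
                                     sprintf("BC%d", (i %% 2) + 1)),
           character(1)),
    sam_read("c1", 3107L, "C", Q30, "BC1"),
    sam_read("c2", 3107L, "C", Q30, "BC2"),
    sam_read("lowq", 3107L, "G", Q10, "BC1")      # below threshold
  )
  write_toy_sam(sam, recs)
  reads <- extract_mito_reads(sam)
  ref <- rep("A", 16569)
  pl <- pileup(reads, ref, min_base_quality = 20)
  expect_equal(sum(pl$bulk[3107, ]), 10)           # low-qual base dropped
  expect_equal(unname(pl$bulk[3107, "C"]), 2)
  expect_equal(unname(pl$bulk[3107, "A"]), 8)
  # per-barcode counts sum to bulk at every covered position
  agg <- tapply(pl$percell$count,
                list(pl$percell$pos, pl$percell$base), sum)
  for (p in rownames(agg)) {
    for (b in colnames(agg)) {
      if (!is.na(agg[p, b])) {
        expect_equal(unname(agg[p, b]), unname(pl$bulk[as.integer(p), b]))
      }
    }
  }
  expect_error(pileup(reads, rep("A", 100)), "length")
})

test_that("empty read sets give an all-zero pileup", {
  empty <- structure(
    data.frame(barcode = character(0), pos = integer(0),
               base = character(0), qual = integer(0)),
    class = c("mito_reads", "data.frame"))
  pl <- pileup(empty, rep("A", 16569))
  expect_equal(sum(pl$bulk), 0)
  expect_equal(nrow(pl$percell), 0L)
})

# Fabricate a pileup object directly from bulk counts.
fake_pileup <- function(counts_by_pos, ref_base = "A") {
  bulk <- matrix(0L, 16569, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in names(counts_by_pos)) bulk[as.integer(p), ] <- counts_by_pos[[p]]
  structure(list(bulk = bulk,
                 percell = data.frame(),
                 reference = rep(ref_base, 16569),
                 min_base_quality = 20L),
            class = "mito_pileup")
}

test_that("variant calling applies the four predicates at their boundaries", {
  pl <- fake_pileup(list(
    "100" = c(6L, 2L, 0L, 0L),     # depth 8, alt C 2, VAF 0.25 -> called
    "200" = c(4L, 3L, 0L, 0L),     # depth 7 -> rejected (depth)
    "300" = c(1L, 199L, 0L, 0L),   # VAF 0.995 -> rejected (window)
    "400" = c(199L, 1L, 0L, 0L),   # alt reads 1 -> rejected (min_reads2)
    "500" = c(300L, 2L, 0L, 0L)    # VAF 0.0066 -> rejected (min_var_freq)
  ))
  v <- call_variants(pl)
  expect_equal(v$position, 100L)
  expect_equal(v$alt, "C")
  expect_equal(v$bulk_depth, 8L)
  expect_equal(v$bulk_alt_count, 2L)
  expect_equal(v$bulk_vaf, 0.25)
})

test_that("multi-allelic sites yield one record per alternative base", {
  pl <- fake_pileup(list("1000" = c(10L, 5L, 5L, 0L)))
  v <- call_variants(pl)
  expect_equal(nrow(v), 2L)
  expect_setequal(v$alt, c("C", "G"))
  expect_true(all(v$bulk_depth == 20L))
})

test_that("called set equals a brute-force predicate scan on random pileups", {
  for (s in 1:5) {
    counts <- withr::with_seed(s, {
      pos <- sample(16569, 40)
      lapply(stats::setNames(pos, pos), function(p) {
        as.integer(rmultinom(1, sample(c(0:12, 50, 200), 1),
                             prob = c(0.7, 0.1, 0.1, 0.1)))
      })
    })
    pl <- fake_pileup(counts)
    got <- call_variants(pl)
    # independent scan of the printed predicates
    expected <- character(0)
    for (p in names(counts)) {
      cnt <- counts[[p]]
      depth <- sum(cnt)
      for (b in 2:4) {       # ref is A
        vaf <- if (depth > 0) cnt[b] / depth else 0
        if (depth >= 8 && cnt[b] >= 2 && vaf >= 0.01 &&
            vaf > 0.01 && vaf < 0.99) {
          expected <- c(expected, paste(p, c("A", "C", "G", "T")[b]))
        }
      }
    }
    expect_setequal(paste(got$position, got$alt), expected)
  }
})

test_that("raising any calling threshold never adds variants", {
  counts <- withr::with_seed(9, {
    pos <- sample(16569, 60)
    lapply(stats::setNames(pos, pos), function(p) {
      as.integer(rmultinom(1, sample(0:40, 1), prob = c(0.6, 0.2, 0.1, 0.1)))
    })
  })
  pl <- fake_pileup(counts)
  base <- paste(call_variants(pl)$position, call_variants(pl)$alt)
  stricter <- list(
    call_variants(pl, min_depth = 12),
    call_variants(pl, min_reads2 = 5),
    call_variants(pl, min_var_freq = 0.1),
    call_variants(pl, vaf_window = c(0.05, 0.8))
  )
  for (v in stricter) {
    expect_true(all(paste(v$position, v$alt) %in% base))
  }
})

test_that("variant tables export to TSV and VCF", {
  pl <- fake_pileup(list("100" = c(6L, 2L, 0L, 0L)))
  v <- call_variants(pl)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v, tsv = tsv, vcf = vcf)
  expect_equal(read.delim(tsv)$position, 100L)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  expect_true(any(grepl("^chrM\t100\t.*DP=8;AF=0.25", lines)))
})
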