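test_that("cytosine report reader applies the coverage filter and preserves order", {
  # empty file
  p <- tempfile()
  writeLines(character(), p)
  expect_equal(nrow(read_cytosine_report(p)), 0L)

  # a site covered by exactly three reads is dropped at the default filter
  p <- write_report_fixture(rbind(
    report_row(pos = 10, n_meth = 2, n_unmeth = 1),
    report_row(pos = 20, n_meth = 2, n_unmeth = 2)))
  rec <- read_cytosine_report(p)
  expect_equal(rec$pos, 20L)
  expect_equal(rec$n_total, 4L)

  # order preserved, levels recomputed by hand
  p <- write_report_fixture(rbind(
    report_row(pos = 150, n_meth = 4, n_unmeth = 0),
    report_row(pos = 10, n_meth = 1, n_unmeth = 4),
    report_row(pos = 500, n_meth = 6, n_unmeth = 6)))
  rec <- read_cytosine_report(p)
  expect_equal(rec$pos, c(150L, 10L, 500L))
  expect_equal(rec$n_meth / rec$n_total, c(1, 0.2, 0.5))
})

test_that("malformed report rows are rejected with their line number", {
  rows <- rbind(
    report_row(pos = 10, n_meth = 2, n_unmeth = 3),
    report_row(pos = 20, n_meth = 5, n_unmeth = 1),
    report_row(pos = 30, n_meth = 9, n_unmeth = 1),
    report_row(pos = 40, n_meth = 3, n_unmeth = 2),
    report_row(pos = 50, n_meth = 0, n_unmeth = 8))
  bad <- rows
  bad[3, 4] <- "-9"                       # negative count on line 3
  expect_error(read_cytosine_report(write_report_fixture(bad)), "line 3")
  bad2 <- rows
  bad2[2, 3] <- "x"                       # bad strand on line 2
  expect_error(read_cytosine_report(write_report_fixture(bad2)), "line 2")
  # with all rows valid, every record survives at min_total = 4 and levels
  # match hand computation
  rec <- read_cytosine_report(write_report_fixture(rows))
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$n_meth / rec$n_total, c(0.4, 5 / 6, 0.9, 0.6, 0))
})

test_that("coverage filter is monotone in min_total", {
  set.seed(7)
  rows <- do.call(rbind, lapply(1:60, function(i) {
    tot <- sample(0:12, 1)
    met <- if (tot > 0) sample(0:tot, 1) else 0
    report_row(pos = i * 7, n_meth = met, n_unmeth = tot - met)
  }))
  p <- write_report_fixture(rows)
  n_at <- vapply(0:10, function(mt) nrow(read_cytosine_report(p, min_total = mt)),
                 integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("tile aggregation means site levels and honours min_sites", {
  rec <- data.frame(chrom = "chr1", pos = 55L, strand = "+", context = "CG",
                    n_meth = 5L, n_total = 10L)
  tm <- aggregate_tiles(rec, min_sites = 1L)
  expect_equal(unname(tm$levels[1, 1]), 0.5)
  expect_equal(tm$tiles$start, 0L)
  expect_equal(tm$tiles$end, 100L)

  rec2 <- data.frame(chrom = "chr1", pos = c(10L, 90L), strand = "+",
                     context = "CG", n_meth = c(4L, 0L), n_total = c(4L, 5L))
  tm2 <- aggregate_tiles(rec2, min_sites = 1L)
  expect_equal(unname(tm2$levels[1, 1]), 0.5)

  # 7 sites across 3 tiles; the single-site tile is missing at min_sites = 3
  rec3 <- data.frame(
    chrom = "chr1",
    pos = c(5L, 50L, 99L, 101L, 150L, 199L, 250L),
    strand = "+", context = "CG",
    n_meth = c(1L, 2L, 3L, 4L, 0L, 5L, 5L),
    n_total = c(4L, 4L, 4L, 8L, 4L, 5L, 10L))
  tm3 <- aggregate_tiles(rec3, min_sites = 3L)
  expect_equal(tm3$tiles$start, c(0L, 100L, 200L))
  expect_equal(unname(tm3$levels[, 1]),
               c(mean(c(0.25, 0.5, 0.75)), mean(c(0.5, 0, 1)), NA))
  # brute-force per-tile oracle agrees exactly on a random fixture
  set.seed(3)
  recr <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                     pos = sample(1:1000, 200, TRUE), strand = "+",
                     context = "CG", n_total = sample(4:20, 200, TRUE))
  recr$n_meth <- vapply(recr$n_total, function(t) sample(0:t, 1), integer(1))
  tmr <- aggregate_tiles(recr, min_sites = 3L)
  expect_equal(unname(tmr$levels[, 1]),
               unname(oracle_tile_means(recr)), tolerance = 0)
})

test_that("weighted aggregation pools reads instead of averaging sites", {
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                    context = "CG", n_meth = c(10L, 0L), n_total = c(10L, 90L))
  expect_equal(unname(aggregate_tiles(rec, min_sites = 1L)$levels[1, 1]), 0.5)
  expect_equal(unname(aggregate_tiles(rec, min_sites = 1L,
                                      weighted = TRUE)$levels[1, 1]), 0.1)
})

test_that("CHH never enters a tile matrix destined for inference", {
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                    context = c("CG", "CHH"),
                    n_meth = c(4L, 4L), n_total = c(4L, 4L))
  expect_error(aggregate_tiles(rec, context = "CHH"))
  tm <- aggregate_tiles(rec, context = "CG", min_sites = 1L)
  expect_equal(unname(tm$n_sites[1, 1]), 1L)
})

test_that("pseudo-reference substitutes exactly the homozygous-alt positions", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  no_snps <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        ind1 = integer())
  expect_equal(as.character(build_pseudo_reference(ref, no_snps, "ind1")[[1]]),
               "ACGTACGTAC")

  one <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "G",
                    ind1 = 2L, ind2 = 1L)
  expect_equal(as.character(build_pseudo_reference(ref, one, "ind1")[[1]]),
               "ACGTGCGTAC")
  # heterozygous individuals keep the reference base
  expect_equal(as.character(build_pseudo_reference(ref, one, "ind2")[[1]]),
               "ACGTACGTAC")
  # ref-allele mismatch is reported with its position
  mism <- data.frame(chrom = "chr1", pos = 5L, ref = "C", alt = "G", ind1 = 2L)
  expect_error(build_pseudo_reference(ref, mism, "ind1"), "5")

  # random 1-kb sequence + 20 SNPs, 12 homozygous-alt: position-wise diff
  set.seed(42)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  ref2 <- Biostrings::DNAStringSet(c(chrX = seq1))
  pos <- sort(sample(1000, 20))
  refb <- substring(seq1, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  geno <- c(rep(2L, 12), rep(c(0L, 1L, NA), length.out = 8))
  snps <- data.frame(chrom = "chrX", pos = pos, ref = refb, alt = unname(altb),
                     ind1 = sample(geno))
  out <- build_pseudo_reference(ref2, snps, "ind1")
  diff_pos <- which(strsplit(as.character(out[[1]]), "")[[1]] !=
                    strsplit(seq1, "")[[1]])
  expect_equal(length(diff_pos), 12L)
  expect_setequal(diff_pos, snps$pos[!is.na(snps$ind1) & snps$ind1 == 2L])
})

test_that("BED round-trips and rejects degenerate intervals", {
  p <- tempfile(fileext = ".bed")
  writeLines(character(), p)
  expect_equal(length(read_bed(p)), 0L)

  gr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(c(1, 501, 21), c(100, 600, 40)))
  gr$name <- c("a", "b", "c")
  gr$score <- c(1.5, 2, 3)
  write_bed(gr, p)
  back <- read_bed(p)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               c("chr1", "chr1", "chr2"))
  expect_equal(BiocGenerics::start(back), c(1L, 501L, 21L))
  expect_equal(BiocGenerics::end(back), c(100L, 600L, 40L))
  expect_equal(back$name, gr$name)
  expect_equal(back$score, gr$score)

  writeLines("chr1\t100\t100", p)
  expect_error(read_bed(p), "start >= end")
})

test_that("tile matrices round-trip through TSV", {
  tm <- tile_matrix(
    tiles = data.frame(chrom = c("chr1", "chr1"), start = c(0L, 300L),
                       end = c(100L, 400L)),
    levels = matrix(c(0.1, NA, 1, 0.55), 2, 2,
                    dimnames = list(NULL, c("s1", "s2"))),
    context = "CHG")
  p <- tempfile(fileext = ".tsv")
  write_tile_matrix(tm, p)
  back <- read_tile_matrix(p)
  expect_equal(back$tiles, tm$tiles)
  expect_equal(back$levels, tm$levels)
  expect_equal(back$context, "CHG")
})

test_that("tile matrix construction validates shape and ordering", {
  tiles <- data.frame(chrom = "chr1", start = c(100L, 0L), end = c(200L, 100L))
  expect_error(tile_matrix(tiles, matrix(0.5, 2, 1)), "sorted")
  tiles2 <- data.frame(chrom = "chr1", start = 0L, end = 0L)
  expect_error(tile_matrix(tiles2, matrix(0.5, 1, 1)), "start")
  tiles3 <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_error(tile_matrix(tiles3, matrix(1.5, 1, 1)), "0, 1")
})
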