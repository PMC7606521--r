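scored_windows <- function(starts, scores, width = 50, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, starts + width - 1))
  gr$score <- scores
  gr
}

test_that("outlier window merging keeps isolated peaks and fuses adjacent ones", {
  set.seed(1)
  base <- scored_windows(seq(1, 991 * 50, by = 50), rnorm(991))
  # an isolated extreme window is returned unmerged, at its own coordinates
  # (the 0.5% quantile rule also admits ~0.5% of the background windows)
  iso <- scored_windows(991 * 50 + 1, 100)
  out <- merge_outlier_windows(c(base, iso))
  hit <- out[out$score == 100]
  expect_equal(length(hit), 1L)
  expect_equal(BiocGenerics::start(hit), 991 * 50 + 1)
  expect_equal(BiocGenerics::width(hit), 50L)

  # two book-ended extreme windows merge into one region with the max score
  two <- scored_windows(c(1e5 + 1, 1e5 + 51), c(90, 95))
  out2 <- merge_outlier_windows(c(base, two))
  hit2 <- out2[out2$score == 95]
  expect_equal(length(hit2), 1L)
  expect_equal(BiocGenerics::start(hit2), 1e5 + 1)
  expect_equal(BiocGenerics::end(hit2), 1e5 + 100)

  expect_warning(
    empty <- merge_outlier_windows(scored_windows(c(1, 51), c(1, 1))),
    "identical")
  expect_equal(length(empty), 0L)
})

test_that("window merging matches a brute-force reference on planted clusters", {
  set.seed(33)
  n <- 1000
  starts <- seq(1, by = 50, length.out = n)
  scores <- rnorm(n)
  planted <- list(c(50, 51), c(200, 201, 202), 400, c(600, 601), 700,
                  c(850, 851), 999)
  for (cl in planted) scores[cl] <- 10 + runif(length(cl))
  w <- scored_windows(starts, scores)
  out <- merge_outlier_windows(w, tail_frac = 0.10, outlier_frac = 0.005)

  # independent reference: explicit scan over sorted tail windows
  thr_tail <- sort(scores)[ceiling(0.9 * n)]           # approx upper decile
  thr_tail <- stats::quantile(scores, 0.9, names = FALSE)
  thr_out <- stats::quantile(scores, 0.995, names = FALSE)
  idx <- which(scores >= thr_tail)
  regions <- list()
  cur <- c(starts[idx[1]], starts[idx[1]] + 49, scores[idx[1]])
  for (i in idx[-1]) {
    if (starts[i] <= cur[2] + 1) {
      cur[2] <- starts[i] + 49
      cur[3] <- max(cur[3], scores[i])
    } else {
      regions[[length(regions) + 1]] <- cur
      cur <- c(starts[i], starts[i] + 49, scores[i])
    }
  }
  regions[[length(regions) + 1]] <- cur
  ref <- do.call(rbind, regions)
  ref <- ref[ref[, 3] >= thr_out, , drop = FALSE]
  expect_equal(BiocGenerics::start(out), as.integer(ref[, 1]))
  expect_equal(BiocGenerics::end(out), as.integer(ref[, 2]))
  expect_equal(out$score, ref[, 3])
})

test_that("self-overlap attains the minimum permutation p-value", {
  universe <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  set.seed(5)
  starts <- sample(seq(1, 1e6 - 200, by = 500), 25)
  query <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 99))
  res <- overlap_permutation_test(query, query, universe, n_perm = 999,
                                  seed = 8)
  expect_equal(res$observed, 25L)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$enrichment, 1)
  # identical seed replays the identical permutation stream
  res2 <- overlap_permutation_test(query, query, universe, n_perm = 999,
                                   seed = 8)
  expect_identical(res$perm, res2$perm)
  # an interval longer than every universe segment cannot be placed
  long_q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e6))
  expect_error(overlap_permutation_test(long_q, query, universe, 9, 1),
               "longer than every")
})

test_that("perfect-LD SNPs reach the minimum p and the >=3 rule gates the call", {
  set.seed(6)
  states <- sample(0:2, 24, TRUE)
  snps_perfect <- rbind(states, states, states)
  res <- dmr_snp_ld_test(states, snps_perfect, n_perm = 999, seed = 3)
  expect_equal(res$p_values, rep(1 / 1000, 3))
  expect_true(res$in_ld)

  # only two significant SNPs: not in LD despite perfect correlation
  res2 <- dmr_snp_ld_test(states, snps_perfect[1:2, , drop = FALSE],
                          n_perm = 999, seed = 3)
  expect_equal(res2$p_values, rep(1 / 1000, 2))
  expect_false(res2$in_ld)

  # monomorphic SNP carries no information
  res3 <- dmr_snp_ld_test(states, rbind(rep(1, 24)), n_perm = 99, seed = 4)
  expect_equal(res3$p_values, 1)
  expect_false(res3$in_ld)
  # monomorphic state vector: every SNP uninformative
  res4 <- dmr_snp_ld_test(rep(2, 24), snps_perfect, n_perm = 99, seed = 4)
  expect_equal(res4$p_values, rep(1, 3))

  # permutations are shared across SNPs: duplicated rows get identical p
  set.seed(7)
  g <- sample(0:2, 24, TRUE)
  res5 <- dmr_snp_ld_test(states, rbind(g, g), n_perm = 199, seed = 5)
  expect_equal(res5$p_values[1], res5$p_values[2])
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- sprintf("g%02d", 1:20)
  candidates <- universe[1:5]
  hits <- c(universe[c(1, 2, 3)], universe[10])
  p <- candidate_enrichment(hits, candidates, universe)
  draws <- utils::combn(20, 4)
  overlap <- colSums(draws <= 5)
  expect_equal(p, mean(overlap >= 3))

  # zero overlap: the upper tail includes the 0 term, so p is exactly 1
  expect_equal(candidate_enrichment(universe[16:18], candidates, universe), 1)
  expect_equal(candidate_enrichment(character(0), candidates, universe), 1)
  expect_equal(candidate_enrichment(universe, universe, universe), 1)
  expect_error(candidate_enrichment("a", "a", character(0)), "universe")
})

test_that("null overlap permutations centre the enrichment ratio at one", {
  set.seed(20)
  universe <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5))
  t_starts <- seq(1, 1e5 - 500, by = 2000)            # ~20% target coverage
  target <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(t_starts, t_starts + 399))
  ratios <- vapply(1:40, function(r) {
    q_starts <- sample(seq(1, 1e5 - 100), 30)
    query <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(q_starts, q_starts + 99))
    res <- overlap_permutation_test(query, target, universe, n_perm = 99,
                                    seed = 100 + r)
    res$observed / mean(res$perm)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})
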