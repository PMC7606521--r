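# Interval and association statistics: merging of outlier selection-scan
# windows, one-sided overlap permutation tests against a mappable universe,
# the DMR-SNP linkage-disequilibrium permutation test, and hypergeometric
# candidate-set enrichment. Empirical p-values use the add-one rule
# p = (1 + #{perm >= obs}) / (n_perm + 1), so p is never 0 and the minimum
# attainable value is 1/(n_perm + 1).

#' Merge outlier windows of a genome scan into selection targets
#'
#' Sliding windows whose score falls in the upper `tail_frac` tail are
#' merged when overlapping or book-ended; each merged region takes the
#' maximum score of its member windows. Regions whose score reaches the
#' upper `outlier_frac` quantile of the original window scores are
#' returned as the targets of selection.
#'
#' @param windows A [GenomicRanges::GRanges] with a numeric `score` column
#'   (e.g. 50-kb windows at 5-kb step from a cross-population scan).
#' @param tail_frac Tail fraction for the merge step (default 0.10).
#' @param outlier_frac Outlier fraction for the final call (default 0.005).
#' @return `GRanges` of merged outlier regions with a `score` column;
#'   empty (with a warning) when the scores carry no tail.
#' @export
merge_outlier_windows <- function(windows, tail_frac = 0.10,
                                  outlier_frac = 0.005) {
  stopifnot(methods::is(windows, "GRanges"), !is.null(windows$score),
            all(is.finite(windows$score)))
  if (length(unique(windows$score)) == 1L) {
    warning("all window scores identical; no tail to merge")
    out <- GenomicRanges::GRanges()
    out$score <- numeric(0)
    return(out)
  }
  q_tail <- stats::quantile(windows$score, 1 - tail_frac, names = FALSE)
  q_out <- stats::quantile(windows$score, 1 - outlier_frac, names = FALSE)
  tail_w <- windows[windows$score >= q_tail]
  merged <- GenomicRanges::reduce(tail_w)
  hits <- GenomicRanges::findOverlaps(merged, tail_w)
  mx <- tapply(tail_w$score[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), max)
  merged$score <- as.numeric(mx[as.character(seq_along(merged))])
  merged[merged$score >= q_out]
}

#' One-sided overlap permutation test
#'
#' Observed statistic: number of query intervals overlapping at least 1 bp
#' of the target set. Null: query interval lengths are re-placed uniformly
#' at random inside the universe segments (within the same chromosome by
#' default), preserving lengths and forbidding self-overlap by rejection.
#'
#' @param query,target,universe `GRanges`; query and target should lie
#'   within the universe.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; the permutation stream is reproducible.
#' @param mode `"within_chrom"` (conservative default) or `"genome_wide"`
#'   placement of shuffled intervals.
#' @return A `permutation_result`: `observed`, `perm` (replicate vector),
#'   `p_value` (add-one one-sided), `enrichment` (observed / mean
#'   permuted), `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(query, target, universe, n_perm = 999L,
                                     seed = 1L,
                                     mode = c("within_chrom", "genome_wide")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(query, "GRanges"), methods::is(target, "GRanges"),
            methods::is(universe, "GRanges"), n_perm >= 1, length(query) > 0)
  universe <- GenomicRanges::reduce(universe)
  observed <- sum(GenomicRanges::countOverlaps(query, target) > 0)

  seg_chrom <- as.character(GenomicRanges::seqnames(universe))
  seg_start <- BiocGenerics::start(universe)
  seg_width <- BiocGenerics::width(universe)
  q_width <- BiocGenerics::width(query)
  q_chrom <- as.character(GenomicRanges::seqnames(query))

  # per query interval, the universe segments it may be placed into
  placeable <- lapply(seq_along(query), function(i) {
    segs <- if (mode == "within_chrom") which(seg_chrom == q_chrom[i])
            else seq_along(seg_width)
    segs <- segs[seg_width[segs] >= q_width[i]]
    if (!length(segs)) {
      stop("query interval ", i, " is longer than every available universe segment")
    }
    segs
  })
  slots <- lapply(seq_along(query), function(i) {
    seg_width[placeable[[i]]] - q_width[i] + 1
  })

  t_chrom <- as.character(GenomicRanges::seqnames(target))
  t_start <- BiocGenerics::start(target)
  t_end <- BiocGenerics::end(target)
  nq <- length(query)
  place_order <- order(q_width, decreasing = TRUE)

  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      p_start <- integer(0)
      p_end <- integer(0)
      p_chr <- character(0)
      for (i in place_order) {
        st <- NA_integer_
        for (try in seq_len(200L)) {
          si <- placeable[[i]][
            sample.int(length(placeable[[i]]), 1L, prob = slots[[i]])]
          st <- seg_start[si] +
            sample.int(seg_width[si] - q_width[i] + 1L, 1L) - 1L
          en <- st + q_width[i] - 1L
          same <- p_chr == seg_chrom[si]
          if (!any(same & st <= p_end & en >= p_start)) break
          # overlap with an already-placed interval: rejected, retry
        }
        p_start <- c(p_start, st)
        p_end <- c(p_end, st + q_width[i] - 1L)
        p_chr <- c(p_chr, seg_chrom[si])
      }
      hits <- 0L
      for (j in seq_len(nq)) {
        tv <- t_chrom == p_chr[j] & t_start <= p_end[j] & t_end >= p_start[j]
        if (any(tv)) hits <- hits + 1L
      }
      hits
    }, integer(1))
  })
  .permutation_result(observed, perm, n_perm, seed)
}

.permutation_result <- function(observed, perm, n_perm, seed) {
  structure(list(
    observed = observed,
    perm = perm,
    p_value = (1 + sum(perm >= observed)) / (n_perm + 1),
    enrichment = if (mean(perm) > 0) observed / mean(perm) else NA_real_,
    n_perm = n_perm, seed = seed),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed %g, null mean %.2f, enrichment %.2f, one-sided p = %.4g (%d permutations)\n",
              x$observed, mean(x$perm), x$enrichment, x$p_value, x$n_perm))
  invisible(x)
}

#' DMR--SNP linkage-disequilibrium permutation test
#'
#' Per SNP, the statistic is the squared Pearson correlation between the
#' genotype column and the DMR methylation state across individuals
#' (pairwise-complete). One-sided p-values come from permuting the state
#' vector; the same permutation stream is shared across the SNPs of one
#' DMR so their p-values are comparable. The DMR is declared in LD when at
#' least `min_sig` SNPs reach `p < alpha`. Monomorphic SNPs (or a
#' monomorphic state vector) carry no information and get `p = 1`.
#'
#' @param dmr_states Numeric/integer vector over individuals (e.g. 0/1/2
#'   calls of the DMR tile).
#' @param snps Numeric matrix, one row per SNP, columns = the same
#'   individuals (genotype 0/1/2, NA allowed).
#' @param n_perm Number of permutations (default 999).
#' @param min_sig Minimum significant SNPs to declare LD (default 3).
#' @param alpha Per-SNP significance level (default 0.01).
#' @param seed Integer seed.
#' @return List with `p_values` (per SNP), `r2` (observed statistics),
#'   `in_ld` (logical), `n_perm`, `seed`.
#' @export
dmr_snp_ld_test <- function(dmr_states, snps, n_perm = 999L, min_sig = 3L,
                            alpha = 0.01, seed = 1L) {
  if (is.data.frame(snps)) snps <- as.matrix(snps)
  stopifnot(is.matrix(snps), ncol(snps) == length(dmr_states), n_perm >= 1)
  n_snp <- nrow(snps)
  n_ind <- length(dmr_states)
  states <- as.numeric(dmr_states)

  r2_vec <- function(st) {
    # squared Pearson correlation of each SNP row with st, pairwise complete
    vapply(seq_len(n_snp), function(i) {
      g <- snps[i, ]
      ok <- !is.na(g) & !is.na(st)
      if (sum(ok) < 3L) return(NA_real_)
      if (stats::sd(g[ok]) == 0 || stats::sd(st[ok]) == 0) return(NA_real_)
      stats::cor(g[ok], st[ok])^2
    }, numeric(1))
  }
  complete <- !anyNA(snps) && !anyNA(states)
  obs <- r2_vec(states)
  perm_mat <- .with_seed(seed, {
    perm_idx <- vapply(seq_len(n_perm), function(p) sample.int(n_ind),
                       integer(n_ind))
    if (complete) {
      # one matrix product gives all SNP x permutation correlations
      Gc <- snps - rowMeans(snps)
      gss <- rowSums(Gc^2)
      S <- matrix(states[perm_idx], n_ind, n_perm)
      Sc <- S - matrix(colMeans(S), n_ind, n_perm, byrow = TRUE)
      sss <- colSums(Sc^2)
      num <- (Gc %*% Sc)^2
      r2 <- num / outer(gss, sss)
      r2[gss == 0, ] <- NA_real_
      if (any(sss == 0)) r2[, sss == 0] <- NA_real_
      r2
    } else {
      vapply(seq_len(n_perm), function(p) r2_vec(states[perm_idx[, p]]),
             numeric(n_snp))
    }
  })
  perm_mat <- matrix(perm_mat, nrow = n_snp)
  p_values <- vapply(seq_len(n_snp), function(i) {
    if (!is.finite(obs[i])) return(1)
    pv <- perm_mat[i, ]
    (1 + sum(pv >= obs[i], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  list(p_values = p_values, r2 = obs,
       in_ld = sum(p_values < alpha) >= min_sig,
       n_perm = n_perm, seed = seed)
}

#' Hypergeometric candidate-set enrichment
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' hit set and a candidate set drawn from a finite universe.
#'
#' @param hits,candidates,universe Character vectors of identifiers;
#'   `hits` and `candidates` must be subsets of `universe`.
#' @return One-sided p-value.
#' @export
candidate_enrichment <- function(hits, candidates, universe) {
  universe <- unique(universe)
  hits <- unique(hits)
  candidates <- unique(candidates)
  if (length(universe) == 0L) stop("empty universe")
  stopifnot(all(hits %in% universe), all(candidates %in% universe))
  x <- length(intersect(hits, candidates))
  stats::phyper(x - 1, length(candidates),
                length(universe) - length(candidates), length(hits),
                lower.tail = FALSE)
}
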