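# Methylome site frequency spectra: per tile, the number k of methylated
# epialleles among m sampled (m = 2n for n outbred diploids, m = n for
# inbred lines), tabulated over k = 0..m. Heterozygous diploid calls
# contribute exactly one methylated and one unmethylated allele.

#' Construct an mSFS object
#'
#' @param m Allele sample size.
#' @param counts Numeric vector of length `m + 1` over `k = 0..m`;
#'   non-negative. Expected (non-integer) counts are allowed, as produced
#'   by hypergeometric projection.
#' @param context Methylation context label.
#' @param label Free-text cohort label.
#' @return An object of class `msfs`.
#' @export
msfs <- function(m, counts, context = "CG", label = "") {
  stopifnot(m >= 1, length(counts) == m + 1, all(counts >= 0))
  structure(list(m = as.integer(m), counts = as.numeric(counts),
                 context = context, label = label),
            class = "msfs")
}

#' @export
print.msfs <- function(x, ...) {
  cat(sprintf("mSFS (%s%s): m = %d alleles, %s tiles\n", x$context,
              if (nzchar(x$label)) paste0(", ", x$label) else "",
              x$m, format(round(sum(x$counts), 2))))
  invisible(x)
}

#' Bar plot of an mSFS
#'
#' @param x An `msfs` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.msfs <- function(x, ...) {
  graphics::barplot(x$counts / sum(x$counts), names.arg = 0:x$m,
                    xlab = "methylated epiallele count k",
                    ylab = "fraction of tiles", ...)
  invisible(x)
}

#' Build a methylome site frequency spectrum from epigenotype calls
#'
#' Per tile, the methylated-allele count is the sum of calls (0/1/2 per
#' outbred diploid, 0/1 per inbred line). Under `missing_policy = "drop"`
#' tiles with any missing call are excluded. Under `"project"`, each tile
#' with observed allele count `m_obs >= target_m` is hypergeometrically
#' downsampled to `target_m` alleles and the expected bin masses are
#' accumulated, preserving the total tile count.
#'
#' @param calls A `call_matrix`.
#' @param missing_policy `"drop"` or `"project"`.
#' @param target_m Target allele sample size for `"project"`; must not
#'   exceed the smallest observed per-tile allele count.
#' @param label Cohort label stored in the result.
#' @return An `msfs` object.
#' @export
build_msfs <- function(calls, missing_policy = c("drop", "project"),
                       target_m = NULL, label = "") {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(calls, "call_matrix"))
  per_allele <- if (calls$ploidy_mode == "outbred") 2L else 1L
  cm <- calls$calls
  n_obs <- rowSums(!is.na(cm))
  k_obs <- rowSums(cm, na.rm = TRUE)
  m_full <- per_allele * ncol(cm)
  if (missing_policy == "drop") {
    complete <- n_obs == ncol(cm)
    counts <- tabulate(k_obs[complete] + 1L, nbins = m_full + 1L)
    return(msfs(m_full, counts, calls$context, label))
  }
  if (is.null(target_m)) stop("missing_policy = 'project' requires target_m")
  keep <- n_obs > 0L
  m_obs <- per_allele * n_obs[keep]
  k_obs <- k_obs[keep]
  if (target_m > min(m_obs)) {
    stop("target_m (", target_m, ") exceeds the smallest observed allele count (",
         min(m_obs), ")")
  }
  counts <- numeric(target_m + 1L)
  combos <- unique(data.frame(k = k_obs, m = m_obs))
  for (i in seq_len(nrow(combos))) {
    kk <- combos$k[i]
    mm <- combos$m[i]
    n_t <- sum(k_obs == kk & m_obs == mm)
    j <- 0:target_m
    counts <- counts + n_t * stats::dhyper(j, kk, mm - kk, target_m)
  }
  msfs(target_m, counts, calls$context, label)
}

#' Classify tiles by population methylation frequency
#'
#' Partition of per-tile methylated-epiallele frequencies `k/m`:
#' exactly 0 = invariant unmethylated; in `(0, 0.1)` = rarely methylated;
#' in `[0.1, 0.9]` = high-frequency variable; in `(0.9, 1)` = rarely
#' unmethylated; exactly 1 = invariant methylated.
#'
#' @param freqs Frequencies in `[0, 1]` (NA allowed; propagates).
#' @return List with `category` (factor over the five levels) and
#'   `fractions` (named numeric summing to 1 over non-missing tiles).
#' @export
classify_tiles <- function(freqs) {
  stopifnot(all(is.na(freqs) | (freqs >= 0 & freqs <= 1)))
  lv <- c("invariant_unmethylated", "rarely_methylated",
          "high_frequency_variable", "rarely_unmethylated",
          "invariant_methylated")
  cat_ <- rep(NA_character_, length(freqs))
  ok <- !is.na(freqs)
  cat_[ok & freqs == 0] <- lv[1]
  cat_[ok & freqs > 0 & freqs < 0.1] <- lv[2]
  cat_[ok & freqs >= 0.1 & freqs <= 0.9] <- lv[3]
  cat_[ok & freqs > 0.9 & freqs < 1] <- lv[4]
  cat_[ok & freqs == 1] <- lv[5]
  f <- factor(cat_, levels = lv)
  frac <- table(f) / sum(ok)
  list(category = f, fractions = stats::setNames(as.numeric(frac), lv))
}

#' Assign tiles to genomic features by majority overlap
#'
#' Each tile goes to the first feature class in `precedence` whose
#' intervals cover at least `min_frac` of the tile; tiles covered by no
#' class fall to `"intergenic"`.
#'
#' @param tiles Tile coordinate data frame (chrom, start 0-based, end) or a
#'   `tile_matrix` / `call_matrix`.
#' @param annotations Named list of [GenomicRanges::GRanges], one per
#'   feature class.
#' @param precedence Character vector ordering the classes; defaults to
#'   `names(annotations)` in order.
#' @param min_frac Minimum covered fraction of the tile (default 0.5).
#' @return Character vector of feature assignments, one per tile.
#' @export
stratify_by_feature <- function(tiles, annotations,
                                precedence = names(annotations),
                                min_frac = 0.5) {
  if (inherits(tiles, "tile_matrix") || inherits(tiles, "call_matrix")) {
    tiles <- tiles$tiles
  }
  stopifnot(is.list(annotations), !is.null(names(annotations)),
            all(precedence %in% names(annotations)))
  tile_gr <- GenomicRanges::GRanges(
    tiles$chrom, IRanges::IRanges(tiles$start + 1L, tiles$end))
  width <- tiles$end - tiles$start
  out <- rep("intergenic", nrow(tiles))
  unassigned <- rep(TRUE, nrow(tiles))
  for (feat in precedence) {
    gr <- GenomicRanges::reduce(annotations[[feat]])
    hits <- GenomicRanges::findOverlaps(tile_gr, gr)
    if (!length(hits)) next
    ov <- GenomicRanges::pintersect(
      tile_gr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)])
    cov <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    pass <- idx[cov / width[idx] >= min_frac]
    pass <- pass[unassigned[pass]]
    out[pass] <- feat
    unassigned[pass] <- FALSE
  }
  out
}

#' Polarize tiles by the majority epiallele of an outgroup population
#'
#' Treats the most common epiallele in the outgroup (e.g. teosinte for
#' maize) as ancestral. Heterozygous calls contribute one methylated and
#' one unmethylated allele. Exact ties and all-missing tiles are
#' `"ambiguous"` and are excluded from polarized fits.
#'
#' @param calls_outgroup A `call_matrix` for the outgroup cohort.
#' @return Character vector per tile: `"ancestral_hyper"`,
#'   `"ancestral_hypo"` or `"ambiguous"`.
#' @export
polarize_by_ancestral_state <- function(calls_outgroup) {
  stopifnot(inherits(calls_outgroup, "call_matrix"))
  per_allele <- if (calls_outgroup$ploidy_mode == "outbred") 2L else 1L
  cm <- calls_outgroup$calls
  n_obs <- rowSums(!is.na(cm))
  meth <- rowSums(cm, na.rm = TRUE)
  unmeth <- per_allele * n_obs - meth
  out <- rep("ambiguous", nrow(cm))
  out[meth > unmeth] <- "ancestral_hyper"
  out[meth < unmeth] <- "ancestral_hypo"
  out[n_obs == 0L] <- "ambiguous"
  out
}

#' Serialize / deserialize an mSFS as JSON
#'
#' @param x An `msfs` object.
#' @param path File path.
#' @export
write_msfs <- function(x, path) {
  stopifnot(inherits(x, "msfs"))
  jsonlite::write_json(list(m = x$m, counts = x$counts, context = x$context,
                            label = x$label),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_msfs
#' @export
read_msfs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  msfs(obj$m, obj$counts, obj$context, obj$label)
}
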