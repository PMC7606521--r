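# Generators for every input the pipeline consumes: stationary-model tile
# frequencies, Hardy-Weinberg genotypes, noisy tile methylation levels,
# per-cytosine reports, SNPs with tunable linkage to the methylation state,
# and interval sets with controlled overlap. Every generator is a pure
# function of (arguments, seed).

#' Sample tile epiallele frequencies from the stationary density
#'
#' Inverse-CDF sampling on a dense Gauss--Jacobi grid of the normalized
#' density: the quadrature weights absorb the endpoint singularities, the
#' CDF is accumulated at the nodes and inverted by monotone interpolation.
#' Draws below the smallest (or above the largest) node are clamped to it,
#' so values always lie strictly inside (0, 1); the clamped range carries
#' negligible sampling probability mass at the grid order used.
#'
#' @param params A `model_params` object.
#' @param n_tiles Number of frequencies to draw.
#' @param seed Integer seed.
#' @param order Quadrature grid order (default 512).
#' @return Numeric vector in `(0, 1)`.
#' @export
simulate_tile_frequencies <- function(params, n_tiles, seed = 1L,
                                      order = 512L) {
  stopifnot(n_tiles >= 1)
  ex <- .density_exponents(params)
  rule <- .unit_jacobi(ex[["one_minus_q"]], ex[["q"]], order)
  lw <- rule$logw + ex[["gamma"]] * rule$q
  w <- exp(lw - max(lw))
  cdf <- (cumsum(w) - w / 2) / sum(w)
  u <- .with_seed(seed, stats::runif(n_tiles))
  q <- stats::approx(cdf, rule$q, xout = u, rule = 2, ties = "ordered")$y
  pmin(pmax(q, rule$q[1]), rule$q[length(rule$q)])
}

#' Sample true epigenotypes from tile frequencies
#'
#' Outbred diploids: genotype ~ Binomial(2, q) per individual
#' (Hardy--Weinberg). Inbred lines: allele ~ Bernoulli(q), coded 0/1.
#'
#' @param q Tile frequencies in `(0, 1)` (or `[0, 1]`).
#' @param n_individuals Number of individuals (columns).
#' @param ploidy_mode `"outbred"` or `"inbred"`.
#' @param seed Integer seed.
#' @param chrom,tile_size Coordinates assigned to the tiles: consecutive
#'   `tile_size`-bp tiles on a single synthetic chromosome.
#' @return A `call_matrix` of true states.
#' @export
simulate_genotypes <- function(q, n_individuals,
                               ploidy_mode = c("outbred", "inbred"),
                               seed = 1L, chrom = "chrSim",
                               tile_size = 100L) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(all(q >= 0 & q <= 1), n_individuals >= 1)
  n_tiles <- length(q)
  size <- if (ploidy_mode == "outbred") 2L else 1L
  calls <- .with_seed(seed, {
    matrix(stats::rbinom(n_tiles * n_individuals, size, q),
           nrow = n_tiles, ncol = n_individuals,
           dimnames = list(NULL, sprintf("ind%02d", seq_len(n_individuals))))
  })
  tiles <- data.frame(
    chrom = chrom,
    start = (seq_len(n_tiles) - 1L) * tile_size,
    end = seq_len(n_tiles) * tile_size,
    stringsAsFactors = FALSE)
  call_matrix(tiles, calls, ploidy_mode)
}

#' Noise specification for simulated tile levels
#'
#' `model = "beta"` draws levels from beta distributions shaped around the
#' class centres: Beta(1, conc) for unmethylated (mode 0), mirrored
#' Beta(conc, 1) for methylated (mode 1), Beta(conc/2, conc/2) for
#' heterozygous (centre 0.5, sd `0.5/sqrt(conc + 1)`). Beta noise respects
#' the [0, 1] support of methylation levels; `model = "normal"` instead
#' adds truncated normal noise with the given per-class `sd`, matching the
#' distributional assumption of the mixture caller.
#'
#' @param model `"beta"` or `"normal"`.
#' @param conc Length-3 positive concentrations (unmethylated,
#'   heterozygous, methylated) for `"beta"`.
#' @param sd Length-3 sds for `"normal"`.
#' @return A `level_noise` object.
#' @export
level_noise <- function(model = c("beta", "normal"),
                        conc = c(50, 100, 50),
                        sd = c(0.03, 0.05, 0.03)) {
  model <- match.arg(model)
  stopifnot(length(conc) == 3L, all(conc > 0),
            length(sd) == 3L, all(sd > 0))
  structure(list(model = model, conc = conc, sd = sd),
            class = "level_noise")
}

#' Simulate noisy tile methylation levels from true states
#'
#' @param true_states A `call_matrix` of true epigenotypes.
#' @param noise A [level_noise()] specification.
#' @param seed Integer seed.
#' @return A `tile_matrix` of levels in `[0, 1]`.
#' @export
simulate_tile_levels <- function(true_states, noise = level_noise(),
                                 seed = 1L) {
  stopifnot(inherits(true_states, "call_matrix"),
            inherits(noise, "level_noise"))
  cm <- true_states$calls
  # map calls to class index 1/2/3 = unmeth/het/meth
  cls <- cm
  if (true_states$ploidy_mode == "inbred") cls[cm == 1L] <- 2L
  cls <- cls + 1L
  lev <- .with_seed(seed, {
    out <- matrix(NA_real_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
    for (j in 1:3) {
      idx <- which(cls == j)
      if (!length(idx)) next
      if (noise$model == "beta") {
        cc <- noise$conc[j]
        out[idx] <- switch(j,
          stats::rbeta(length(idx), 1, cc),
          stats::rbeta(length(idx), cc / 2, cc / 2),
          stats::rbeta(length(idx), cc, 1))
      } else {
        centre <- c(0, 0.5, 1)[j]
        out[idx] <- pmin(pmax(
          stats::rnorm(length(idx), centre, noise$sd[j]), 0), 1)
      }
    }
    out
  })
  tile_matrix(true_states$tiles, lev,
              context = true_states$context)
}

#' Simulate a per-cytosine report from tile levels
#'
#' Places `sites_per_tile` cytosines at evenly spaced positions inside each
#' tile; per site, depth ~ NegBin(mean = `depth_mean`, size =
#' `depth_dispersion`) and the methylated count ~ Binomial(depth, tile
#' level). The result parses under [read_cytosine_report()] and
#' aggregates back to the input levels within binomial noise.
#'
#' @param levels Numeric vector of tile levels in `[0, 1]` (NA tiles are
#'   skipped).
#' @param tiles Tile coordinates (data.frame chrom/start/end) matching
#'   `levels`; taken from a `tile_matrix` if one is supplied as `levels`.
#' @param sites_per_tile Cytosines per tile.
#' @param depth_mean,depth_dispersion Negative-binomial coverage model;
#'   defaults emulate ~20x whole-genome bisulfite coverage.
#' @param context Context string written for every site.
#' @param strand Strand written for every site.
#' @param seed Integer seed.
#' @param path Optional file path; when given, the report is written as TSV
#'   (chrom, pos, strand, n_meth, n_unmeth, context) and the path returned
#'   invisibly.
#' @return Data frame of cytosine records (also written when `path` given).
#' @export
simulate_cytosine_report <- function(levels, tiles = NULL,
                                     sites_per_tile = 8L,
                                     depth_mean = 20, depth_dispersion = 5,
                                     context = "CG", strand = "+",
                                     seed = 1L, path = NULL) {
  if (inherits(levels, "tile_matrix")) {
    stopifnot(ncol(levels$levels) == 1L)
    tiles <- levels$tiles
    context <- levels$context
    levels <- levels$levels[, 1L]
  }
  stopifnot(!is.null(tiles), nrow(tiles) == length(levels),
            sites_per_tile >= 1L, depth_mean > 0, depth_dispersion > 0)
  keep <- which(is.finite(levels))
  width <- tiles$end - tiles$start
  offsets <- function(w) round(seq(1, w, length.out = sites_per_tile))
  rec <- .with_seed(seed, {
    pos <- unlist(lapply(keep, function(i) {
      tiles$start[i] + offsets(width[i])
    }), use.names = FALSE)
    lv <- rep(levels[keep], each = sites_per_tile)
    depth <- stats::rnbinom(length(pos), mu = depth_mean,
                            size = depth_dispersion)
    n_meth <- stats::rbinom(length(pos), depth, lv)
    data.frame(chrom = rep(tiles$chrom[keep], each = sites_per_tile),
               pos = as.integer(pos), strand = strand, context = context,
               n_meth = n_meth, n_total = depth, stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    out <- data.frame(rec$chrom, rec$pos, rec$strand, rec$n_meth,
                      rec$n_total - rec$n_meth, rec$context)
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  rec
}

#' Simulate SNPs linked to methylation states and interval sets with
#' controlled overlap
#'
#' For each focal tile, `snps_per_dmr` SNP genotype columns are generated
#' by copying the tile's per-individual methylation alleles with error:
#' each SNP allele equals the corresponding methylation allele with
#' probability `sqrt(r2_target)` and is otherwise drawn independently from
#' the tile's allele frequency, giving expected squared correlation
#' `r2_target` between genotype and methylation state. Interval sets place
#' one "DMR" per focal tile and a "sweep" overlapping each DMR
#' independently with probability `overlap_frac`, inside a single-segment
#' mappable universe.
#'
#' @param calls A `call_matrix`.
#' @param focal_tiles Indices of tiles to treat as DMRs (default: all).
#' @param r2_target Target squared correlation in `[0, 1]`.
#' @param snps_per_dmr SNPs generated within +/-1 kb of each DMR.
#' @param overlap_frac Fraction of DMRs overlapped by a sweep, in
#'   expectation.
#' @param seed Integer seed.
#' @return List with `snps` (data.frame chrom, pos, ref, alt, one genotype
#'   column per individual, plus a `dmr` index column), `dmrs`, `sweeps`
#'   and `universe` (`GRanges`).
#' @export
simulate_snps_and_intervals <- function(calls, focal_tiles = NULL,
                                        r2_target = 0.5, snps_per_dmr = 6L,
                                        overlap_frac = 0.5, seed = 1L) {
  stopifnot(inherits(calls, "call_matrix"),
            r2_target >= 0, r2_target <= 1, snps_per_dmr >= 1)
  if (is.null(focal_tiles)) focal_tiles <- seq_len(nrow(calls$calls))
  per_allele <- if (calls$ploidy_mode == "outbred") 2L else 1L
  cm <- calls$calls
  n_ind <- ncol(cm)
  copy_p <- sqrt(r2_target)
  tiles <- calls$tiles[focal_tiles, , drop = FALSE]

  res <- .with_seed(seed, {
    snp_rows <- vector("list", length(focal_tiles))
    for (fi in seq_along(focal_tiles)) {
      t_idx <- focal_tiles[fi]
      g_meth <- cm[t_idx, ]
      p_meth <- mean(g_meth, na.rm = TRUE) / per_allele
      if (!is.finite(p_meth)) p_meth <- 0.5
      pos <- sort(sample(
        max(1L, tiles$start[fi] - 1000L):(tiles$end[fi] + 1000L),
        snps_per_dmr))
      # methylation alleles per individual: g_meth[ij] ones, rest zeros
      A <- vapply(seq_len(n_ind), function(ij) {
        if (is.na(g_meth[ij])) rep(NA_integer_, per_allele)
        else c(rep(1L, g_meth[ij]), rep(0L, per_allele - g_meth[ij]))
      }, integer(per_allele))
      A <- matrix(A, nrow = per_allele)   # per_allele x n_ind
      n_al <- per_allele * n_ind * snps_per_dmr
      Arep <- array(rep(A, snps_per_dmr), dim = c(per_allele, n_ind,
                                                  snps_per_dmr))
      copy <- array(stats::runif(n_al) < copy_p, dim = dim(Arep))
      rand <- array(stats::rbinom(n_al, 1L, p_meth), dim = dim(Arep))
      alleles <- ifelse(copy, Arep, rand)
      alleles[is.na(Arep)] <- NA_integer_   # missing call -> missing genotype
      geno <- t(apply(alleles, c(2, 3), sum))   # snps x n_ind
      dimnames(geno) <- list(NULL, colnames(cm))
      snp_rows[[fi]] <- data.frame(
        chrom = tiles$chrom[fi], pos = pos, ref = "A", alt = "G",
        dmr = fi, geno,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    width <- tiles$end - tiles$start
    sweep_hit <- stats::runif(length(focal_tiles)) < overlap_frac
    # sweeps sit fully inside their DMR so overlap with neighbouring DMRs
    # cannot distort the constructed overlap fraction
    sweep_offset <- vapply(width, function(w) {
      sample.int(max(1L, w %/% 2L), 1L) - 1L
    }, integer(1))
    list(snps = do.call(rbind, snp_rows), sweep_hit = sweep_hit,
         sweep_offset = sweep_offset)
  })

  dmrs <- GenomicRanges::GRanges(
    tiles$chrom, IRanges::IRanges(tiles$start + 1L, tiles$end))
  chrom_end <- max(tiles$end) + 10000L
  universe <- GenomicRanges::GRanges(
    tiles$chrom[1], IRanges::IRanges(1L, chrom_end))
  hit <- which(res$sweep_hit)
  sweeps <- if (length(hit)) {
    w <- pmax(1L, (tiles$end[hit] - tiles$start[hit]) %/% 2L - 1L)
    st <- tiles$start[hit] + res$sweep_offset[hit]
    GenomicRanges::GRanges(tiles$chrom[hit],
                           IRanges::IRanges(st + 1L, st + w))
  } else {
    GenomicRanges::GRanges()
  }
  list(snps = res$snps, dmrs = dmrs, sweeps = sweeps, universe = universe)
}

#' One-call synthetic cohort
#'
#' Convenience wrapper chaining frequency, genotype and level simulation
#' with per-stage seeds derived from `seed`.
#'
#' @param params A `model_params`.
#' @param n_tiles,n_individuals Cohort dimensions.
#' @param ploidy_mode `"outbred"` or `"inbred"`.
#' @param noise A [level_noise()].
#' @param seed Integer seed.
#' @return List with `q`, `genotypes` (`call_matrix`), `levels`
#'   (`tile_matrix`).
#' @export
simulate_cohort <- function(params, n_tiles, n_individuals,
                            ploidy_mode = "outbred",
                            noise = level_noise(), seed = 1L) {
  q <- simulate_tile_frequencies(params, n_tiles, seed = .child_seed(seed, 1L))
  geno <- simulate_genotypes(q, n_individuals, ploidy_mode,
                             seed = .child_seed(seed, 2L))
  lev <- simulate_tile_levels(geno, noise, seed = .child_seed(seed, 3L))
  list(q = q, genotypes = geno, levels = lev)
}
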