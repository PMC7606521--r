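# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through explicit temp files.

# Write a cytosine-report TSV from a data.frame of records
# (chrom, pos, strand, n_meth, n_unmeth, context).
write_report_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(apply(rows, 1L, paste, collapse = "\t"), path)
  path
}

report_row <- function(chrom = "chr1", pos, strand = "+", n_meth, n_unmeth,
                       context = "CG") {
  c(chrom, pos, strand, n_meth, n_unmeth, context)
}

# Independent brute-force tile aggregation: per-tile mean of site levels.
oracle_tile_means <- function(records, tile_size = 100L, min_sites = 3L) {
  key <- sprintf("%s %09d", records$chrom,
                 (records$pos - 1L) %/% tile_size * tile_size)
  lv <- records$n_meth / records$n_total
  out <- vapply(split(lv, key), function(x) {
    if (length(x) < min_sites) NA_real_ else mean(x)
  }, numeric(1))
  out[order(names(out))]
}

# Brute-force spectrum: loop tiles, count methylated alleles, tabulate.
oracle_msfs_counts <- function(calls, per_allele) {
  m <- per_allele * ncol(calls)
  counts <- integer(m + 1L)
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (any(is.na(row))) next
    counts[sum(row) + 1L] <- counts[sum(row) + 1L] + 1L
  }
  counts
}

# Brute-force normalization integral by trapezoid after substitutions that
# remove both endpoint singularities exactly:
#   q = t^(1/beta) near 0, 1 - q = t^(1/alpha) near 1.
oracle_norm_integral <- function(alpha, beta, gamma, n_grid = 1e6) {
  f_mid <- function(q) exp(gamma * q) * (1 - q)^(alpha - 1) * q^(beta - 1)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  # left piece: int_0^{1/2} q^(beta-1) g(q) dq = (1/beta) int_0^{(1/2)^beta} g(t^(1/beta)) dt
  tl <- seq(0, 0.5^beta, length.out = n_grid)
  ql <- tl^(1 / beta)
  gl <- exp(gamma * ql) * (1 - ql)^(alpha - 1)
  left <- trap(tl, gl) / beta
  # right piece: int_{1/2}^1 (1-q)^(alpha-1) h(q) dq with 1-q = t^(1/alpha)
  tr <- seq(0, 0.5^alpha, length.out = n_grid)
  qr <- 1 - tr^(1 / alpha)
  hr <- exp(gamma * qr) * qr^(beta - 1)
  right <- trap(tr, hr) / alpha
  left + right
}

# Genotype matrix covering all three classes, for noise-model tests.
make_noise_genotypes <- function(n_tiles = 600, n_ind = 5, seed = 14) {
  simulate_genotypes(rep(c(0.05, 0.5, 0.95), length.out = n_tiles),
                     n_ind, "outbred", seed = seed)
}

# Default generating parameters of the simulation studies: the scaled
# values (alpha, beta, gamma) = (0.72, 0.036, 8.0) at Ne = 50,000, i.e.
# mu = 3.6e-6, nu = 1.8e-7, Ne*s = 2.
cg_truth_params <- function(ne = 5e4) {
  params_from_scaled(0.72, 0.036, 8.0, ne = ne)
}
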