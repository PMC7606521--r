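# Readers/writers for the external formats the pipeline consumes, the
# per-site coverage filter, and aggregation of per-cytosine calls into
# 100-bp tile methylation levels.

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a Bismark-style per-cytosine report
#'
#' Tab-separated columns: chrom, 1-based position, strand (+/-), two count
#' columns, context (CG/CHG/CHH), optional trinucleotide. The two count
#' columns are `(methylated, unmethylated)` reads in the Bismark dialect
#' (default) or `(methylated, total)` with `count_mode = "meth_total"`.
#' Sites covered by fewer than `min_total` reads are removed; the default
#' `min_total = 4` keeps sites with more than three mapped reads.
#'
#' @param path Path to the TSV report (plain or gzipped).
#' @param min_total Minimum total read count for a site to be retained.
#' @param count_mode `"meth_unmeth"` (Bismark) or `"meth_total"`.
#' @return A `data.frame` with columns chrom, pos, strand, context, n_meth,
#'   n_total, in file order. Strands are never merged: the two cytosines of
#'   a symmetric CpG remain separate records.
#' @export
read_cytosine_report <- function(path, min_total = 4L,
                                 count_mode = c("meth_unmeth", "meth_total")) {
  count_mode <- match.arg(count_mode)
  stopifnot(file.exists(path), min_total >= 0)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      blank.lines.skip = TRUE, data.table = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse cytosine report: ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L) {
    stop("cytosine report must have at least 6 tab-separated columns")
  }
  bad_cols <- which(is.na(dt[[4L]]) | is.na(dt[[5L]]))
  if (length(bad_cols)) {
    stop("malformed cytosine report at line ", bad_cols[1],
         ": wrong column count or non-numeric counts")
  }
  chrom <- as.character(dt[[1L]])
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  strand <- as.character(dt[[3L]])
  c4 <- suppressWarnings(as.numeric(dt[[4L]]))
  c5 <- suppressWarnings(as.numeric(dt[[5L]]))
  context <- as.character(dt[[6L]])
  .bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop("malformed cytosine report at line ", i[1], ": ", what)
  }
  .bad(is.na(pos) | pos < 1L, "position must be a 1-based integer")
  .bad(!strand %in% c("+", "-"), "strand must be '+' or '-'")
  .bad(is.na(c4) | is.na(c5) | c4 < 0 | c5 < 0, "negative or missing counts")
  .bad(!context %in% .CONTEXTS, "context must be CG, CHG or CHH")
  n_meth <- as.integer(c4)
  n_total <- if (count_mode == "meth_total") as.integer(c5) else
    as.integer(c4 + c5)
  .bad(n_meth > n_total, "methylated count exceeds total count")
  keep <- n_total >= min_total
  data.frame(chrom = chrom[keep], pos = pos[keep], strand = strand[keep],
             context = context[keep], n_meth = n_meth[keep],
             n_total = n_total[keep], stringsAsFactors = FALSE)
}

#' Substitute homozygous SNP alleles into a reference sequence
#'
#' Builds the pseudo-reference used to reduce bisulfite mapping bias: every
#' position where `individual` is homozygous for the alternate allele
#' (genotype 2) carries the alternate base; heterozygous and missing
#' genotypes keep the reference base, because a single output sequence
#' cannot encode ambiguity without breaking downstream bisulfite logic.
#'
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param snps SNP table: data.frame with columns chrom, pos (1-based), ref,
#'   alt (single bases), plus one genotype column per individual coded
#'   0/1/2/NA.
#' @param individual Name of the genotype column to substitute.
#' @param out_fasta Optional path; if given the result is also written out.
#' @return A `DNAStringSet` with the same names and lengths as the input.
#' @export
build_pseudo_reference <- function(reference, snps, individual,
                                   out_fasta = NULL) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  stopifnot(methods::is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (nrow(snps) == 0L) {
    if (!is.null(out_fasta)) Biostrings::writeXStringSet(reference, out_fasta)
    return(reference)
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snps)),
            individual %in% names(snps))
  if (any(snps$ref == snps$alt)) stop("SNP with identical ref and alt allele")
  if (any(nchar(snps$ref) != 1L | nchar(snps$alt) != 1L)) {
    stop("only single-nucleotide alleles are supported")
  }
  if (!all(snps$chrom %in% names(reference))) {
    stop("SNP chromosome absent from reference: ",
         setdiff(snps$chrom, names(reference))[1])
  }
  out <- reference
  for (chr in unique(snps$chrom)) {
    rows <- snps[snps$chrom == chr, , drop = FALSE]
    if (any(rows$pos < 1L | rows$pos > length(reference[[chr]]))) {
      stop("SNP position outside chromosome ", chr)
    }
    have <- as.character(Biostrings::extractAt(
      reference[[chr]], IRanges::IRanges(rows$pos, rows$pos)))
    mism <- which(toupper(have) != toupper(rows$ref))
    if (length(mism)) {
      stop("reference allele mismatch at ", chr, ":",
           paste(rows$pos[mism], collapse = ","))
    }
    hom <- which(!is.na(rows[[individual]]) & rows[[individual]] == 2L)
    if (length(hom)) {
      out[[chr]] <- Biostrings::replaceLetterAt(
        out[[chr]], rows$pos[hom], rows$alt[hom])
    }
  }
  if (!is.null(out_fasta)) Biostrings::writeXStringSet(out, out_fasta)
  out
}

#' Aggregate per-cytosine records into tile methylation levels
#'
#' Tiles are fixed windows of `tile_size` bp anchored at reference
#' coordinate 0 (0-based half-open, so position `pos` falls in tile
#' `floor((pos - 1)/tile_size)`). The level of a tile is the unweighted
#' mean of the per-site levels `n_meth / n_total` of its covered cytosines
#' (set `weighted = TRUE` to pool reads instead); tiles covered by fewer
#' than `min_sites` cytosines are reported missing.
#'
#' @param records Data frame from [read_cytosine_report()].
#' @param context Single context to aggregate (`"CG"` or `"CHG"`; CHH is
#'   excluded from population-genetic analysis and is rejected here).
#' @param tile_size Tile width in bp.
#' @param min_sites Minimum covered cytosines for a defined tile level.
#' @param weighted If `TRUE`, tile level is `sum(n_meth)/sum(n_total)`.
#' @param id Column name for this individual in the resulting matrix.
#' @return A `tile_matrix` with one column: list with elements `tiles`
#'   (data.frame chrom/start/end), `context`, `levels` and `n_sites`
#'   (matrices tiles x individuals).
#' @export
aggregate_tiles <- function(records, context = c("CG", "CHG"),
                            tile_size = 100L, min_sites = 3L,
                            weighted = FALSE, id = "sample1") {
  context <- match.arg(context)
  stopifnot(tile_size >= 1, min_sites >= 1)
  rec <- records[records$context == context, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(tile_matrix(
      tiles = data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE),
      levels = matrix(numeric(), 0, 1, dimnames = list(NULL, id)),
      n_sites = matrix(integer(), 0, 1, dimnames = list(NULL, id)),
      context = context))
  }
  dt <- data.table::data.table(
    chrom = rec$chrom,
    start = as.integer((rec$pos - 1L) %/% tile_size) * tile_size,
    level = rec$n_meth / rec$n_total,
    n_meth = rec$n_meth, n_total = rec$n_total)
  agg <- dt[, list(level_mean = mean(level),
                   level_pooled = sum(n_meth) / sum(n_total),
                   n = .N),
            by = c("chrom", "start")]
  data.table::setorderv(agg, c("chrom", "start"))
  lev <- if (weighted) agg$level_pooled else agg$level_mean
  lev[agg$n < min_sites] <- NA_real_
  tile_matrix(
    tiles = data.frame(chrom = agg$chrom, start = agg$start,
                       end = agg$start + as.integer(tile_size),
                       stringsAsFactors = FALSE),
    levels = matrix(lev, ncol = 1, dimnames = list(NULL, id)),
    n_sites = matrix(as.integer(agg$n), ncol = 1, dimnames = list(NULL, id)),
    context = context)
}

#' Tile-level methylation matrix
#'
#' Container for tiles x individuals methylation levels in `[0, 1]`
#' (missing allowed) over fixed-width genomic tiles of a single context.
#'
#' @param tiles Data frame with chrom, start (0-based), end; constant width;
#'   sorted by (chrom, start).
#' @param levels Numeric matrix, rows = tiles, columns = individuals.
#' @param n_sites Integer matrix of covered-cytosine counts, same shape.
#' @param context `"CG"` or `"CHG"`.
#' @return An object of class `tile_matrix`.
#' @export
tile_matrix <- function(tiles, levels, n_sites = NULL,
                        context = c("CG", "CHG")) {
  context <- match.arg(context)
  stopifnot(is.data.frame(tiles),
            all(c("chrom", "start", "end") %in% names(tiles)),
            is.matrix(levels), nrow(levels) == nrow(tiles))
  if (nrow(tiles) > 0L) {
    w <- tiles$end - tiles$start
    if (length(unique(w)) > 1L) stop("tiles must share a single width")
    if (any(w <= 0)) stop("tile start must be < end")
    o <- order(tiles$chrom, tiles$start)
    if (!identical(o, seq_len(nrow(tiles)))) {
      stop("tiles must be sorted by (chrom, start)")
    }
    finite <- levels[is.finite(levels)]
    if (length(finite) && (min(finite) < 0 || max(finite) > 1)) {
      stop("methylation levels must lie in [0, 1]")
    }
  }
  if (is.null(n_sites)) {
    n_sites <- matrix(NA_integer_, nrow(levels), ncol(levels),
                      dimnames = dimnames(levels))
  }
  structure(list(tiles = tiles, levels = levels, n_sites = n_sites,
                 context = context),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat(sprintf("tile_matrix: %d tiles x %d individuals (%s, %d-bp tiles, %.1f%% missing)\n",
              nrow(x$levels), ncol(x$levels), x$context,
              if (nrow(x$tiles)) x$tiles$end[1] - x$tiles$start[1] else NA_integer_,
              100 * mean(is.na(x$levels))))
  invisible(x)
}

#' Combine single-individual tile matrices
#'
#' Aligns per-individual one-column matrices (e.g. from [aggregate_tiles()])
#' on the union of their tiles; tiles absent from an individual are missing.
#'
#' @param mats List of `tile_matrix` objects sharing context and tile size.
#' @return A multi-column `tile_matrix`.
#' @export
combine_tile_matrices <- function(mats) {
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "tile_matrix")))
  ctx <- unique(vapply(mats, `[[`, "", "context"))
  if (length(ctx) != 1L) stop("all tile matrices must share one context")
  keys <- lapply(mats, function(m) paste(m$tiles$chrom, m$tiles$start))
  all_tiles <- unique(do.call(rbind, lapply(mats, `[[`, "tiles")))
  all_tiles <- all_tiles[order(all_tiles$chrom, all_tiles$start), ,
                         drop = FALSE]
  rownames(all_tiles) <- NULL
  key_all <- paste(all_tiles$chrom, all_tiles$start)
  ids <- unlist(lapply(mats, function(m) colnames(m$levels)))
  if (anyDuplicated(ids)) stop("duplicated individual ids across matrices")
  lev <- matrix(NA_real_, nrow(all_tiles), length(ids),
                dimnames = list(NULL, ids))
  ns <- matrix(NA_integer_, nrow(all_tiles), length(ids),
               dimnames = list(NULL, ids))
  col <- 0L
  for (j in seq_along(mats)) {
    idx <- match(keys[[j]], key_all)
    for (jj in seq_len(ncol(mats[[j]]$levels))) {
      col <- col + 1L
      lev[idx, col] <- mats[[j]]$levels[, jj]
      ns[idx, col] <- mats[[j]]$n_sites[, jj]
    }
  }
  tile_matrix(all_tiles, lev, ns, ctx)
}

#' Read / write BED interval sets
#'
#' BED is 0-based half-open with at least 3 columns; columns 4-6 (name,
#' score, strand) are kept when present. Intervals with `start >= end` are
#' rejected. The result round-trips through [write_bed()] unchanged.
#'
#' @param path File path.
#' @param name Label stored in the metadata of the returned object.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$name <- name
    return(gr)
  }
  tab <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                           data.table = FALSE, colClasses = list(character = 1))
  if (ncol(tab) < 3L) stop("BED requires at least 3 columns")
  start0 <- suppressWarnings(as.numeric(tab[[2L]]))
  end0 <- suppressWarnings(as.numeric(tab[[3L]]))
  if (any(is.na(start0) | is.na(end0) | start0 < 0)) {
    stop("malformed BED coordinates at line ",
         which(is.na(start0) | is.na(end0) | start0 < 0)[1])
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop("degenerate BED interval (start >= end) at line ", bad[1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tab[[1L]]),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  if (ncol(tab) >= 4L) gr$name <- as.character(tab[[4L]])
  if (ncol(tab) >= 5L) gr$score <- suppressWarnings(as.numeric(tab[[5L]]))
  if (ncol(tab) >= 6L) {
    str <- as.character(tab[[6L]])
    str[!str %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- str
  }
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' @rdname read_bed
#' @param gr A `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  n <- length(gr)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               format(BiocGenerics::start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(BiocGenerics::end(gr), scientific = FALSE, trim = TRUE))
  has_name <- !is.null(gr$name)
  has_score <- !is.null(gr$score)
  has_strand <- any(as.character(BiocGenerics::strand(gr)) != "*")
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(if (has_name) gr$name else rep(".", n)))
  }
  if (has_score || has_strand) {
    cols <- c(cols, list(if (has_score) as.character(gr$score) else rep("0", n)))
  }
  if (has_strand) cols <- c(cols, list(as.character(BiocGenerics::strand(gr))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write tile matrices as TSV
#'
#' Header row `chrom start end context id1 id2 ...`; levels formatted with
#' full precision, missing as `NA`. Round-trip identity is tested.
#'
#' @param path File path.
#' @export
read_tile_matrix <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE, colClasses = list(character = 1))
  stopifnot(all(c("chrom", "start", "end", "context") %in% names(tab)))
  ids <- setdiff(names(tab), c("chrom", "start", "end", "context"))
  lev <- as.matrix(tab[, ids, drop = FALSE])
  storage.mode(lev) <- "double"
  ctx <- unique(tab$context)
  stopifnot(length(ctx) <= 1L || nrow(tab) == 0L)
  tile_matrix(tiles = data.frame(chrom = tab$chrom,
                                 start = as.integer(tab$start),
                                 end = as.integer(tab$end),
                                 stringsAsFactors = FALSE),
              levels = lev,
              context = if (nrow(tab)) ctx else "CG")
}

#' @rdname read_tile_matrix
#' @param tiles A `tile_matrix` to write.
#' @export
write_tile_matrix <- function(tiles, path) {
  stopifnot(inherits(tiles, "tile_matrix"))
  out <- data.frame(tiles$tiles, context = tiles$context,
                    tiles$levels, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
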