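# Gene annotation: 7-column tab-delimited BED-like file
#   chrom, start, end, gene_id, score (unused), strand, cgi_flag (0/1)
# Coordinates are BED (0-based half-open). The TSS of a + strand gene is
# its start; for a - strand gene it is end - 1 (the last covered base),
# the standard convention.

#' Read a gene annotation table
#'
#' @param path Path to the 7-column tab-delimited annotation (no header):
#'   chrom, start, end, gene_id, score (ignored), strand (+/-),
#'   cgi_flag (0/1 marking CpG-island promoters).
#' @param assembly A `GenomeAssembly` used for bounds validation.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cgi_promoter` (logical), `tss` (0-based position) and
#'   `chrx` (logical, gene on the assembly's sex chromosome).
#' @export
read_genes <- function(path, assembly) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "score", "strand", "cgi_flag"))
  df <- as.data.frame(dt)
  validate_intervals(df, assembly, what = basename(path))
  if (anyDuplicated(df$gene_id))
    stop(basename(path), ": duplicate gene_id '",
         df$gene_id[duplicated(df$gene_id)][1], "'")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop(basename(path), " line ", which(bad)[1], ": strand must be + or -")
  data.frame(gene_id = as.character(df$gene_id),
             chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand,
             cgi_promoter = df$cgi_flag != 0,
             tss = ifelse(df$strand == "+", df$start, df$end - 1),
             chrx = df$chrom == assembly$sex_chromosome,
             stringsAsFactors = FALSE)
}

#' Write a gene annotation table
#' @param genes Gene table as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  data.table::fwrite(
    data.table::data.table(genes$chrom, format_bp(genes$start),
                           format_bp(genes$end), genes$gene_id, 0L,
                           genes$strand, as.integer(genes$cgi_promoter)),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive promoter windows around TSSs
#'
#' The promoter is the symmetric window TSS +/- `flank` bp, clipped to the
#' chromosome: `[tss - flank, tss + flank)`. The window is symmetric, so
#' strand does not change it.
#'
#' @param tss Numeric vector of 0-based TSS positions.
#' @param chrom Chromosome of each TSS (recycled if scalar).
#' @param assembly A `GenomeAssembly`.
#' @param flank Half-width in bp (default 2000).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), one row
#'   per TSS.
#' @examples
#' asm <- assembly(c(chr1 = 1e6))
#' make_promoter(10000, "chr1", asm)   # [8000, 12000)
#' make_promoter(1000, "chr1", asm)    # clipped: [0, 3000)
#' @export
make_promoter <- function(tss, chrom, assembly, flank = 2000) {
  stopifnot(inherits(assembly, "GenomeAssembly"), flank > 0)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(tss))
  unknown <- !chrom %in% names(assembly$lengths)
  if (any(unknown))
    stop("unknown chromosome '", chrom[which(unknown)[1]], "'")
  lens <- unname(assembly$lengths[chrom])
  if (any(tss < 0 | tss >= lens))
    stop("TSS position outside chromosome bounds")
  data.frame(chrom = unname(chrom),
             start = pmax(0, tss - flank),
             end = pmin(lens, tss + flank),
             stringsAsFactors = FALSE)
}

#' Promoter windows for a gene table
#'
#' @param genes Gene table as returned by [read_genes()].
#' @param assembly A `GenomeAssembly`.
#' @param flank Half-width in bp (default 2000).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_promoters <- function(genes, assembly, flank = 2000) {
  p <- make_promoter(genes$tss, genes$chrom, assembly, flank)
  cbind(gene_id = genes$gene_id, p, stringsAsFactors = FALSE)
}
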