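#' Construct a genome assembly
#'
#' An assembly is the coordinate substrate of every computation in the
#' package: an ordered set of named chromosomes with lengths, plus the name
#' of the X-equivalent sex chromosome used by the dosage analyses.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#'   Names are chromosome names; order is preserved.
#' @param sex_chromosome Name of the X-equivalent chromosome; must be one
#'   of `names(lengths)` when given. The default uses `"chrX"` if present
#'   and otherwise the last chromosome listed.
#' @return An object of class `GenomeAssembly`: a list with elements
#'   `lengths` (named numeric) and `sex_chromosome` (character scalar).
#' @examples
#' asm <- assembly(c(chr1 = 5e6, chr2 = 5e6, chrX = 3e6))
#' genome_length(asm)
#' @export
assembly <- function(lengths, sex_chromosome = NULL) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (is.null(sex_chromosome))
    sex_chromosome <- if ("chrX" %in% names(lengths)) "chrX"
                      else names(lengths)[length(lengths)]
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names: ",
         paste(unique(names(lengths)[duplicated(names(lengths))]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  if (!sex_chromosome %in% names(lengths))
    stop("sex_chromosome '", sex_chromosome, "' is not a chromosome of the assembly")
  structure(list(lengths = setNames(as.numeric(lengths), names(lengths)),
                 sex_chromosome = sex_chromosome),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$lengths), "chromosomes,",
      format(genome_length(x), big.mark = ","), "bp total; sex chromosome:",
      x$sex_chromosome, "\n")
  invisible(x)
}

#' Total genome length of an assembly
#' @param assembly A `GenomeAssembly`.
#' @return Numeric scalar, sum of chromosome lengths in bp.
#' @export
genome_length <- function(assembly) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  sum(assembly$lengths)
}

#' Read a chrom-sizes file
#'
#' Two tab-delimited columns: chromosome name, length in bp. No header.
#'
#' @param path Path to the chrom-sizes file.
#' @param sex_chromosome Name of the X-equivalent chromosome; defaults to
#'   `"chrX"` if present, otherwise the last chromosome listed.
#' @return A `GenomeAssembly`.
#' @export
read_assembly <- function(path, sex_chromosome = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1, numeric = 2))
  if (nrow(dt) == 0L) stop("empty chrom-sizes file: ", path)
  lens <- setNames(dt$length, dt$chrom)
  if (is.null(sex_chromosome))
    sex_chromosome <- if ("chrX" %in% names(lens)) "chrX" else names(lens)[length(lens)]
  assembly(lens, sex_chromosome)
}

#' Write a chrom-sizes file
#' @param assembly A `GenomeAssembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  data.table::fwrite(
    data.table::data.table(chrom = names(assembly$lengths),
                           length = format_bp(assembly$lengths)),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign a developmental stage to a gestational week
#'
#' Weeks 8-10 map to early, 11-15 to middle and 20-23 to late stage;
#' anything else (including the 16-19 gap, which no stage covers) maps to
#' `"unassigned"` and is excluded from stage-stratified analyses.
#'
#' @param week Integer vector of gestational weeks (>= 0).
#' @return Factor with levels `early`, `middle`, `late`, `unassigned`.
#' @examples
#' assign_stage(c(9, 14, 17, 23))
#' @export
assign_stage <- function(week) {
  if (any(!is.finite(week)) || any(week < 0))
    stop("gestational week must be a non-negative number")
  out <- rep("unassigned", length(week))
  out[week >= 8 & week <= 10] <- "early"
  out[week >= 11 & week <= 15] <- "middle"
  out[week >= 20 & week <= 23] <- "late"
  factor(out, levels = c("early", "middle", "late", "unassigned"))
}

#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome from position 0 without overlap; the last bin
#' of a chromosome may be shorter than `width`. Bin lengths sum exactly to
#' the genome length and bins never cross chromosome boundaries.
#'
#' @param assembly A `GenomeAssembly`.
#' @param width Bin width in bp (default 5000, the escapee-calling scale).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `bin_id`.
#' @export
bin_genome <- function(assembly, width = 5000) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (!is.finite(width) || width <= 0) stop("bin width must be > 0")
  pieces <- lapply(names(assembly$lengths), function(ch) {
    len <- assembly$lengths[[ch]]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin_id <- paste0(out$chrom, ":", format_bp(out$start), "-", format_bp(out$end))
  rownames(out) <- NULL
  out
}

# integers printed without scientific notation (coordinates can exceed 1e5)
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
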