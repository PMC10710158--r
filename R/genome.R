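#' Define a genome: chromosome names, lengths, placement and autosome status
#'
#' A `genome_def` fixes the coordinate frame for the whole pipeline: which
#' sequences are placed chromosomes (calls on anything else are dropped as
#' unplaced-scaffold calls) and which of those are autosomes (Vst is computed
#' on autosomal regions only, sidestepping sex-chromosome ploidy).
#'
#' @param chrom_names character vector of unique chromosome identifiers, in
#'   the order used for sorting all outputs.
#' @param chrom_lengths positive integer lengths in bp, one per chromosome.
#' @param placed chromosomes assigned to the assembly (default: names not
#'   matching a scaffold-like pattern `Un`, `random`, `scaf`, `NW_`, `JH`).
#' @param autosomes subset of `placed` (default: placed chromosomes that are
#'   not named like a sex or mitochondrial chromosome).
#' @return an object of class `genome_def` with fields `chrom_names`,
#'   `chrom_lengths` (named), `placed_set`, `autosome_set`.
#' @examples
#' g <- genome_def(c("chr1", "chrX", "chrUn_scaf1"), c(5e6, 3e6, 1e5))
#' g$autosome_set  # "chr1"
#' @export
genome_def <- function(chrom_names, chrom_lengths,
                       placed = NULL, autosomes = NULL) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names))
    .stopf("duplicated chromosome names in genome definition")
  if (length(chrom_lengths) != length(chrom_names))
    .stopf("chrom_lengths must have one entry per chromosome")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    .stopf("all chromosome lengths must be positive")
  if (is.null(placed)) {
    placed <- chrom_names[!grepl("Un|random|scaf|NW_|JH", chrom_names,
                                 ignore.case = TRUE)]
  }
  if (!all(placed %in% chrom_names))
    .stopf("placed set contains unknown chromosomes: %s",
           paste(setdiff(placed, chrom_names), collapse = ", "))
  if (is.null(autosomes)) {
    autosomes <- placed[!grepl("^(chr)?(X|Y|M|MT|W|Z)$", placed,
                               ignore.case = TRUE)]
  }
  if (!all(autosomes %in% placed))
    .stopf("autosome set must be a subset of the placed set")
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
      placed_set = placed,
      autosome_set = autosomes
    ),
    class = "genome_def"
  )
}

#' Read a genome definition from a chromosome-sizes file
#'
#' Standard two-column `chrom\tlength` TSV as produced by
#' `samtools faidx` / UCSC chrom.sizes.
#'
#' @param path path to the chromosome-sizes TSV.
#' @inheritParams genome_def
#' @return a [genome_def].
#' @export
read_chrom_sizes <- function(path, placed = NULL, autosomes = NULL) {
  if (!file.exists(path)) .stopf("chromosome sizes file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) .stopf("empty chromosome sizes file: %s", path)
  genome_def(tab$chrom, tab$length, placed = placed, autosomes = autosomes)
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("genome_def: %d sequences (%d placed, %d autosomes), %.1f Mb\n",
              length(x$chrom_names), length(x$placed_set),
              length(x$autosome_set), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

#' Total genome length in bp
#' @param genome a [genome_def].
#' @return numeric scalar, the sum of all chromosome lengths.
#' @export
genome_length <- function(genome) sum(genome$chrom_lengths)

#' Write a genome definition back to a chromosome-sizes TSV
#' @param genome a [genome_def].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = genome$chrom_names,
               length = unname(genome$chrom_lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
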