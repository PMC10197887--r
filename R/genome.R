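#' @importFrom methods is
#' @importFrom stats median p.adjust pchisq quantile rbinom rexp rnbinom
#'   rnorm rpois runif sd setNames cor complete.cases fisher.test rgamma
#' @importFrom utils read.delim write.table head
NULL

# Fixed vocabulary for the 96 single-base-substitution channels:
# six pyrimidine substitution types crossed with 4 x 4 flanking bases.
SBS_SUBS  <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' The 96 substitution channel labels in canonical order
#'
#' Channels are ordered substitution-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then by 5' flank and 3' flank (A, C, G, T each), giving labels such as
#' `"T[C>T]A"`. All catalogs and signature matrices in the package share
#' this order.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBS, function(s) {
    unlist(lapply(DNA_BASES, function(f5) {
      paste0(f5, "[", s, "]", DNA_BASES)
    }))
  }), use.names = FALSE)
}

#' Reverse complement of nucleotide strings
#'
#' Plain-character utility used for short context strings; whole contigs go
#' through [Biostrings::reverseComplement()] where performance matters.
#'
#' @param x Character vector over the alphabet A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and returned as a named character vector of
#' contigs, the in-memory genome representation used across the package.
#' Contig names are truncated at the first whitespace, as in FASTA headers.
#'
#' @param path Path to a (plain or gzipped) FASTA file.
#' @return Named character vector, one uppercase sequence per contig.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out)))
    stop("duplicate contig names in ", path)
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome))))
    stop("genome must be a named character vector of contig sequences")
  if (anyDuplicated(names(genome)))
    stop("genome contig names must be unique")
  invisible(genome)
}

# 1-based inclusive slice of one contig; positions outside [1, length]
# are an error, callers truncate windows themselves.
genome_slice <- function(genome, chrom, start, end) {
  seqs <- genome[[chrom]]
  if (is.null(seqs)) stop("contig not in genome: ", chrom)
  if (start < 1 || end > nchar(seqs) || start > end)
    stop(sprintf("slice [%d,%d] outside contig %s (length %d)",
                 start, end, chrom, nchar(seqs)))
  substr(seqs, start, end)
}

#' Reverse complement a whole genome
#'
#' Used by strand-symmetry checks: every contig is reverse complemented and
#' coordinates of features must be mapped to `L - pos + 1` by the caller.
#'
#' @param genome Named character vector of contig sequences.
#' @return Genome with each contig reverse complemented.
#' @export
revcomp_genome <- function(genome) {
  validate_genome(genome)
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(genome)))
  names(out) <- names(genome)
  out
}
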