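#' @import data.table
#' @importFrom stats rnorm rpois rbinom runif rmultinom setNames
#' @importFrom utils write.table read.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes mapped to the set of plain bases they stand for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of a DNA string
#'
#' Handles IUPAC ambiguity codes; case is upper-cased first.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  stringi::stri_reverse(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x))
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

#' Match an IUPAC mask along a sequence
#'
#' Slides `mask` along `sequence` and returns 1-based start positions where
#' the number of mask-position violations is at most `max_mismatch`. A mask
#' position matches a subject base iff the base belongs to the IUPAC set of
#' the mask code; an `N` (or any non-ACGT symbol) in the subject matches
#' nothing.
#'
#' @param sequence DNA string (subject).
#' @param mask IUPAC pattern string.
#' @param max_mismatch allowed number of non-matching mask positions.
#' @return integer vector of start positions (possibly empty).
#' @export
iupac_match <- function(sequence, mask, max_mismatch = 0L) {
  mask_chars <- seq_chars(mask)
  if (!all(mask_chars %in% names(IUPAC_SETS)))
    stop("mask contains non-IUPAC characters: ", mask)
  s <- seq_chars(sequence)
  L <- length(s)
  m <- length(mask_chars)
  if (L < m) return(integer(0))
  n_win <- L - m + 1L
  mm <- integer(n_win)
  for (k in seq_len(m)) {
    ok <- s[k:(n_win + k - 1L)] %in% IUPAC_SETS[[mask_chars[k]]]
    mm <- mm + !ok
  }
  which(mm <= max_mismatch)
}

# Hamming distance between two equal-length plain DNA strings.
hamming <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  sum(ca != cb)
}

# 1-based positions p such that sequence has T at p and A at p+1; the
# returned coordinate is the T. Callers wanting the A add 1.
ta_dinucleotides <- function(sequence) {
  s <- seq_chars(sequence)
  L <- length(s)
  if (L < 2L) return(integer(0))
  which(s[-L] == "T" & s[-1L] == "A")
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## ---- file writers -----------------------------------------------------

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), names(dss))
}

#' Write paired reads as Phred+33 FASTQ
#'
#' Qualities are constant (`I`, Q40), matching the simulator's error model.
#'
#' @param reads data.frame with columns `id`, `seq1`, `seq2`.
#' @param path1,path2 output FASTQ files for the two mates.
#' @export
write_fastq <- function(reads, path1, path2) {
  wr <- function(seqs, ids, path) {
    if (length(seqs) == 0L) {
      file.create(path)
      return(invisible())
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                                qualities = quals)
  }
  wr(reads$seq1, paste0(reads$id, "/1"), path1)
  wr(reads$seq2, paste0(reads$id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read a FASTQ file into a character vector of sequences
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L) return(character(0))
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), names(dss))
}

#' Write a GFF3 file
#'
#' @param df data.frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `attributes`.
#' @param path output file.
#' @export
write_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     df$seqid, df$source, df$type,
                     as.integer(df$start), as.integer(df$end),
                     as.character(df$score), df$strand,
                     as.character(df$phase), df$attributes)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a data.frame as TSV with header
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
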