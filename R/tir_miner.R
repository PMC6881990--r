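#' Parameters for structural TIR/TSD element mining
#'
#' Defaults mirror the mariner-style screen used for carrot elements:
#' a 13-nt IUPAC TIR mask, a TA target-site-duplication mask, no mask
#' mismatches, identical TSD copies, and at most one mismatch between an
#' element's own 5' and 3' TIRs.
#'
#' @param tir_mask IUPAC mask matched at the 5' terminus (and, reverse
#'   complemented, at the 3' terminus).
#' @param tsd_mask IUPAC mask for the duplicated target site.
#' @param tir_mask_mismatches,tsd_mask_mismatches allowed mask violations.
#' @param tsd_seq_mismatches allowed mismatches between the two TSD copies.
#' @param tir_seq_mismatches allowed mismatches between the element's 5' TIR
#'   and the reverse complement of its 3' TIR.
#' @param min_length,max_length element span bounds (TIR to TIR, bp).
#' @param extend_tirs extend reported TIR sequences inward to the maximal
#'   mutually reverse-complementary stretch beyond the mask.
#' @param dedupe `"all"` reports every candidate span; `"longest"` applies
#'   greedy longest-first non-overlap selection.
#' @return validated list of class `tir_search_params`.
#' @export
tir_search_params <- function(tir_mask = "CTCCCTYYSKYMC",
                              tsd_mask = "TA",
                              tir_mask_mismatches = 0L,
                              tsd_mask_mismatches = 0L,
                              tsd_seq_mismatches = 0L,
                              tir_seq_mismatches = 1L,
                              min_length = 50L,
                              max_length = 6000L,
                              extend_tirs = FALSE,
                              dedupe = c("all", "longest")) {
  dedupe <- match.arg(dedupe)
  if (!nzchar(tir_mask) || !nzchar(tsd_mask)) stop("masks must be non-empty")
  for (m in c(tir_mask, tsd_mask))
    if (!all(seq_chars(m) %in% names(IUPAC_SETS)))
      stop("non-IUPAC character in mask: ", m)
  if (tir_mask_mismatches < 0L || tsd_mask_mismatches < 0L ||
      tsd_seq_mismatches < 0L || tir_seq_mismatches < 0L)
    stop("mismatch budgets must be >= 0")
  if (min_length > max_length) stop("min_length must be <= max_length")
  structure(list(tir_mask = toupper(tir_mask), tsd_mask = toupper(tsd_mask),
                 tir_mask_mismatches = as.integer(tir_mask_mismatches),
                 tsd_mask_mismatches = as.integer(tsd_mask_mismatches),
                 tsd_seq_mismatches = as.integer(tsd_seq_mismatches),
                 tir_seq_mismatches = as.integer(tir_seq_mismatches),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 extend_tirs = isTRUE(extend_tirs), dedupe = dedupe),
            class = "tir_search_params")
}

#' Mine TIR/TSD-bounded elements from assembled sequence
#'
#' Reports every span whose 5' end matches the TIR mask, whose 3' end
#' matches the reverse-complemented mask, whose own TIRs are mutually
#' reverse-complementary within the configured budget, and which is framed
#' by duplicated target sites matching the TSD mask. Coordinates are 1-based
#' inclusive and exclude the TSDs. Subject `N`s never match.
#'
#' @param sequence DNA string to scan.
#' @param params a [tir_search_params()].
#' @param seqname sequence name carried into the output.
#' @return data.frame with columns `chromosome`, `start`, `end`, `length`,
#'   `tir5`, `tir3`, `tsd_left`, `tsd_right`, `tsd_ok`, `strand`.
#' @export
find_tir_elements <- function(sequence, params = tir_search_params(),
                              seqname = "seq1") {
  stopifnot(inherits(params, "tir_search_params"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  m <- nchar(params$tir_mask)
  tl <- nchar(params$tsd_mask)
  empty <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      tir5 = character(0), tir3 = character(0),
                      tsd_left = character(0), tsd_right = character(0),
                      tsd_ok = logical(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (L < 2L * m) return(empty)
  fw <- iupac_match(sequence, params$tir_mask, params$tir_mask_mismatches)
  rc <- iupac_match(sequence, revcomp(params$tir_mask),
                    params$tir_mask_mismatches)
  if (length(fw) == 0L || length(rc) == 0L) return(empty)
  rc_end <- rc + m - 1L

  # pair 5' starts with 3' ends under the length bounds
  pairs <- data.table::CJ(i = fw, j = rc_end)
  pairs <- pairs[j - i + 1L >= pmax(params$min_length, 2L * m) &
                 j - i + 1L <= params$max_length]
  if (nrow(pairs) == 0L) return(empty)

  keep <- logical(nrow(pairs))
  tir5 <- tir3 <- tsd_l <- tsd_r <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (i - tl < 1L || j + tl > L) next
    t5 <- substring(sequence, i, i + m - 1L)
    t3 <- substring(sequence, j - m + 1L, j)
    if (hamming(t5, revcomp(t3)) > params$tir_seq_mismatches) next
    sl <- substring(sequence, i - tl, i - 1L)
    sr <- substring(sequence, j + 1L, j + tl)
    if (length(iupac_match(sl, params$tsd_mask,
                           params$tsd_mask_mismatches)) == 0L) next
    if (length(iupac_match(sr, params$tsd_mask,
                           params$tsd_mask_mismatches)) == 0L) next
    if (hamming(sl, sr) > params$tsd_seq_mismatches) next
    if (params$extend_tirs) {
      s <- seq_chars(substring(sequence, i, j))
      w <- length(s)
      k <- m
      while (k < floor(w / 2) &&
             s[k + 1L] == IUPAC_COMPLEMENT[[s[w - k]]]) k <- k + 1L
      t5 <- paste(s[1:k], collapse = "")
      t3 <- paste(s[(w - k + 1L):w], collapse = "")
    }
    keep[r] <- TRUE
    tir5[r] <- t5; tir3[r] <- t3; tsd_l[r] <- sl; tsd_r[r] <- sr
  }
  if (!any(keep)) return(empty)
  out <- data.frame(chromosome = seqname, start = pairs$i[keep],
                    end = pairs$j[keep],
                    length = pairs$j[keep] - pairs$i[keep] + 1L,
                    tir5 = tir5[keep], tir3 = tir3[keep],
                    tsd_left = tsd_l[keep], tsd_right = tsd_r[keep],
                    tsd_ok = TRUE, strand = "+", stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (params$dedupe == "longest" && nrow(out) > 1L) {
    ord <- order(-out$length, out$start)
    chosen <- integer(0)
    for (r in ord) {
      if (!length(chosen) ||
          all(out$end[r] < out$start[chosen] | out$start[r] > out$end[chosen]))
        chosen <- c(chosen, r)
    }
    out <- out[sort(chosen), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Mine every chromosome of a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param params a [tir_search_params()].
#' @return row-bound [find_tir_elements()] output.
#' @export
mine_genome <- function(genome, params = tir_search_params()) {
  res <- lapply(names(genome), function(ch)
    find_tir_elements(genome[[ch]], params, seqname = ch))
  do.call(rbind, res)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' Reports every ATG with its nearest in-frame downstream stop codon on both
#' strands (nested starts sharing a stop are all reported), in genomic
#' coordinates including the stop codon.
#'
#' @param sequence DNA string.
#' @param min_codons minimum ORF length in codons (stop included).
#' @return data.frame with `start`, `end`, `strand`, `frame`, `n_codons`,
#'   `protein` (stop excluded).
#' @export
find_orfs <- function(sequence, min_codons = 100L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  code <- Biostrings::GENETIC_CODE
  one_strand <- function(s, strand) {
    res <- list()
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < 1L) next
      cs <- f + 3L * (seq_len(n_cod) - 1L) + 1L
      codons <- substring(s, cs, cs + 2L)
      stops <- which(codons %in% STOP_CODONS)
      atgs <- which(codons == "ATG")
      if (!length(stops) || !length(atgs)) next
      for (a in atgs) {
        b <- stops[stops >= a]
        if (!length(b)) next
        b <- b[1]
        if (b - a + 1L < min_codons) next
        p1 <- cs[a]; p2 <- cs[b] + 2L
        prot <- if (b > a)
          paste(code[codons[a:(b - 1L)]], collapse = "") else ""
        gs <- if (strand == "+") p1 else L - p2 + 1L
        ge <- if (strand == "+") p2 else L - p1 + 1L
        res[[length(res) + 1L]] <- data.frame(
          start = gs, end = ge, strand = strand, frame = f,
          n_codons = b - a + 1L, protein = prot, stringsAsFactors = FALSE)
      }
    }
    res
  }
  res <- c(one_strand(sequence, "+"), one_strand(revcomp(sequence), "-"))
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_codons = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein for the mariner DD39D catalytic triad
#'
#' Looks for aspartates at indices i < j < k with `k = j + 40` (39
#' intervening residues) and `j - i - 1` inside the configured first-spacer
#' range; the first such triple in (i, j) scan order is reported.
#'
#' @param protein amino-acid string.
#' @param first_spacer length-2 range of intervening residues between the
#'   first and second aspartate.
#' @return list with `ddd_motif` (`"complete"` or `"absent"`), `positions`
#'   (the triple, or NULL) and `protein_length`.
#' @export
scan_ddd_motif <- function(protein, first_spacer = c(1L, 150L)) {
  p <- seq_chars(protein)
  ds <- which(p == "D")
  for (i in ds) {
    for (j in ds[ds > i]) {
      spacer <- j - i - 1L
      if (spacer < first_spacer[1] || spacer > first_spacer[2]) next
      k <- j + 40L
      if (k <= length(p) && p[k] == "D")
        return(list(ddd_motif = "complete", positions = c(i, j, k),
                    protein_length = length(p)))
    }
  }
  list(ddd_motif = "absent", positions = NULL, protein_length = length(p))
}

#' Triage a mined element into MITE-like, autonomous candidate or truncated
#'
#' An element is an `autonomous_candidate` if it contains an ORF of at least
#' `min_codons` whose protein carries a complete DD39D motif; `mite_like` if
#' it is below 800 bp with no such ORF; `truncated` otherwise (a long
#' element, or one with substantial coding capacity but an incomplete
#' motif).
#'
#' @param element element sequence, or a list/row with `start` and `end`
#'   used to cut `sequence`.
#' @param sequence optional chromosome sequence when `element` gives
#'   coordinates.
#' @param min_codons minimum ORF size treated as coding capacity.
#' @param first_spacer DD39D first-spacer range, see [scan_ddd_motif()].
#' @return list with `class`, `length`, `orf` (best ORF row or NULL) and
#'   `motif`.
#' @export
classify_element <- function(element, sequence = NULL, min_codons = 100L,
                             first_spacer = c(1L, 150L)) {
  seq <- if (is.character(element) && length(element) == 1L) element
  else {
    if (is.null(sequence)) stop("coordinates given without a sequence")
    substring(sequence, element$start, element$end)
  }
  len <- nchar(seq)
  orfs <- find_orfs(seq, min_codons = min_codons)
  best <- NULL; motif <- NULL
  if (nrow(orfs)) {
    for (r in order(-orfs$n_codons)) {
      sc <- scan_ddd_motif(orfs$protein[r], first_spacer)
      if (sc$ddd_motif == "complete") {
        best <- orfs[r, , drop = FALSE]; motif <- sc
        break
      }
    }
    if (is.null(best)) {
      best <- orfs[which.max(orfs$n_codons), , drop = FALSE]
      motif <- scan_ddd_motif(best$protein, first_spacer)
    }
  }
  cls <- if (!is.null(motif) && motif$ddd_motif == "complete")
    "autonomous_candidate"
  else if (nrow(orfs) == 0L && len < 800L) "mite_like"
  else "truncated"
  list(class = cls, length = len, orf = best, motif = motif)
}

#' Extract the terminal sequences of an element
#'
#' @param element element sequence.
#' @param n terminal window (nt); the element must be at least `2n` long.
#' @return list with `five_prime` and `three_prime` windows.
#' @export
terminal_sequences <- function(element, n) {
  L <- nchar(element)
  if (L < 2L * n) stop("element shorter than twice the terminal window")
  list(five_prime = substring(element, 1L, n),
       three_prime = substring(element, L - n + 1L, L))
}
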