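#' Parameters for junction-read insertion calling
#'
#' The defaults re-interpret the published RelocaTE settings for this
#' from-scratch matcher: a minimum terminal overlap of 12 bp with the family
#' consensus (`-bm 12`), an exact 11-bp seed (`-bt 11`), a 0.2 mismatch
#' fraction cap on the TE-matching portion (`-m 0.2`), and a single
#' supporting read (`-r 1`). This is a re-interpretation of those
#' parameters, not an emulation of the original tool.
#'
#' @param min_te_match minimum terminal overlap with the consensus (bp).
#' @param seed_size exact seed length anchoring the consensus terminus (bp).
#' @param mismatch_rate_max mismatch fraction tolerated in the TE-matching
#'   portion (and in flank placement).
#' @param min_support_reads minimum junction reads per call.
#' @param flank_seed exact seed length for placing trimmed flanks on the
#'   reference (bp); flanks shorter than this are discarded.
#' @param unique_mapping_required discard flanks with more than one best
#'   placement (the surrogate for repetitive-region read filtering).
#' @return validated list of class `caller_params`.
#' @export
caller_params <- function(min_te_match = 12L, seed_size = 11L,
                          mismatch_rate_max = 0.2, min_support_reads = 1L,
                          flank_seed = 20L, unique_mapping_required = TRUE) {
  if (min_te_match < seed_size) stop("min_te_match must be >= seed_size")
  if (mismatch_rate_max < 0 || mismatch_rate_max >= 1)
    stop("mismatch_rate_max must lie in [0,1)")
  if (min_support_reads < 1L) stop("min_support_reads must be >= 1")
  structure(list(min_te_match = as.integer(min_te_match),
                 seed_size = as.integer(seed_size),
                 mismatch_rate_max = mismatch_rate_max,
                 min_support_reads = as.integer(min_support_reads),
                 flank_seed = as.integer(flank_seed),
                 unique_mapping_required = isTRUE(unique_mapping_required)),
            class = "caller_params")
}

# Flatten simulate_reads() output (or a plain vector) into a named vector.
pool_reads <- function(reads) {
  if (is.data.frame(reads)) {
    out <- c(setNames(reads$seq1, paste0(reads$id, "/1")),
             setNames(reads$seq2, paste0(reads$id, "/2")))
  } else {
    out <- reads
    if (is.null(names(out)) && length(out))
      names(out) <- sprintf("r%07d", seq_along(out))
  }
  out[nchar(out) > 0L]
}

# Seed positions of `pattern` in each read; returns data.table(read, pos).
seed_hits <- function(dss, pattern) {
  mi <- Biostrings::vmatchPattern(pattern, dss)
  counts <- S4Vectors::elementNROWS(mi)
  if (sum(counts) == 0L)
    return(data.table::data.table(read = integer(0), pos = integer(0)))
  data.table::data.table(read = rep(seq_along(dss), counts),
                         pos = IRanges::start(unlist(mi, use.names = FALSE)))
}

#' Match reads against a family consensus and trim the TE portion
#'
#' A read qualifies when one of its ends overlaps a consensus terminus by at
#' least `min_te_match` bases (anchored by an exact `seed_size` seed on the
#' terminus) with at most `mismatch_rate_max` mismatch fraction over the
#' overlap. The TE portion is removed; the remaining genomic fragment is the
#' junction flank. Both read orientations are examined; reads matching
#' entirely within the consensus are consumed but yield no junction. When
#' several terminal matches qualify, the longest overlap wins.
#'
#' @param reads character vector of read sequences (named), or a
#'   [simulate_reads()] data frame.
#' @param consensus family consensus sequence.
#' @param params a [caller_params()].
#' @return data.frame with `read_id`, `side` (`five_prime` = flank precedes
#'   the element in consensus orientation), `flank`, `te_overlap`,
#'   `mismatches`.
#' @export
match_and_trim <- function(reads, consensus, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  reads <- pool_reads(reads)
  cons <- toupper(consensus)
  clen <- nchar(cons)
  ss <- params$seed_size
  if (clen < params$min_te_match)
    stop("consensus shorter than min_te_match")
  empty <- data.frame(read_id = character(0), side = character(0),
                      flank = character(0), te_overlap = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  seed5 <- substring(cons, 1L, ss)
  seed3 <- substring(cons, clen - ss + 1L, clen)

  dss_f <- Biostrings::DNAStringSet(unname(reads))
  dss_r <- Biostrings::reverseComplement(dss_f)
  rl <- nchar(reads)
  cand <- list()
  for (ori in c("f", "r")) {
    seqs <- if (ori == "f") reads else setNames(as.character(dss_r),
                                                names(reads))
    dss <- if (ori == "f") dss_f else dss_r
    h5 <- seed_hits(dss, seed5)
    if (nrow(h5)) {
      len <- rl[h5$read]
      te_len <- len - h5$pos + 1L
      ok <- te_len <= clen & te_len >= params$min_te_match
      h5 <- h5[ok]; te_len <- te_len[ok]
      if (nrow(h5)) {
        te_read <- substring(seqs[h5$read], h5$pos, rl[h5$read])
        te_cons <- substring(cons, 1L, te_len)
        mm <- mapply(hamming, te_read, te_cons, USE.NAMES = FALSE)
        ok <- mm <= params$mismatch_rate_max * te_len & h5$pos > 1L
        if (any(ok))
          cand[[length(cand) + 1L]] <- data.table::data.table(
            read = h5$read[ok], side = "five_prime",
            flank = substring(seqs[h5$read[ok]], 1L, h5$pos[ok] - 1L),
            te_overlap = te_len[ok], mismatches = mm[ok])
      }
    }
    h3 <- seed_hits(dss, seed3)
    if (nrow(h3)) {
      te_len <- h3$pos + ss - 1L
      ok <- te_len <= clen & te_len >= params$min_te_match &
        (h3$pos + ss - 1L) < rl[h3$read]
      h3 <- h3[ok]; te_len <- te_len[ok]
      if (nrow(h3)) {
        te_read <- substring(seqs[h3$read], 1L, te_len)
        te_cons <- substring(cons, clen - te_len + 1L, clen)
        mm <- mapply(hamming, te_read, te_cons, USE.NAMES = FALSE)
        ok <- mm <= params$mismatch_rate_max * te_len
        if (any(ok))
          cand[[length(cand) + 1L]] <- data.table::data.table(
            read = h3$read[ok], side = "three_prime",
            flank = substring(seqs[h3$read[ok]], te_len[ok] + 1L,
                              rl[h3$read[ok]]),
            te_overlap = te_len[ok], mismatches = mm[ok])
      }
    }
  }
  if (!length(cand)) return(empty)
  dt <- data.table::rbindlist(cand)
  dt <- dt[nchar(flank) > 0L]
  if (nrow(dt) == 0L) return(empty)
  # best terminal match per read: longest overlap, then fewest mismatches
  data.table::setorder(dt, read, -te_overlap, mismatches)
  dt <- dt[!duplicated(read)]
  data.frame(read_id = names(reads)[dt$read], side = dt$side,
             flank = dt$flank, te_overlap = dt$te_overlap,
             mismatches = dt$mismatches, stringsAsFactors = FALSE)
}

#' Build an exact k-mer index of a reference genome
#'
#' @param reference named character vector of chromosome sequences.
#' @param k k-mer size (typically `flank_seed`).
#' @return keyed data.table with columns `kmer`, `chrom`, `pos`.
#' @export
build_flank_index <- function(reference, k) {
  parts <- lapply(names(reference), function(ch) {
    L <- nchar(reference[[ch]])
    if (L < k) return(NULL)
    data.table::data.table(kmer = substring(reference[[ch]],
                                            1:(L - k + 1L), k:L),
                           chrom = ch, pos = 1:(L - k + 1L))
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, kmer)
  attr(idx, "k") <- as.integer(k)
  idx
}

#' Place junction flanks on the reference genome
#'
#' Each flank is placed by an exact junction-adjacent seed of `flank_seed`
#' bases extended over the full flank on both strands, tolerating up to
#' `mismatch_rate_max` mismatch fraction. Flanks with more than one best
#' placement are discarded when unique mapping is required. The implied
#' insertion position is the A of the reference TA target site: a junction
#' on the left side of the element maps to the flank's right end, one on the
#' right side to the base after the flank's left end.
#'
#' @param junctions [match_and_trim()] output (optionally with a `family`
#'   column).
#' @param reference named character vector of chromosome sequences.
#' @param params a [caller_params()].
#' @param index optional [build_flank_index()] result to reuse.
#' @return data.frame with `read_id`, `family`, `chrom`, `position`,
#'   `junction` (`left`/`right`), `mismatches`; attribute `n_discarded`
#'   counts flanks dropped as short, unplaced or multi-mapping.
#' @export
map_flanks <- function(junctions, reference, params = caller_params(),
                       index = NULL) {
  stopifnot(inherits(params, "caller_params"))
  k <- params$flank_seed
  if (is.null(index)) index <- build_flank_index(reference, k)
  if (!identical(attr(index, "k"), k))
    stop("flank index built with a different k")
  empty <- data.frame(read_id = character(0), family = character(0),
                      chrom = character(0), position = integer(0),
                      junction = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(junctions) == 0L) {
    attr(empty, "n_discarded") <- 0L
    return(empty)
  }
  if (is.null(junctions$family)) junctions$family <- NA_character_
  flen <- nchar(junctions$flank)
  short <- flen < k
  n_disc <- sum(short)
  if (n_disc) message(n_disc, " flank(s) shorter than the seed discarded")
  jx <- junctions[!short, , drop = FALSE]
  flen <- flen[!short]
  if (nrow(jx) == 0L) {
    attr(empty, "n_discarded") <- n_disc
    return(empty)
  }
  s_off <- ifelse(jx$side == "five_prime", flen - k + 1L, 1L)
  seed <- substring(jx$flank, s_off, s_off + k - 1L)
  q <- data.table::data.table(qid = seq_len(nrow(jx)), seed = seed,
                              rcseed = revcomp(seed), flen = flen,
                              s_off = s_off)
  hit_f <- index[q, on = c(kmer = "seed"), nomatch = NULL,
                 .(qid = i.qid, chrom = x.chrom, pos = x.pos, strand = "+",
                   flen = i.flen, s_off = i.s_off)]
  hit_r <- index[q, on = c(kmer = "rcseed"), nomatch = NULL,
                 .(qid = i.qid, chrom = x.chrom, pos = x.pos, strand = "-",
                   flen = i.flen, s_off = i.s_off)]
  hits <- rbind(hit_f, hit_r)
  if (nrow(hits) == 0L) {
    attr(empty, "n_discarded") <- n_disc + nrow(jx)
    return(empty)
  }
  r_off <- hits$flen - hits$s_off - k + 2L
  hits$start <- ifelse(hits$strand == "+", hits$pos - hits$s_off + 1L,
                       hits$pos - r_off + 1L)
  hits$end <- hits$start + hits$flen - 1L
  chrom_len <- setNames(nchar(reference), names(reference))
  hits <- hits[hits$start >= 1L & hits$end <= chrom_len[hits$chrom]]
  if (nrow(hits) == 0L) {
    attr(empty, "n_discarded") <- n_disc + nrow(jx)
    return(empty)
  }
  ref_seq <- character(nrow(hits))
  for (ch in unique(hits$chrom)) {
    rows <- which(hits$chrom == ch)
    ref_seq[rows] <- substring(reference[[ch]], hits$start[rows],
                               hits$end[rows])
  }
  qseq <- ifelse(hits$strand == "+", jx$flank[hits$qid],
                 revcomp(jx$flank[hits$qid]))
  hits$mm <- mapply(hamming, ref_seq, qseq, USE.NAMES = FALSE)
  hits <- hits[hits$mm <= params$mismatch_rate_max * hits$flen]
  if (nrow(hits) == 0L) {
    attr(empty, "n_discarded") <- n_disc + nrow(jx)
    return(empty)
  }
  # keep unique best placements
  data.table::setorder(hits, qid, mm)
  best <- hits[, .SD[mm == mm[1L]], by = qid]
  n_per <- best[, .N, by = qid]
  if (params$unique_mapping_required) {
    multi <- n_per$qid[n_per$N > 1L]
    best <- best[!qid %in% multi]
  } else {
    best <- best[!duplicated(qid)]
  }
  n_disc <- n_disc + (nrow(jx) - data.table::uniqueN(best$qid))
  if (nrow(best) == 0L) {
    attr(empty, "n_discarded") <- n_disc
    return(empty)
  }
  side <- jx$side[best$qid]
  left <- (side == "five_prime") == (best$strand == "+")
  out <- data.frame(read_id = jx$read_id[best$qid],
                    family = jx$family[best$qid],
                    chrom = best$chrom,
                    position = ifelse(left, best$end, best$start + 1L),
                    junction = ifelse(left, "left", "right"),
                    mismatches = best$mm, stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- n_disc
  out
}

#' Call non-reference MITE insertions for one accession
#'
#' Runs consensus matching and trimming for every family, assigns each
#' junction read to the family with the longest qualifying terminal match
#' (equal-length ties are dropped), places the trimmed flanks uniquely on
#' the reference, validates the TA target-site convention against the
#' reference sequence, and reports one call per (chromosome, position,
#' family) with left/right junction support.
#'
#' @param reads read sequences (vector or [simulate_reads()] frame).
#' @param families list of `mite_family` objects (or named character vector
#'   of consensus sequences).
#' @param reference named character vector of chromosome sequences.
#' @param params a [caller_params()].
#' @param index optional [build_flank_index()] result to reuse.
#' @return data.frame with `chrom`, `position`, `family`, `left_support`,
#'   `right_support`; attributes `n_family_ties` and `n_ta_suppressed`.
#' @export
call_insertions <- function(reads, families, reference,
                            params = caller_params(), index = NULL) {
  stopifnot(inherits(params, "caller_params"))
  reads <- pool_reads(reads)
  cons <- if (is.list(families))
    setNames(vapply(families, `[[`, character(1), "consensus"),
             vapply(families, `[[`, character(1), "name"))
  else families
  empty <- data.frame(chrom = character(0), position = integer(0),
                      family = character(0), left_support = integer(0),
                      right_support = integer(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) {
    attr(empty, "n_family_ties") <- 0L
    attr(empty, "n_ta_suppressed") <- 0L
    return(empty)
  }
  jx <- list()
  for (fam in names(cons)) {
    j <- match_and_trim(reads, cons[[fam]], params)
    if (nrow(j)) {
      j$family <- fam
      jx[[fam]] <- j
    }
  }
  n_ties <- 0L
  if (!length(jx)) {
    attr(empty, "n_family_ties") <- 0L
    attr(empty, "n_ta_suppressed") <- 0L
    return(empty)
  }
  jx <- data.table::rbindlist(jx)
  # family assignment: longest qualifying terminal match wins, ties dropped
  data.table::setorder(jx, read_id, -te_overlap)
  best_len <- jx[, .(best = te_overlap[1L],
                     n_best = sum(te_overlap == te_overlap[1L])),
                 by = read_id]
  n_ties <- sum(best_len$n_best > 1L)
  if (n_ties) message(n_ties, " junction read(s) dropped as family ties")
  keep_ids <- best_len$read_id[best_len$n_best == 1L]
  jx <- jx[!duplicated(read_id)][read_id %in% keep_ids]
  placed <- map_flanks(as.data.frame(jx), reference, params, index)
  if (nrow(placed) == 0L) {
    attr(empty, "n_family_ties") <- n_ties
    attr(empty, "n_ta_suppressed") <- 0L
    return(empty)
  }
  # TA invariant: reference bases at (position-1, position) must be T, A
  ta_ok <- vapply(seq_len(nrow(placed)), function(i) {
    p <- placed$position[i]
    p >= 2L && substring(reference[[placed$chrom[i]]], p - 1L, p) == "TA"
  }, logical(1))
  n_sup <- sum(!ta_ok)
  if (n_sup) message(n_sup, " junction placement(s) suppressed at non-TA sites")
  placed <- placed[ta_ok, , drop = FALSE]
  if (nrow(placed) == 0L) {
    attr(empty, "n_family_ties") <- n_ties
    attr(empty, "n_ta_suppressed") <- n_sup
    return(empty)
  }
  dt <- data.table::as.data.table(placed)
  calls <- dt[, .(left_support = sum(junction == "left"),
                  right_support = sum(junction == "right")),
              by = .(chrom, position, family)]
  calls <- calls[left_support + right_support >= params$min_support_reads]
  data.table::setorder(calls, chrom, position, family)
  out <- as.data.frame(calls)
  attr(out, "n_family_ties") <- n_ties
  attr(out, "n_ta_suppressed") <- n_sup
  out
}

count_probe <- function(dss, probe) {
  sum(Biostrings::vcountPattern(probe, dss)) +
    sum(Biostrings::vcountPattern(revcomp(probe), dss))
}

#' Genotype reference-assembly insertion sites from reads
#'
#' For each reference-borne element (spanned by duplicated TA target sites),
#' occupied-junction evidence is counted as reads crossing either
#' flank/element boundary, and empty evidence as reads spanning the
#' reconstructed empty allele (flank-TA-flank) with `flank_seed` bases on
#' each side. A site is `occupied` with only occupied evidence, `empty` with
#' only empty evidence, `heterozygous` with both at or above
#' `min_support_reads`, and `no_call` with neither.
#'
#' @param reads read sequences (vector or [simulate_reads()] frame).
#' @param sites data.frame with `chromosome`, `start`, `end` element spans
#'   (TIR to TIR, TSDs excluded) as returned by [find_tir_elements()].
#' @param reference named character vector of chromosome sequences.
#' @param params a [caller_params()].
#' @return `sites` with added `occupied_support`, `empty_support`, `status`.
#' @export
genotype_reference_sites <- function(reads, sites, reference,
                                     params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  reads <- pool_reads(reads)
  dss <- Biostrings::DNAStringSet(unname(reads))
  fs <- params$flank_seed
  occ <- emp <- integer(nrow(sites))
  status <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chromosome[i]
    s <- sites$start[i]; e <- sites$end[i]
    seq <- reference[[ch]]
    if (substring(seq, s - 2L, s - 1L) != "TA" ||
        substring(seq, e + 1L, e + 2L) != "TA")
      stop("site ", i, " lacks the duplicated TA target-site context")
    left_probe <- substring(seq, s - fs, s + fs - 1L)
    right_probe <- substring(seq, e - fs + 1L, e + fs)
    empty_probe <- paste0(substring(seq, s - 2L - fs, s - 1L),
                          substring(seq, e + 3L, e + 2L + fs))
    occ[i] <- count_probe(dss, left_probe) + count_probe(dss, right_probe)
    emp[i] <- count_probe(dss, empty_probe)
    status[i] <- if (occ[i] >= params$min_support_reads &&
                     emp[i] >= params$min_support_reads) "heterozygous"
    else if (occ[i] >= params$min_support_reads) "occupied"
    else if (emp[i] >= params$min_support_reads) "empty"
    else "no_call"
  }
  sites$occupied_support <- occ
  sites$empty_support <- emp
  sites$status <- status
  sites
}

#' Screen reads for the presence of an element's internal sequence
#'
#' Presence requires at least `min_hit_reads` reads matching the internal
#' (TIR-stripped) query at `min_identity` or better over at least half the
#' read. Stripping the TIRs from the query prevents cross-family false
#' positives from MITEs sharing the element's termini.
#'
#' @param reads read sequences (vector or [simulate_reads()] frame).
#' @param query internal element sequence, TIRs already removed.
#' @param min_hit_reads hit-count threshold for presence.
#' @param min_identity identity threshold over the matched half-read.
#' @return list with `present` (logical) and `n_hits`.
#' @export
detect_element_presence <- function(reads, query, min_hit_reads = 5L,
                                    min_identity = 0.9) {
  reads <- pool_reads(reads)
  query <- toupper(query)
  if (length(reads) == 0L) return(list(present = FALSE, n_hits = 0L))
  rl <- max(nchar(reads))
  if (nchar(query) < rl)
    stop("internal query shorter than the read length")
  dss <- Biostrings::DNAStringSet(unname(reads))
  k <- 15L
  L <- nchar(query)
  kmers <- unique(substring(query, 1:(L - k + 1L), k:(L)))
  pd <- Biostrings::PDict(kmers)
  hit_f <- which(Biostrings::vcountPDict(pd, dss, collapse = 2) > 0L)
  hit_r <- which(Biostrings::vcountPDict(
    pd, Biostrings::reverseComplement(dss), collapse = 2) > 0L)
  cand <- union(hit_f, hit_r)
  qdna <- Biostrings::DNAString(query)
  n_hits <- 0L
  for (i in cand) {
    r <- as.character(dss[[i]])
    half <- nchar(r) %/% 2L
    cap <- floor((1 - min_identity) * half)
    pieces <- c(substring(r, 1L, half),
                substring(r, nchar(r) - half + 1L, nchar(r)))
    pieces <- c(pieces, revcomp(pieces))
    hit <- FALSE
    for (p in pieces) {
      if (Biostrings::countPattern(p, qdna, max.mismatch = cap) > 0L) {
        hit <- TRUE
        break
      }
    }
    if (hit) n_hits <- n_hits + 1L
  }
  list(present = n_hits >= min_hit_reads, n_hits = n_hits)
}
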