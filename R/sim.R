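#' Simulation configuration for a MITE-bearing population
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the desk-scale study population used throughout the
#' package: 10 accessions over 2 x 200 kb chromosomes, 3 MITE families with
#' 31-nt TIRs and TA target-site duplications, a mean of 15 insertions per
#' accession per family, 30% unique (single-accession) sites, 5 parallel
#' insertion loci, and error-free 20x paired 100-bp reads.
#'
#' @param seed integer master seed; every downstream `simulate_*` call
#'   derives its randomness from it.
#' @param n_chromosomes,chrom_length reference shape.
#' @param n_genes total genes across chromosomes.
#' @param gene_span length-2 range (bp) of gene spans.
#' @param exons_per_gene length-2 range of exon counts.
#' @param utr_length length-2 range (bp) for each UTR.
#' @param n_families number of MITE families.
#' @param element_length length-2 range (bp) of family consensus lengths;
#'   must stay below 800 bp (the MITE size bound).
#' @param tir_length terminal inverted repeat length (nt).
#' @param at_fraction background A+T fraction in `[0,1]`.
#' @param n_accessions population size.
#' @param mean_insertions mean insertions per accession per family.
#' @param fraction_unique fraction of insertion-site rows present in exactly
#'   one accession.
#' @param n_parallel_loci number of positions carrying different families in
#'   different accessions (insertional hotspots).
#' @param ploidy_model `"haploid"` or `"diploid"` (two pooled haplotypes;
#'   heterozygous means present on exactly one).
#' @param coverage fold sequencing coverage.
#' @param read_length read length (bp).
#' @param insert_size_mean,insert_size_sd fragment size model (bp).
#' @param error_rate per-base substitution probability.
#' @param repeat_block_length length of a two-copy repeat block planted in
#'   the reference to exercise the repetitive-flank filter; 0 disables it.
#' @param tir_iupac optional character vector of IUPAC TIR consensus strings;
#'   family i takes a random concrete resolution of `tir_iupac[i]`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 200000L,
                       n_genes = 30L,
                       gene_span = c(2000L, 5000L),
                       exons_per_gene = c(2L, 4L),
                       utr_length = c(100L, 300L),
                       n_families = 3L,
                       element_length = c(150L, 450L),
                       tir_length = 31L,
                       at_fraction = 0.62,
                       n_accessions = 10L,
                       mean_insertions = 15,
                       fraction_unique = 0.3,
                       n_parallel_loci = 5L,
                       ploidy_model = c("haploid", "diploid"),
                       coverage = 20,
                       read_length = 100L,
                       insert_size_mean = 300L,
                       insert_size_sd = 30,
                       error_rate = 0,
                       repeat_block_length = 2000L,
                       tir_iupac = NULL) {
  ploidy_model <- match.arg(ploidy_model)
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              gene_span = as.integer(gene_span), exons_per_gene = as.integer(exons_per_gene),
              utr_length = as.integer(utr_length), n_families = as.integer(n_families),
              element_length = as.integer(element_length), tir_length = as.integer(tir_length),
              at_fraction = at_fraction, n_accessions = as.integer(n_accessions),
              mean_insertions = mean_insertions, fraction_unique = fraction_unique,
              n_parallel_loci = as.integer(n_parallel_loci), ploidy_model = ploidy_model,
              coverage = coverage, read_length = as.integer(read_length),
              insert_size_mean = as.integer(insert_size_mean), insert_size_sd = insert_size_sd,
              error_rate = error_rate, repeat_block_length = as.integer(repeat_block_length),
              tir_iupac = tir_iupac)
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "n_families",
              "n_accessions", "n_parallel_loci", "read_length",
              "repeat_block_length")
  for (f in counts)
    if (cfg[[f]] < 0L) stop("'", f, "' must be >= 0")
  for (f in c("at_fraction", "fraction_unique", "error_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0,1]")
  if (cfg$mean_insertions < 0) stop("'mean_insertions' must be >= 0")
  if (cfg$coverage < 0) stop("'coverage' must be >= 0")
  if (max(cfg$element_length) >= 800L)
    stop("MITE family consensus length must stay below 800 bp")
  if (cfg$tir_length > min(cfg$element_length) / 2)
    stop("'tir_length' must be at most half the shortest element length")
  if (cfg$n_parallel_loci > 0L && (cfg$n_accessions < 2L || cfg$n_families < 2L))
    stop("parallel loci require at least 2 accessions and 2 families")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, at_fraction) {
  p <- c(at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2, at_fraction / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

resolve_iupac <- function(mask) {
  paste(vapply(seq_chars(mask), function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("non-IUPAC character in TIR consensus: ", ch)
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

mutate_bases <- function(seq, n_changes) {
  s <- seq_chars(seq)
  idx <- sample(length(s), n_changes)
  for (i in idx) s[i] <- sample(setdiff(DNA_BASES, s[i]), 1L)
  paste(s, collapse = "")
}

# Partition a gene span into exon/intron blocks and UTR/CDS sub-features.
build_gene_features <- function(gene_id, chrom, start, span, strand,
                                n_exons, u5, u3) {
  min_intron <- 50L
  min_mid <- 60L
  mins <- c(u5 + 30L, rep(min_mid, max(0L, n_exons - 2L)),
            if (n_exons > 1L) u3 + 30L else 0L)
  if (n_exons == 1L) mins <- u5 + u3 + 30L
  intron_mins <- rep(min_intron, n_exons - 1L)
  need <- sum(mins) + sum(intron_mins)
  span <- max(span, need)
  extra <- span - need
  nblk <- 2L * n_exons - 1L
  add <- if (extra > 0L) as.integer(rmultinom(1, extra, rep(1, nblk))) else rep(0L, nblk)
  lens <- integer(nblk)
  lens[seq(1L, nblk, 2L)] <- mins
  if (n_exons > 1L) lens[seq(2L, nblk, 2L)] <- intron_mins
  lens <- lens + add
  ends <- start - 1L + cumsum(lens)
  starts <- c(start, head(ends, -1L) + 1L)
  is_exon <- rep(c(TRUE, FALSE), length.out = nblk)
  exons <- data.frame(start = starts[is_exon], end = ends[is_exon])
  gene_end <- ends[nblk]
  # UTRs sit at the transcription ends: leftmost exon carries the 5'UTR on
  # '+' genes and the 3'UTR on '-' genes.
  feats <- list()
  ne <- nrow(exons)
  left_u <- if (strand == "+") u5 else u3
  right_u <- if (strand == "+") u3 else u5
  left_lab <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  right_lab <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  for (i in seq_len(ne)) {
    es <- exons$start[i]; ee <- exons$end[i]
    cs <- es; ce <- ee
    if (i == 1L && left_u > 0L) {
      feats[[length(feats) + 1L]] <- data.frame(type = left_lab, start = es,
                                                end = es + left_u - 1L)
      cs <- es + left_u
    }
    if (i == ne && right_u > 0L) {
      feats[[length(feats) + 1L]] <- data.frame(type = right_lab,
                                                start = ee - right_u + 1L, end = ee)
      ce <- ee - right_u
    }
    if (cs <= ce)
      feats[[length(feats) + 1L]] <- data.frame(type = "CDS", start = cs, end = ce)
    feats[[length(feats) + 1L]] <- data.frame(type = "exon", start = es, end = ee)
  }
  feats <- do.call(rbind, feats)
  feats$gene_id <- gene_id; feats$chrom <- chrom; feats$strand <- strand
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                         end = gene_end, strand = strand,
                         stringsAsFactors = FALSE),
       features = feats[, c("gene_id", "chrom", "type", "start", "end", "strand")])
}

#' Simulate a reference genome, gene annotation and MITE families
#'
#' Chromosomes are i.i.d. background sequence at the configured AT fraction.
#' Genes are placed without overlap, each with a 5'UTR/CDS/intron/3'UTR
#' structure on a random strand. Each family consensus is a 5' TIR, an
#' AT-rich interior and the reverse-complemented TIR; when two or more
#' families are requested the second family's TIR differs from the first by
#' at most two mismatches, so that TIR-similar family pairs exist for the
#' parallel-insertion analyses. A two-copy repeat block is planted in
#' intergenic sequence when `repeat_block_length > 0`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `annotation`
#'   (list of `genes` and `features` data frames), `families` (list of
#'   `mite_family` lists with `name`, `consensus`, `tir5`, `tir3`, `tsd`),
#'   `repeats` (data frame of planted repeat intervals) and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome <- setNames(
    vapply(chrom_names, function(ch) random_dna(config$chrom_length,
                                                config$at_fraction),
           character(1)),
    chrom_names)

  # genes: round-robin over chromosomes, non-overlapping, 4.5 kb clearance
  genes <- list(); features <- list()
  gap <- 4500L
  if (config$n_genes > 0L) {
    per_chrom <- table(factor(rep(chrom_names, length.out = config$n_genes),
                              levels = chrom_names))
    gid <- 0L
    for (ch in chrom_names) {
      k <- as.integer(per_chrom[[ch]])
      if (k == 0L) next
      spans <- sample(seq(config$gene_span[1], config$gene_span[2]), k,
                      replace = TRUE)
      need <- sum(spans) + (k + 1L) * gap
      if (need > config$chrom_length)
        stop("chromosome too short to place requested genes (need ", need,
             " bp, have ", config$chrom_length, ")")
      slack <- config$chrom_length - need
      cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
      starts <- gap + cuts + cumsum(c(0L, head(spans, -1L) + gap)) + 1L
      for (i in seq_len(k)) {
        gid <- gid + 1L
        g <- build_gene_features(sprintf("gene%03d", gid), ch, starts[i],
                                 spans[i],
                                 sample(c("+", "-"), 1L),
                                 sample(seq(config$exons_per_gene[1],
                                            config$exons_per_gene[2]), 1L),
                                 sample(seq(config$utr_length[1],
                                            config$utr_length[2]), 1L),
                                 sample(seq(config$utr_length[1],
                                            config$utr_length[2]), 1L))
        genes[[gid]] <- g$gene
        features[[gid]] <- g$features
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  features <- if (length(features)) do.call(rbind, features) else
    data.frame(gene_id = character(0), chrom = character(0),
               type = character(0), start = integer(0), end = integer(0),
               strand = character(0))

  # two-copy repeat block in intergenic sequence of the first chromosome
  repeats <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  rl <- config$repeat_block_length
  if (rl > 0L) {
    ch <- chrom_names[1]
    occ <- genes[genes$chrom == ch, , drop = FALSE]
    bounds <- sort(c(1L, occ$start, occ$end, config$chrom_length))
    gaps_start <- c(1L, occ$end + 1L)
    gaps_end <- c(occ$start - 1L, config$chrom_length)
    ok <- which(gaps_end - gaps_start + 1L >= rl + 200L)
    if (length(ok) >= 2L) {
      picks <- sample(ok, 2L)
      s1 <- gaps_start[picks[1]] + 100L
      s2 <- gaps_start[picks[2]] + 100L
      block <- substring(genome[[ch]], s1, s1 + rl - 1L)
      genome[[ch]] <- paste0(substring(genome[[ch]], 1L, s2 - 1L), block,
                             substring(genome[[ch]], s2 + rl, config$chrom_length))
      repeats <- data.frame(chrom = ch, start = c(s1, s2),
                            end = c(s1, s2) + rl - 1L)
    } else {
      message("no intergenic room for the repeat block; skipping it")
    }
  }

  # MITE families
  families <- vector("list", config$n_families)
  t <- config$tir_length
  for (i in seq_len(config$n_families)) {
    tir5 <- if (!is.null(config$tir_iupac) && i <= length(config$tir_iupac)) {
      resolve_iupac(config$tir_iupac[i])
    } else if (i == 2L) {
      mutate_bases(families[[1]]$tir5, 2L)
    } else {
      random_dna(t, min(0.75, config$at_fraction + 0.1))
    }
    if (nchar(tir5) > min(config$element_length) / 2)
      stop("TIR consensus longer than half the shortest element length")
    len <- sample(seq(config$element_length[1], config$element_length[2]), 1L)
    interior <- random_dna(len - 2L * nchar(tir5),
                           min(0.8, config$at_fraction + 0.12))
    consensus <- paste0(tir5, interior, revcomp(tir5))
    families[[i]] <- structure(
      list(name = sprintf("MITE%d", i), consensus = consensus, tir5 = tir5,
           tir3 = revcomp(tir5), tsd = "TA", length = nchar(consensus)),
      class = "mite_family")
  }
  names(families) <- vapply(families, `[[`, character(1), "name")

  list(genome = genome,
       annotation = list(genes = genes, features = features),
       families = families, repeats = repeats, config = config)
}

#' Insert an element at a TA target site with TSD duplication
#'
#' The insertion point is the A of a TA dinucleotide; the inserted allele
#' reads `...TA + element + TA...`, duplicating the target site, so the
#' sequence grows by `nchar(element) + 2`.
#'
#' @param sequence chromosome sequence.
#' @param position 1-based coordinate of the A of the target TA.
#' @param element element sequence to insert.
#' @return modified sequence.
#' @export
insert_element <- function(sequence, position, element) {
  L <- nchar(sequence)
  if (position < 2L || position > L) stop("position outside sequence")
  if (substring(sequence, position - 1L, position) != "TA")
    stop("position is not the A of a TA dinucleotide")
  paste0(substring(sequence, 1L, position), element, "TA",
         substring(sequence, position + 1L, L))
}

# Sample `n` TA insertion points (coordinates of the A) with a minimum
# spacing, avoiding chromosome ends and the planted repeat block.
sample_ta_sites <- function(genome, n, min_gap, margin, repeats) {
  cand <- list()
  for (ch in names(genome)) {
    p <- ta_dinucleotides(genome[[ch]]) + 1L   # A coordinate
    L <- nchar(genome[[ch]])
    p <- p[p > margin & p < L - margin]
    if (nrow(repeats)) {
      rr <- repeats[repeats$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(rr)))
        p <- p[p < rr$start[i] - margin | p > rr$end[i] + margin]
    }
    if (length(p))
      cand[[ch]] <- data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(chrom = character(0), pos = integer(0))
  if (nrow(cand) == 0L && n > 0L)
    stop("no eligible TA target sites in the reference")
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  kept <- integer(0)
  kept_chrom <- character(0); kept_pos <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept) >= n) break
    same <- kept_chrom == cand$chrom[i]
    if (!any(same) || all(abs(kept_pos[same] - cand$pos[i]) >= min_gap)) {
      kept <- c(kept, i)
      kept_chrom <- c(kept_chrom, cand$chrom[i])
      kept_pos <- c(kept_pos, cand$pos[i])
    }
  }
  if (length(kept) < n)
    stop("requested ", n, " insertion sites but only ", length(kept),
         " spaced TA sites are available")
  cand[kept, , drop = FALSE]
}

#' Simulate a population of accessions carrying MITE insertions
#'
#' Site rows are planned family by family. For a single-accession population
#' the number of distinct sites is drawn Poisson(`mean_insertions`). For
#' larger populations, per-family total presences are drawn
#' Poisson(`mean_insertions * n_accessions`) and converted into site rows so
#' that the configured `fraction_unique` of all rows (parallel-locus rows
#' included) is single-accession by construction; shared rows receive a
#' uniform 2..N accession occupancy. Exactly `n_parallel_loci` positions
#' carry two different families in two different accessions. Every insertion
#' lands on a TA dinucleotide and duplicates it.
#'
#' @param reference output of [simulate_reference()].
#' @param families list of `mite_family` objects (defaults to the
#'   reference's).
#' @param config a [sim_config()].
#' @return list with `genomes` (per accession: named chromosome vector, or
#'   `list(hap1, hap2)` under the diploid model), `truth` (data frame:
#'   accession, chrom, pos, family, zygosity) and `site_rows` (row-level
#'   plan: chrom, pos, family, n_accessions, parallel flag).
#' @export
simulate_population <- function(reference, families = reference$families,
                                config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genome <- reference$genome
  N <- config$n_accessions
  accs <- sprintf("acc%02d", seq_len(N))
  lambda <- config$mean_insertions
  P <- config$n_parallel_loci
  fam_names <- names(families)

  empty_truth <- data.frame(accession = character(0), chrom = character(0),
                            pos = integer(0), family = character(0),
                            zygosity = character(0), stringsAsFactors = FALSE)
  if (N == 0L || length(families) == 0L ||
      (lambda == 0 && P == 0L)) {
    genomes <- lapply(accs, function(a)
      if (config$ploidy_model == "diploid") list(hap1 = genome, hap2 = genome)
      else genome)
    names(genomes) <- accs
    return(list(genomes = genomes, truth = empty_truth,
                site_rows = empty_truth[0, c("chrom", "pos", "family")]))
  }

  # plan site rows per family
  if (N == 1L) {
    S_f <- rpois(length(families), lambda)
    rows <- data.frame(family = rep(fam_names, S_f), occ = 1L,
                       stringsAsFactors = FALSE)
    if (P > 0L) stop("parallel loci require at least 2 accessions")
  } else {
    T_f <- rpois(length(families), lambda * N)
    cbar <- config$fraction_unique +
      (1 - config$fraction_unique) * (N + 2) / 2
    S_f <- pmax(ifelse(T_f > 0, 1L, 0L), round(T_f / cbar))
    rows <- data.frame(family = rep(fam_names, S_f), occ = NA_integer_,
                       stringsAsFactors = FALSE)
    S_total <- nrow(rows) + 2L * P
    U_target <- round(config$fraction_unique * S_total)
    U_nonpis <- U_target - 2L * P
    if (U_nonpis < 0L)
      stop("fraction_unique too small to accommodate ", P, " parallel loci")
    if (U_nonpis > nrow(rows))
      stop("fraction_unique too large for the planned number of sites")
    uniq_idx <- sample.int(nrow(rows), U_nonpis)
    rows$occ <- sample(2:N, nrow(rows), replace = TRUE)
    rows$occ[uniq_idx] <- 1L
  }
  rows$parallel <- FALSE

  # parallel-locus rows: one position, two families, two accessions
  if (P > 0L) {
    prow <- do.call(rbind, lapply(seq_len(P), function(i) {
      fams <- sample(fam_names, 2L)
      data.frame(family = fams, occ = 1L, parallel = TRUE,
                 locus = i, stringsAsFactors = FALSE)
    }))
  } else prow <- NULL

  n_positions <- nrow(rows) + P
  sites <- sample_ta_sites(genome, n_positions,
                           min_gap = 2L * config$read_length,
                           margin = config$read_length + 2L,
                           repeats = reference$repeats)
  rows$chrom <- sites$chrom[seq_len(nrow(rows))]
  rows$pos <- sites$pos[seq_len(nrow(rows))]
  if (P > 0L) {
    ppos <- sites[nrow(rows) + seq_len(P), , drop = FALSE]
    prow$chrom <- ppos$chrom[prow$locus]
    prow$pos <- ppos$pos[prow$locus]
    prow$locus <- NULL
    rows <- rbind(rows, prow)
  }

  # accession membership
  memb <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) memb[[i]] <- sort(sample.int(N, rows$occ[i]))
  pi <- which(rows$parallel)
  if (length(pi)) {
    # the two rows of each parallel locus must sit in different accessions
    for (k in seq_len(length(pi) / 2L)) {
      a <- sample.int(N, 2L)
      memb[[pi[2L * k - 1L]]] <- a[1]
      memb[[pi[2L * k]]] <- a[2]
    }
  }

  # per-row element strand (one historical insertion event per row)
  rows$strand <- sample(c("+", "-"), nrow(rows), replace = TRUE)

  truth <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    a <- memb[[i]]
    zyg <- if (config$ploidy_model == "diploid")
      sample(c("hom", "het"), length(a), replace = TRUE) else
      rep("hom", length(a))
    data.frame(accession = accs[a], chrom = rows$chrom[i], pos = rows$pos[i],
               family = rows$family[i], zygosity = zyg,
               stringsAsFactors = FALSE)
  }))
  truth <- truth[order(truth$accession, truth$chrom, truth$pos, truth$family), ]
  rownames(truth) <- NULL

  elem_of <- setNames(vapply(families, `[[`, character(1), "consensus"),
                      fam_names)
  apply_insertions <- function(seqs, ins) {
    for (ch in unique(ins$chrom)) {
      sub <- ins[ins$chrom == ch, , drop = FALSE]
      sub <- sub[order(-sub$pos), , drop = FALSE]
      s <- seqs[[ch]]
      for (i in seq_len(nrow(sub))) {
        el <- elem_of[[sub$family[i]]]
        if (sub$strand[i] == "-") el <- revcomp(el)
        s <- insert_element(s, sub$pos[i], el)
      }
      seqs[[ch]] <- s
    }
    seqs
  }

  row_key <- paste(rows$chrom, rows$pos, rows$family)
  genomes <- lapply(seq_len(N), function(a) {
    mine <- truth[truth$accession == accs[a], , drop = FALSE]
    mine$strand <- rows$strand[match(paste(mine$chrom, mine$pos, mine$family),
                                     row_key)]
    if (config$ploidy_model == "diploid") {
      list(hap1 = apply_insertions(genome, mine),
           hap2 = apply_insertions(genome,
                                   mine[mine$zygosity == "hom", , drop = FALSE]))
    } else {
      apply_insertions(genome, mine)
    }
  })
  names(genomes) <- accs

  list(genomes = genomes, truth = truth,
       site_rows = rows[, c("chrom", "pos", "family", "occ", "parallel")])
}

mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(nerr > 0L)) {
    s <- seq_chars(seqs[i])
    idx <- sample(length(s), nerr[i])
    for (j in idx) s[j] <- sample(setdiff(DNA_BASES, s[j]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate uniform-coverage paired reads from a genome
#'
#' Fragments are uniform over each chromosome with Normal insert sizes
#' (floored at the read length), sequenced from a random strand; mate 2 is
#' the reverse complement of the fragment's far end (FR orientation).
#' Substitution errors are applied at the configured per-base rate. Under
#' the diploid model reads are pooled equally from the two haplotypes.
#'
#' @param genome named chromosome vector, or `list(hap1, hap2)` of such
#'   vectors for a diploid accession.
#' @param config a [sim_config()].
#' @param seed seed for this read set (defaults to `config$seed`).
#' @return data.frame with columns `id`, `seq1`, `seq2`.
#' @export
simulate_reads <- function(genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  if (rl > config$insert_size_mean)
    stop("read_length exceeds the mean insert size")
  set.seed(as.integer(seed))
  haps <- if (is.list(genome)) genome else list(genome)
  cov_h <- config$coverage / length(haps)
  out <- list()
  idx <- 0L
  for (h in seq_along(haps)) {
    seqs <- haps[[h]]
    lens <- nchar(seqs)
    n_pairs <- round(cov_h * sum(lens) / (2 * rl))
    if (n_pairs == 0L) next
    per_chrom <- as.integer(rmultinom(1, n_pairs, lens))
    for (ci in seq_along(seqs)) {
      n <- per_chrom[ci]
      if (n == 0L) next
      L <- lens[ci]
      isize <- pmin(L, pmax(rl, round(rnorm(n, config$insert_size_mean,
                                            config$insert_size_sd))))
      start <- 1L + floor(runif(n) * (L - isize + 1))
      r1 <- substring(seqs[[ci]], start, start + rl - 1L)
      r2 <- revcomp(substring(seqs[[ci]], start + isize - rl,
                              start + isize - 1L))
      flip <- runif(n) < 0.5
      tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
      r1 <- mutate_reads(r1, config$error_rate)
      r2 <- mutate_reads(r2, config$error_rate)
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("r%07d", idx + seq_len(n)),
        seq1 = r1, seq2 = r2, stringsAsFactors = FALSE)
      idx <- idx + n
    }
  }
  if (length(out) == 0L)
    return(data.frame(id = character(0), seq1 = character(0),
                      seq2 = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA (one per gene), exon, CDS and UTR features with 1-based
#' inclusive coordinates.
#'
#' @param annotation list with `genes` and `features` data frames.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  f <- annotation$features
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chrom[i], source = "mitepop", type = c("gene", "mRNA"),
      start = g$start[i], end = g$end[i], score = ".", strand = g$strand[i],
      phase = ".",
      attributes = c(sprintf("ID=%s", gid),
                     sprintf("ID=%s.t1;Parent=%s", gid, gid)),
      stringsAsFactors = FALSE)
    sub <- f[f$gene_id == gid, , drop = FALSE]
    if (nrow(sub))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = sub$chrom, source = "mitepop", type = sub$type,
        start = sub$start, end = sub$end, score = ".", strand = sub$strand,
        phase = ifelse(sub$type == "CDS", "0", "."),
        attributes = sprintf("Parent=%s.t1", gid), stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(0), source = character(0), type = character(0),
               start = integer(0), end = integer(0), score = character(0),
               strand = character(0), phase = character(0),
               attributes = character(0))
  write_gff3(df, path)
}

#' Write a simulation truth table as TSV
#' @param truth truth data frame from [simulate_population()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth[, c("accession", "chrom", "pos", "family", "zygosity")],
            path)
}
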