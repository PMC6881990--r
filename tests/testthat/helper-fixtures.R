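# Shared fixtures and independent brute-force oracles.

small_config <- function(...) {
  defaults <- list(seed = 7L, n_chromosomes = 1L, chrom_length = 30000L,
                   n_genes = 3L, n_families = 2L, n_accessions = 3L,
                   mean_insertions = 4, fraction_unique = 0.4,
                   n_parallel_loci = 1L, coverage = 15,
                   repeat_block_length = 0L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

rand_dna <- function(n, p_at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(p_at / 2, (1 - p_at) / 2, (1 - p_at) / 2, p_at / 2)),
        collapse = "")
}

rc_simple <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

## independent IUPAC matching used by the TIR oracle
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_mask_mm <- function(schars, i, mask_chars) {
  mm <- 0L
  for (k in seq_along(mask_chars)) {
    b <- schars[i + k - 1L]
    if (!(b %in% ORACLE_IUPAC[[mask_chars[k]]])) mm <- mm + 1L
  }
  mm
}

# Exhaustive pair scan over all (i, j): independent of the miner.
oracle_find_tir <- function(sequence, params) {
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(s)
  mask <- strsplit(params$tir_mask, "")[[1]]
  rcm <- strsplit(revcomp(params$tir_mask), "")[[1]]
  m <- length(mask)
  tl <- nchar(params$tsd_mask)
  tmask <- strsplit(params$tsd_mask, "")[[1]]
  fw <- integer(0); rc <- integer(0)
  for (i in seq_len(max(0L, L - m + 1L))) {
    if (oracle_mask_mm(s, i, mask) <= params$tir_mask_mismatches)
      fw <- c(fw, i)
    if (oracle_mask_mm(s, i, rcm) <= params$tir_mask_mismatches)
      rc <- c(rc, i)
  }
  out <- NULL
  for (i in fw) for (j2 in rc) {
    j <- j2 + m - 1L
    w <- j - i + 1L
    if (w < max(params$min_length, 2L * m) || w > params$max_length) next
    if (i - tl < 1L || j + tl > L) next
    t5 <- paste(s[i:(i + m - 1L)], collapse = "")
    t3 <- paste(s[(j - m + 1L):j], collapse = "")
    if (sum(strsplit(t5, "")[[1]] !=
            strsplit(revcomp(t3), "")[[1]]) > params$tir_seq_mismatches) next
    if (oracle_mask_mm(s, i - tl, tmask) > params$tsd_mask_mismatches) next
    if (oracle_mask_mm(s, j + 1L, tmask) > params$tsd_mask_mismatches) next
    if (sum(s[(i - tl):(i - 1L)] != s[(j + 1L):(j + tl)]) >
        params$tsd_seq_mismatches) next
    out <- rbind(out, data.frame(start = i, end = j))
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else
    out[order(out$start, out$end), , drop = FALSE]
}

# Plant an element with exact-mask TIRs and TA TSDs at a given offset.
plant_element <- function(sequence, offset, elem) {
  paste0(substring(sequence, 1, offset - 1), "TA", elem, "TA",
         substring(sequence, offset, nchar(sequence)))
}

# A concrete ACGT resolution of an IUPAC mask (first base of each set).
mask_resolution <- function(mask) {
  paste(vapply(strsplit(mask, "")[[1]],
               function(ch) ORACLE_IUPAC[[ch]][1], character(1)),
        collapse = "")
}

# Element with given TIR and interior; TSDs are added by plant_element.
make_element <- function(tir5, interior_len, tir3 = NULL, p_at = 0.6) {
  if (is.null(tir3)) tir3 <- rc_simple(tir5)
  paste0(tir5, rand_dna(interior_len, p_at), tir3)
}

## six-frame ORF scan oracle (walks codons one by one)
oracle_find_orfs <- function(sequence, min_codons) {
  L <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  res <- NULL
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") toupper(sequence) else rc_simple(toupper(sequence))
    for (f in 0:2) {
      n_cod <- (nchar(ss) - f) %/% 3
      if (n_cod < 1) next
      for (a in seq_len(n_cod)) {
        p1 <- f + 3 * (a - 1) + 1
        if (substring(ss, p1, p1 + 2) != "ATG") next
        b <- a
        found <- FALSE
        while (b <= n_cod) {
          q <- f + 3 * (b - 1) + 1
          if (substring(ss, q, q + 2) %in% stops) { found <- TRUE; break }
          b <- b + 1
        }
        if (!found || b - a + 1 < min_codons) next
        p2 <- f + 3 * (b - 1) + 3
        gs <- if (strand == "+") p1 else L - p2 + 1
        ge <- if (strand == "+") p2 else L - p1 + 1
        res <- rbind(res, data.frame(start = gs, end = ge, strand = strand,
                                     n_codons = b - a + 1))
      }
    }
  }
  if (is.null(res)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0), n_codons = integer(0))
  else res[order(res$start, res$end, res$strand), , drop = FALSE]
}

## exhaustive DD39D triple enumeration
oracle_ddd <- function(protein, first_spacer = c(1, 150)) {
  p <- strsplit(protein, "")[[1]]
  ds <- which(p == "D")
  for (i in ds) for (j in ds) for (k in ds) {
    if (i < j && j < k && k == j + 40 &&
        (j - i - 1) >= first_spacer[1] && (j - i - 1) <= first_spacer[2])
      return(list(complete = TRUE, triple = c(i, j, k)))
  }
  list(complete = FALSE, triple = NULL)
}

## toy two-gene annotation (one gene per strand) on a 10 kb chromosome
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"), chrom = "chr1",
    start = c(1001L, 6001L), end = c(2000L, 7000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c(rep("geneA", 5), rep("geneB", 5)),
    chrom = "chr1",
    type = c("five_prime_UTR", "CDS", "exon", "CDS", "three_prime_UTR",
             "three_prime_UTR", "CDS", "exon", "CDS", "five_prime_UTR"),
    start = c(1001L, 1151L, 1001L, 1501L, 1851L,
              6001L, 6101L, 6001L, 6701L, 6901L),
    end = c(1150L, 1300L, 1300L, 1850L, 2000L,
            6100L, 6400L, 6400L, 6900L, 7000L),
    strand = rep(c("+", "-"), each = 5), stringsAsFactors = FALSE)
  # exon rows for the right-hand exon of each gene
  features <- rbind(features, data.frame(
    gene_id = c("geneA", "geneB"), chrom = "chr1", type = "exon",
    start = c(1501L, 6701L), end = c(2000L, 7000L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
  list(genes = genes, features = features)
}

## per-base brute-force genic classifier, independent interval logic
oracle_classify <- function(chrom, position, annotation, flank = 2000) {
  genes <- annotation$genes[annotation$genes$chrom == chrom, , drop = FALSE]
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (position >= g$start && position <= g$end) {
      fe <- annotation$features[annotation$features$gene_id == g$gene_id, ]
      hit <- function(tp) {
        sub <- fe[fe$type == tp, ]
        nrow(sub) > 0 && any(position >= sub$start & position <= sub$end)
      }
      if (hit("CDS")) return("cds")
      if (hit("five_prime_UTR")) return("utr5")
      if (hit("three_prime_UTR")) return("utr3")
      return("intron")
    }
  }
  best_d <- Inf; best_lab <- "intergenic"; best_start <- -Inf
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (position < g$start) {
      d <- g$start - position; before <- TRUE
    } else {
      d <- position - g$end; before <- FALSE
    }
    take <- d < best_d ||
      (d == best_d && before && g$start > best_start)
    if (take && d <= flank) {
      best_d <- d
      best_start <- if (before) g$start else -Inf
      upstream <- (before && g$strand == "+") || (!before && g$strand == "-")
      best_lab <- if (upstream) "upstream_2kb" else "downstream_2kb"
    }
  }
  best_lab
}

## random toy annotation generator for oracle trials
random_annotation <- function(chrom_len = 12000L, n_genes = 3L) {
  starts <- sort(sample(seq(500L, chrom_len - 1500L), n_genes))
  genes <- NULL; features <- NULL
  last_end <- 0L
  kept <- 0L
  for (i in seq_len(n_genes)) {
    s <- max(starts[i], last_end + 200L)
    len <- sample(400:900, 1)
    e <- s + len - 1L
    if (e > chrom_len - 100L) next
    kept <- kept + 1L
    gid <- sprintf("g%d", kept)
    strand <- sample(c("+", "-"), 1)
    u1 <- sample(40:80, 1); u2 <- sample(40:80, 1)
    e1_end <- s + sample(150:200, 1)
    e2_start <- e1_end + sample(60:120, 1)
    genes <- rbind(genes, data.frame(gene_id = gid, chrom = "chr1",
                                     start = s, end = e, strand = strand,
                                     stringsAsFactors = FALSE))
    left_lab <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
    right_lab <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
    features <- rbind(features, data.frame(
      gene_id = gid, chrom = "chr1",
      type = c(left_lab, "CDS", "exon", "CDS", right_lab, "exon"),
      start = c(s, s + u1, s, e2_start, e - u2 + 1L, e2_start),
      end = c(s + u1 - 1L, e1_end, e1_end, e - u2, e, e),
      strand = strand, stringsAsFactors = FALSE))
    last_end <- e
  }
  list(genes = genes, features = features)
}

## end-to-end pipeline fixture shared by the caller tests
run_small_pipeline <- function(cfg) {
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  calls <- call_population(pop, ref, cfg)
  list(ref = ref, pop = pop, calls = calls)
}
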