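test_that("config validation enforces the generator invariants", {
  expect_error(sim_config(at_fraction = 1.2), "at_fraction")
  expect_error(sim_config(element_length = c(300L, 900L)), "800")
  expect_error(sim_config(tir_length = 200L, element_length = c(150L, 300L)),
               "tir_length")
  expect_error(sim_config(n_parallel_loci = 2L, n_accessions = 1L),
               "parallel")
  expect_error(sim_config(mean_insertions = -1), "mean_insertions")
})

test_that("reference genome honours length, AT fraction and gene placement", {
  cfg <- small_config(chrom_length = 200000L, at_fraction = 0.62,
                      n_genes = 10L)
  ref <- simulate_reference(cfg)
  expect_equal(unname(nchar(ref$genome)), 200000L)
  s <- strsplit(ref$genome[[1]], "")[[1]]
  at <- mean(s %in% c("A", "T"))
  expect_gte(at, 0.60)
  expect_lte(at, 0.64)
  g <- ref$annotation$genes
  expect_equal(nrow(g), 10L)
  g <- g[order(g$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  # every gene has a full sub-feature complement inside its span
  for (i in seq_len(nrow(g))) {
    fe <- ref$annotation$features[ref$annotation$features$gene_id ==
                                    g$gene_id[i], ]
    expect_setequal(unique(fe$type),
                    c("five_prime_UTR", "CDS", "three_prime_UTR", "exon"))
    expect_true(all(fe$start >= g$start[i] & fe$end <= g$end[i]))
  }
  expect_error(simulate_reference(small_config(chrom_length = 20000L,
                                               n_genes = 50L)),
               "too short")
})

test_that("an empty annotation still yields a genome and a header-only GFF3", {
  cfg <- small_config(n_genes = 0L, chrom_length = 5000L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$annotation$genes), 0L)
  expect_equal(nchar(ref$genome[[1]]), 5000L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ref$annotation, path)
  expect_identical(readLines(path), "##gff-version 3")
})

test_that("family TIR structure is embedded and IUPAC consensus resolves", {
  mask31 <- "CTCCCTCCGTCCCTWTTTATCTGTCCAHTTT"
  cfg <- small_config(n_families = 3L, tir_iupac = mask31,
                      element_length = c(150L, 400L))
  ref <- simulate_reference(cfg)
  f1 <- ref$families[[1]]
  expect_equal(nchar(f1$tir5), 31L)
  # stored TIR is a concrete ACGT resolution of the IUPAC string
  tchars <- strsplit(f1$tir5, "")[[1]]
  mchars <- strsplit(mask31, "")[[1]]
  expect_true(all(mapply(function(b, m) b %in% ORACLE_IUPAC[[m]],
                         tchars, mchars)))
  for (f in ref$families) {
    expect_identical(substring(f$consensus, 1, nchar(f$tir5)), f$tir5)
    expect_identical(substring(f$consensus, f$length - nchar(f$tir3) + 1,
                               f$length), f$tir3)
    expect_identical(f$tir3, revcomp(f$tir5))
  }
  # two families share TIRs within 2 mismatches
  d12 <- sum(strsplit(ref$families[[1]]$tir5, "")[[1]] !=
               strsplit(ref$families[[2]]$tir5, "")[[1]])
  expect_lte(d12, 2L)
})

test_that("population truth obeys the TA target-site and length invariants", {
  cfg <- small_config(n_accessions = 4L, mean_insertions = 6,
                      n_parallel_loci = 2L)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  tr <- pop$truth
  expect_gt(nrow(tr), 0L)
  for (i in seq_len(nrow(tr)))
    expect_identical(substring(ref$genome[[tr$chrom[i]]], tr$pos[i] - 1L,
                               tr$pos[i]), "TA")
  expect_false(anyDuplicated(paste(tr$accession, tr$chrom, tr$pos,
                                   tr$family)) > 0)
  elen <- sapply(ref$families, `[[`, "length")
  for (a in names(pop$genomes)) {
    mine <- tr[tr$accession == a, ]
    expect_equal(sum(nchar(pop$genomes[[a]])),
                 sum(nchar(ref$genome)) + sum(elen[mine$family] + 2L))
  }
})

test_that("zero rate with no parallel loci leaves accessions untouched", {
  cfg <- small_config(mean_insertions = 0, n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  expect_equal(nrow(pop$truth), 0L)
  for (a in names(pop$genomes))
    expect_identical(pop$genomes[[a]], ref$genome)
})

test_that("single-accession site counts follow the Poisson design", {
  cfg0 <- small_config(n_accessions = 1L, n_families = 1L,
                       mean_insertions = 20, n_parallel_loci = 0L,
                       chrom_length = 25000L, n_genes = 0L)
  ref <- simulate_reference(cfg0)
  counts <- vapply(1:100, function(i) {
    cfg <- cfg0
    cfg$seed <- 1000L + i
    nrow(simulate_population(ref, config = cfg)$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 100))
})

test_that("parallel loci and the unique fraction are hit exactly", {
  cfg <- small_config(n_accessions = 6L, n_families = 3L,
                      mean_insertions = 8, n_parallel_loci = 5L,
                      fraction_unique = 0.3, chrom_length = 60000L)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  # brute-force grouping of the truth table by position
  key <- paste(pop$truth$chrom, pop$truth$pos)
  nfam <- tapply(pop$truth$family, key, function(x) length(unique(x)))
  expect_equal(sum(nfam >= 2L), 5L)
  sr <- pop$site_rows
  expect_equal(sum(sr$occ == 1L), round(0.3 * nrow(sr)))
})

test_that("read simulation meets the coverage and error-model contracts", {
  cfg <- small_config(chrom_length = 50000L, n_genes = 0L, coverage = 10,
                      mean_insertions = 0, n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref$genome, cfg, seed = 5L)
  bases <- sum(nchar(reads$seq1)) + sum(nchar(reads$seq2))
  expect_lt(abs(bases - 10 * 50000) / (10 * 50000), 0.05)
  # error-free reads are exact substrings of the genome or its complement
  g <- ref$genome[[1]]
  grc <- revcomp(g)
  some <- c(head(reads$seq1, 150), head(reads$seq2, 150))
  expect_true(all(vapply(some, function(r)
    grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE), logical(1))))
  # coverage 0 gives valid empty FASTQs
  cfg0 <- cfg; cfg0$coverage <- 0
  r0 <- simulate_reads(ref$genome, cfg0)
  expect_equal(nrow(r0), 0L)
  p1 <- withr::local_tempfile(fileext = ".fq")
  p2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(r0, p1, p2)
  expect_identical(read_fastq(p1), character(0))
  expect_error(simulate_reads(ref$genome,
                              small_config(read_length = 400L)),
               "insert size")
})

test_that("substitution errors appear at the configured rate", {
  cfg <- small_config(chrom_length = 40000L, n_genes = 0L, coverage = 5,
                      error_rate = 0.01, mean_insertions = 0,
                      n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref$genome, cfg, seed = 11L)
  g <- ref$genome[[1]]; grc <- revcomp(g)
  mm <- vapply(head(reads$seq1, 200), function(r) {
    # align by the longest end anchor (errors are sparse at 1%)
    for (tmpl in c(g, grc)) {
      hit <- regexpr(substring(r, 1, 40), tmpl, fixed = TRUE)
      if (hit > 0) {
        ref_r <- substring(tmpl, hit, hit + nchar(r) - 1)
        return(sum(strsplit(r, "")[[1]] != strsplit(ref_r, "")[[1]]))
      }
      hit <- regexpr(substring(r, nchar(r) - 39, nchar(r)), tmpl, fixed = TRUE)
      if (hit > 0) {
        ref_r <- substring(tmpl, hit - (nchar(r) - 40), hit + 39)
        return(sum(strsplit(r, "")[[1]] != strsplit(ref_r, "")[[1]]))
      }
    }
    NA_real_
  }, numeric(1))
  rate <- sum(mm, na.rm = TRUE) / (100 * sum(!is.na(mm)))
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.02)
})

test_that("every simulate_* call is byte-identical under a fixed seed", {
  cfg <- small_config()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  p1 <- simulate_population(r1, config = cfg)
  p2 <- simulate_population(r1, config = cfg)
  expect_identical(p1, p2)
  expect_identical(simulate_reads(p1$genomes[[1]], cfg, seed = 3L),
                   simulate_reads(p1$genomes[[1]], cfg, seed = 3L))
})

test_that("insert_element duplicates the TA target site", {
  s <- "GGGGTACCCC"
  out <- insert_element(s, 6L, "AAAA")
  expect_identical(out, "GGGGTAAAAATACCCC")
  expect_error(insert_element(s, 3L, "AAAA"), "TA")
})

test_that("diploid accessions pool two haplotypes with het on one", {
  cfg <- small_config(ploidy_model = "diploid", n_accessions = 2L,
                      mean_insertions = 5, n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  expect_true(all(c("hap1", "hap2") %in% names(pop$genomes[[1]])))
  tr <- pop$truth[pop$truth$accession == "acc01", ]
  elen <- sapply(ref$families, `[[`, "length")
  expect_equal(sum(nchar(pop$genomes[["acc01"]]$hap1)),
               sum(nchar(ref$genome)) + sum(elen[tr$family] + 2L))
  hom <- tr[tr$zygosity == "hom", ]
  expect_equal(sum(nchar(pop$genomes[["acc01"]]$hap2)),
               sum(nchar(ref$genome)) + sum(elen[hom$family] + 2L))
})
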