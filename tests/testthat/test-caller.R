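make_cons <- function(len = 200L) {
  set.seed(101)
  tir <- "CTCCCTCCGTCCCTATTTATCTGTCCAATTT"
  make_element(tir, len - 2L * nchar(tir))
}

test_that("terminal matching trims reads at the published thresholds", {
  cons <- make_cons()
  pars <- caller_params()
  flank <- rand_dna(30, 0.5)
  read <- paste0(flank, substring(cons, 1, 70))
  j <- match_and_trim(setNames(read, "r1"), cons, pars)
  expect_equal(nrow(j), 1L)
  expect_identical(j$side, "five_prime")
  expect_identical(j$flank, flank)
  expect_equal(j$te_overlap, 70L)
  # fully contained read yields no junction
  inner <- substring(cons, 20, 119)
  expect_equal(nrow(match_and_trim(setNames(inner, "r2"), cons, pars)), 0L)
  # 10 bp terminal overlap is below the 12 bp minimum
  r10 <- paste0(rand_dna(90, 0.5), substring(cons, 1, 10))
  expect_equal(nrow(match_and_trim(setNames(r10, "r3"), cons, pars)), 0L)
  # 12 bp overlap qualifies
  r12 <- paste0(rand_dna(88, 0.5), substring(cons, 1, 12))
  j12 <- match_and_trim(setNames(r12, "r4"), cons, pars)
  expect_equal(j12$te_overlap, 12L)
  # three-prime side, via the reverse-complement orientation
  read3 <- revcomp(paste0(substring(cons, 131, 200), rand_dna(30, 0.5)))
  j3 <- match_and_trim(setNames(read3, "r5"), cons, pars)
  expect_identical(j3$side, "three_prime")
  expect_equal(j3$te_overlap, 70L)
})

test_that("the mismatch fraction cap applies to the TE portion", {
  cons <- make_cons()
  pars <- caller_params()
  te <- substring(cons, 1, 30)
  flip <- function(x, i) {
    ch <- strsplit(x, "")[[1]]
    for (k in i) ch[k] <- setdiff(c("A", "C", "G", "T"), ch[k])[1]
    paste(ch, collapse = "")
  }
  ok_read <- paste0(rand_dna(70, 0.5), flip(te, c(15, 20, 25)))   # 3/30
  bad_read <- paste0(rand_dna(70, 0.5), flip(te, c(13, 15, 18, 20, 23, 25, 28)))
  expect_equal(match_and_trim(setNames(ok_read, "a"), cons, pars)$te_overlap,
               30L)
  expect_equal(nrow(match_and_trim(setNames(bad_read, "b"), cons, pars)), 0L)
})

test_that("flank placement derives the TA position on both strands", {
  set.seed(102)
  ref <- c(chr1 = rand_dna(10000, 0.55))
  pars <- caller_params()
  p <- ta_positions <- which(strsplit(ref[[1]], "")[[1]] == "T" &
                               c(strsplit(ref[[1]], "")[[1]][-1], "") == "A")
  p <- p[p > 200 & p < 9000][1] + 1L   # the A coordinate
  # five_prime flank ends ...TA at p
  jx5 <- data.frame(read_id = "q5", side = "five_prime",
                    flank = substring(ref[[1]], p - 39, p),
                    te_overlap = 50L, mismatches = 0L)
  ev5 <- map_flanks(jx5, ref, pars)
  expect_equal(ev5$position, p)
  expect_identical(ev5$junction, "left")
  # three_prime flank starting TA... at p-1
  jx3 <- data.frame(read_id = "q3", side = "three_prime",
                    flank = substring(ref[[1]], p - 1, p + 38),
                    te_overlap = 50L, mismatches = 0L)
  ev3 <- map_flanks(jx3, ref, pars)
  expect_equal(ev3$position, p)
  expect_identical(ev3$junction, "right")
  # the same flanks reverse-complemented land on the minus strand
  jx5r <- jx5; jx5r$flank <- revcomp(jx5$flank); jx5r$side <- "three_prime"
  ev5r <- map_flanks(jx5r, ref, pars)
  expect_equal(ev5r$position, p)
  # absent flank yields nothing
  jxa <- jx5; jxa$flank <- rand_dna(40, 0.5)
  expect_equal(nrow(map_flanks(jxa, ref, pars)), 0L)
})

test_that("flanks inside a two-copy repeat are discarded as multi-mapping", {
  set.seed(103)
  base <- rand_dna(6000, 0.55)
  block <- substring(base, 1001, 2000)
  ref <- c(chr1 = paste0(substring(base, 1, 4000), block,
                         substring(base, 5001, 6000)))
  pars <- caller_params()
  jx <- data.frame(read_id = "dup", side = "five_prime",
                   flank = substring(ref[[1]], 1201, 1240),
                   te_overlap = 50L, mismatches = 0L)
  ev <- map_flanks(jx, ref, pars)
  expect_equal(nrow(ev), 0L)
  expect_gte(attr(ev, "n_discarded"), 1L)
})

test_that("short flanks are discarded with a message", {
  set.seed(104)
  ref <- c(chr1 = rand_dna(2000, 0.5))
  jx <- data.frame(read_id = "s", side = "five_prime",
                   flank = substring(ref[[1]], 100, 109),
                   te_overlap = 50L, mismatches = 0L)
  expect_message(ev <- map_flanks(jx, ref, caller_params()), "discarded")
  expect_equal(nrow(ev), 0L)
})

test_that("reads from the unmodified reference produce zero calls", {
  cfg <- small_config(chrom_length = 40000L, n_genes = 0L,
                      mean_insertions = 0, n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(ref$genome, cfg, seed = 9L)
  calls <- call_insertions(reads, ref$families, ref$genome)
  expect_equal(nrow(calls), 0L)
})

test_that("a single homozygous insertion is called exactly once", {
  cfg <- small_config(chrom_length = 40000L, n_genes = 0L,
                      mean_insertions = 0, n_parallel_loci = 0L)
  ref <- simulate_reference(cfg)
  fam <- ref$families[[1]]
  s <- strsplit(ref$genome[[1]], "")[[1]]
  ta <- which(s == "T" & c(s[-1], "") == "A")
  p <- ta[ta > 5000 & ta < 30000][1] + 1L
  genome <- c(chr1 = insert_element(ref$genome[[1]], p, fam$consensus))
  reads <- simulate_reads(genome, cfg, seed = 10L)
  calls <- call_insertions(reads, ref$families, ref$genome)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, p)
  expect_identical(calls$family, fam$name)
  expect_gte(calls$left_support + calls$right_support, 1L)
})

test_that("different families at one position give two co-located calls", {
  cfg <- small_config(chrom_length = 40000L, n_genes = 0L,
                      mean_insertions = 0, n_parallel_loci = 0L,
                      n_families = 3L)
  ref <- simulate_reference(cfg)
  s <- strsplit(ref$genome[[1]], "")[[1]]
  ta <- which(s == "T" & c(s[-1], "") == "A")
  p <- ta[ta > 5000 & ta < 30000][1] + 1L
  # family 1 and family 3 (TIR-dissimilar) in two accessions
  calls <- lapply(c(1L, 3L), function(fi) {
    g <- c(chr1 = insert_element(ref$genome[[1]], p,
                                 ref$families[[fi]]$consensus))
    reads <- simulate_reads(g, cfg, seed = 20L + fi)
    call_insertions(reads, ref$families, ref$genome)
  })
  expect_equal(calls[[1]]$position, p)
  expect_equal(calls[[2]]$position, p)
  expect_identical(calls[[1]]$family, "MITE1")
  expect_identical(calls[[2]]$family, "MITE3")
})

test_that("doubling coverage never loses true calls", {
  cfg <- small_config(chrom_length = 30000L, n_genes = 0L,
                      mean_insertions = 3, n_parallel_loci = 0L,
                      n_accessions = 1L, n_families = 2L, coverage = 10)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, config = cfg)
  cfg2 <- cfg; cfg2$coverage <- 20
  r1 <- simulate_reads(pop$genomes[[1]], cfg, seed = 31L)
  r2 <- rbind(r1, simulate_reads(pop$genomes[[1]], cfg, seed = 32L))
  c1 <- call_insertions(r1, ref$families, ref$genome)
  c2 <- call_insertions(r2, ref$families, ref$genome)
  k1 <- paste(c1$chrom, c1$position, c1$family)
  k2 <- paste(c2$chrom, c2$position, c2$family)
  tk <- paste(pop$truth$chrom, pop$truth$pos, pop$truth$family)
  expect_true(all(intersect(k1, tk) %in% k2))
})

test_that("reference-site genotyping separates occupied, empty and het", {
  cfg <- small_config(chrom_length = 30000L, n_genes = 0L,
                      mean_insertions = 0, n_parallel_loci = 0L,
                      coverage = 20)
  base <- simulate_reference(cfg)
  fam <- base$families[[1]]
  s <- strsplit(base$genome[[1]], "")[[1]]
  ta <- which(s == "T" & c(s[-1], "") == "A")
  p <- ta[ta > 5000 & ta < 20000][1] + 1L
  ref_with <- c(chr1 = insert_element(base$genome[[1]], p, fam$consensus))
  sites <- data.frame(chromosome = "chr1", start = p + 1L,
                      end = p + fam$length)
  empty_genome <- base$genome
  carrier <- ref_with
  reads_occ <- simulate_reads(c(chr1 = unname(carrier)), cfg, seed = 41L)
  reads_emp <- simulate_reads(empty_genome, cfg, seed = 42L)
  g_occ <- genotype_reference_sites(reads_occ, sites, ref_with)
  g_emp <- genotype_reference_sites(reads_emp, sites, ref_with)
  expect_identical(g_occ$status, "occupied")
  expect_identical(g_emp$status, "empty")
  # pooled haplotypes (one carrier, one empty) call heterozygous
  half <- cfg; half$coverage <- 10
  reads_het <- rbind(simulate_reads(c(chr1 = unname(carrier)), half, seed = 43L),
                     simulate_reads(empty_genome, half, seed = 44L))
  g_het <- genotype_reference_sites(reads_het, sites, ref_with)
  expect_identical(g_het$status, "heterozygous")
})

test_that("element presence screening needs internal sequence, not TIRs", {
  set.seed(105)
  tir <- "CTCCCTCCGTCCCTATTTATCTGTCCAATTT"
  internal <- rand_dna(1500, 0.5)
  dcmar <- paste0(tir, internal, rc_simple(tir))
  cfg <- small_config(chrom_length = 30000L, n_genes = 0L,
                      mean_insertions = 0, n_parallel_loci = 0L,
                      coverage = 8)
  base <- simulate_reference(cfg)
  s <- strsplit(base$genome[[1]], "")[[1]]
  ta <- which(s == "T" & c(s[-1], "") == "A")
  p <- ta[ta > 5000 & ta < 20000][1] + 1L
  with_el <- c(chr1 = insert_element(base$genome[[1]], p, dcmar))
  # a MITE sharing the TIRs but not the internal sequence
  mite <- make_element(tir, 200)
  with_mite <- c(chr1 = insert_element(base$genome[[1]], p, mite))
  reads_el <- simulate_reads(with_el, cfg, seed = 51L)
  reads_mite <- simulate_reads(with_mite, cfg, seed = 52L)
  reads_none <- simulate_reads(base$genome, cfg, seed = 53L)
  expect_true(detect_element_presence(reads_el, internal)$present)
  expect_false(detect_element_presence(reads_mite, internal)$present)
  expect_false(detect_element_presence(reads_none, internal)$present)
  expect_error(detect_element_presence(reads_el, rand_dna(50)), "shorter")
})
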