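#!/usr/bin/env Rscript
# Step 1 — build the desk-scale study population.
#
# Generates the reference genome (2 x 200 kb), its gene annotation, the
# three MITE families, ten accession genomes carrying family-structured
# insertions at TA target sites (30% unique sites, five parallel loci), and
# error-free 20x paired reads for the first accession as an illustration.
# Every later step regenerates the same objects from the same seed instead
# of loading intermediates, so each script is self-contained.

suppressPackageStartupMessages(library(mitepop))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101L)
ref <- simulate_reference(cfg)
pop <- simulate_population(ref, config = cfg)

write_fasta(ref$genome, "results/sim/reference.fa")
write_annotation_gff3(ref$annotation, "results/sim/annotation.gff3")
write_fasta(setNames(vapply(ref$families, `[[`, character(1), "consensus"),
                     names(ref$families)),
            "results/sim/families.fa")
write_truth(pop$truth, "results/sim/truth.tsv")

reads1 <- simulate_reads(pop$genomes[[1]], cfg, seed = cfg$seed + 1001L)
write_fastq(reads1, "results/sim/acc01_R1.fastq", "results/sim/acc01_R2.fastq")

cl <- classify_sites(truth_matrix(pop$truth))
cat("Simulated", nrow(pop$truth), "insertions over",
    length(unique(rownames(truth_matrix(pop$truth)))), "sites in",
    cfg$n_accessions, "accessions\n")
cat("  unique sites:", sum(cl$sites$class == "uis"),
    sprintf("(%.1f%%)", 100 * mean(cl$sites$class == "uis")), "\n")
cat("  parallel insertion loci:", nrow(cl$pis), "\n")
cat("  per-family site counts:\n")
print(table(classify_sites(truth_matrix(pop$truth))$sites$family))
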