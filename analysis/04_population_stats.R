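#!/usr/bin/env Rscript
# Step 4 — population statistics on the presence/absence matrix.
#
# Merges the per-accession calls into a binary sites-by-accessions matrix
# and computes the study's population summaries: per-family site totals,
# unique insertion sites (UIS) and proliferation coefficients (PrC); the
# family-by-accession contingency analysis with a 2000-replicate
# Monte-Carlo chi-squared p-value and Pearson residuals; Jaccard distances
# with principal coordinate analysis; the coverage/site-count Spearman
# check; and family-pair co-occurrence at parallel insertion sites (PIS)
# against cumulative copy number and TIR distance.

suppressPackageStartupMessages(library(mitepop))
dir.create("results/popstats", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101L)
ref <- simulate_reference(cfg)
pop <- simulate_population(ref, config = cfg)
calls <- call_population(pop, ref, cfg)
m <- build_matrix(calls)

cl <- classify_sites(m)
fs <- family_stats(m)
write_tsv(fs, "results/popstats/family_stats.tsv")
write_tsv(cl$pis, "results/popstats/parallel_sites.tsv")
write_tsv(data.frame(site = rownames(m), m, check.names = FALSE),
          "results/popstats/presence_matrix.tsv")

cat("Matrix:", nrow(m), "sites x", ncol(m), "accessions\n")
cat("  UIS:", sum(cl$sites$class == "uis"),
    " fixed:", sum(cl$sites$class == "fixed"),
    " PIS:", nrow(cl$pis), "\n")
cat("  PrC by family:\n")
print(fs)

# family x accession contingency table of call counts
tab <- t(vapply(sort(unique(cl$sites$family)), function(f)
  colSums(m[cl$sites$family == f, , drop = FALSE]), numeric(ncol(m))))
ct <- contingency_test(tab, n_replicates = 2000L, seed = 303L)
cat(sprintf("Family x accession chi-squared: X2 = %.2f, MC p = %.4g\n",
            ct$statistic, ct$p_value))
write_tsv(data.frame(family = rownames(ct$residuals), ct$residuals,
                     check.names = FALSE),
          "results/popstats/pearson_residuals.tsv")

d <- jaccard_distances(m)
pc <- pcoa_coords(d)
write_tsv(data.frame(accession = rownames(pc$coordinates),
                     pc$coordinates[, 1:min(4, ncol(pc$coordinates))],
                     check.names = FALSE),
          "results/popstats/pcoa_coordinates.tsv")
cat(sprintf("PCoA: axis 1 explains %.1f%%, axis 2 %.1f%% of the variance\n",
            100 * pc$variance_explained[1], 100 * pc$variance_explained[2]))

# sequencing effort vs detected sites
reads_per_acc <- vapply(seq_along(pop$genomes), function(i)
  nrow(simulate_reads(pop$genomes[[i]], cfg, seed = cfg$seed + 1000L + i)),
  numeric(1))
sites_per_acc <- colSums(m)
cc <- coverage_correlation(reads_per_acc, sites_per_acc)
cat(sprintf("Coverage vs sites: Spearman rho = %.2f, p = %.2f\n",
            cc$rho, cc$p_value))

tirs <- setNames(vapply(ref$families, `[[`, character(1), "tir5"),
                 names(ref$families))
pisco <- pis_cooccurrence(m, cl$pis, tirs)
write_tsv(pisco$pairs, "results/popstats/pis_cooccurrence.tsv")
cat("PIS co-occurrence by family pair:\n")
print(pisco$pairs)

export_insertion_gff(m, ref$genome, ref$annotation,
                     path = "results/popstats/insertions.gff3")
cat("Wrote insertions.gff3 (start = A of the TA site, end = start + 1)\n")
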