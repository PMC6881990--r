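GENOTYPE_VOCAB <- c("hom_empty", "hom_occupied", "het_empty_occupied",
                    "hom_variant_other_size", "het_empty_variant",
                    "het_occupied_variant", "no_amplification")

CONCORDANCE_CATEGORIES <- data.frame(
  in_silico = c("empty", "occupied", "occupied", "empty", "empty",
                "occupied", "empty", "empty", "occupied"),
  genotype = c("hom_empty", "hom_occupied", "het_empty_occupied",
               "hom_variant_other_size", "het_empty_variant",
               "het_occupied_variant", "het_empty_occupied", "hom_occupied",
               "hom_empty"),
  category = c("empty / homozygous empty",
               "occupied / homozygous occupied",
               "occupied / heterozygous (empty + occupied)",
               "empty / homozygous variant of different size",
               "empty / heterozygous (empty + variant of different size)",
               "occupied / heterozygous (occupied + variant of different size)",
               "empty / heterozygous (empty + occupied)",
               "empty / homozygous occupied",
               "occupied / homozygous empty"),
  status = c(rep("concordant", 6L), rep("discordant", 3L)),
  stringsAsFactors = FALSE)

# Combinations absent from the published verification table but reachable in
# the vocabulary cross-product: a variant allele is 'empty' for the assayed
# element, so an occupied prediction over variant-only genotypes is wrong,
# as is an empty prediction when one allele carries the element.
CONCORDANCE_CATEGORIES <- rbind(CONCORDANCE_CATEGORIES, data.frame(
  in_silico = c("occupied", "occupied", "empty"),
  genotype = c("hom_variant_other_size", "het_empty_variant",
               "het_occupied_variant"),
  category = c("occupied / homozygous variant of different size",
               "occupied / heterozygous (empty + variant of different size)",
               "empty / heterozygous (occupied + variant of different size)"),
  status = "discordant", stringsAsFactors = FALSE))

#' Classify an in silico / genotyping call pair
#'
#' Maps one accession-by-site combination onto the ten verification
#' categories. Heterozygous empty+occupied genotypes are concordant with an
#' `occupied` in silico call (the read-based pipeline detects presence
#' regardless of zygosity) and discordant with an `empty` one; variant-size
#' alleles are `empty` for the assayed element. `no_amplification` passes
#' through unclassified.
#'
#' @param in_silico `"empty"` or `"occupied"`.
#' @param genotype one of `hom_empty`, `hom_occupied`, `het_empty_occupied`,
#'   `hom_variant_other_size`, `het_empty_variant`, `het_occupied_variant`,
#'   `no_amplification`.
#' @return list with `category` and `status` (`concordant`, `discordant` or
#'   `no_amplification`).
#' @export
classify_pair <- function(in_silico, genotype) {
  if (!in_silico %in% c("empty", "occupied"))
    stop("in_silico must be 'empty' or 'occupied'")
  if (!genotype %in% GENOTYPE_VOCAB)
    stop("unknown genotype value: ", genotype)
  if (genotype == "no_amplification")
    return(list(category = "No amplification", status = "no_amplification"))
  row <- CONCORDANCE_CATEGORIES[
    CONCORDANCE_CATEGORIES$in_silico == in_silico &
      CONCORDANCE_CATEGORIES$genotype == genotype, , drop = FALSE]
  list(category = row$category, status = row$status)
}

#' Summarise classified in silico / genotyping combinations
#'
#' Per-category counts and percentages of the grand total (no-amplification
#' combinations included), rounded half-up to one decimal, plus the
#' correct / incorrect / no-amplification totals.
#'
#' @param combinations data.frame with columns `in_silico` and `genotype`,
#'   optionally weighted by a count column `n`.
#' @return list with `table` (per-category data frame), `totals` (counts)
#'   and `percentages` (correct/incorrect/no_amplification, one decimal).
#' @export
summarize_concordance <- function(combinations) {
  if (nrow(combinations) == 0L) stop("need at least one combination")
  n <- if (is.null(combinations$n)) rep(1L, nrow(combinations)) else
    combinations$n
  cls <- lapply(seq_len(nrow(combinations)), function(i)
    classify_pair(combinations$in_silico[i], combinations$genotype[i]))
  cat_levels <- c(CONCORDANCE_CATEGORIES$category, "No amplification")
  cats <- factor(vapply(cls, `[[`, character(1), "category"),
                 levels = cat_levels)
  stat <- vapply(cls, `[[`, character(1), "status")
  total <- sum(n)
  counts <- vapply(cat_levels, function(cl) sum(n[cats == cl]), numeric(1))
  tab <- data.frame(category = cat_levels,
                    status = c(CONCORDANCE_CATEGORIES$status,
                               "no_amplification"),
                    n = as.integer(counts),
                    percent = round_half_up(100 * counts / total, 1L),
                    stringsAsFactors = FALSE)
  totals <- c(correct = sum(n[stat == "concordant"]),
              incorrect = sum(n[stat == "discordant"]),
              no_amplification = sum(n[stat == "no_amplification"]),
              total = total)
  list(table = tab,
       totals = totals,
       percentages = c(
         correct = round_half_up(100 * totals[["correct"]] / total, 1L),
         incorrect = round_half_up(100 * totals[["incorrect"]] / total, 1L),
         no_amplification = round_half_up(
           100 * totals[["no_amplification"]] / total, 1L)))
}
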