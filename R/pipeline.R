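utils::globalVariables(c(
  "flank", "read", "te_overlap", "mismatches", "read_id", "qid", "mm",
  "kmer", "chrom", "position", "family", "left_support", "right_support",
  "junction", "n_families", "uis", "presences", "total_sites", "prc",
  "i.qid", "x.chrom", "x.pos", "i.flen", "i.s_off", "N", "accession",
  "pos", "n_calls"))

#' Presence matrix straight from simulator truth
#'
#' Bypasses the read-based caller: the ground-truth insertion table is
#' converted directly into a sites-by-accessions matrix, the reference
#' against which caller recovery is measured.
#'
#' @param truth truth data frame from [simulate_population()].
#' @return presence matrix, see [build_matrix()].
#' @export
truth_matrix <- function(truth) {
  build_matrix(truth[, c("accession", "chrom", "pos", "family")])
}

#' Simulate reads and call insertions for every accession
#'
#' Runs [simulate_reads()] and [call_insertions()] per accession with
#' deterministic per-accession seed substreams; the flank k-mer index of
#' the reference is built once and reused.
#'
#' @param population output of [simulate_population()].
#' @param reference output of [simulate_reference()].
#' @param config the [sim_config()] used for the simulation.
#' @param params a [caller_params()].
#' @return named list of per-accession call data frames.
#' @export
call_population <- function(population, reference, config,
                            params = caller_params()) {
  index <- build_flank_index(reference$genome, params$flank_seed)
  accs <- names(population$genomes)
  calls <- vector("list", length(accs))
  names(calls) <- accs
  for (i in seq_along(accs)) {
    reads <- simulate_reads(population$genomes[[i]], config,
                            seed = config$seed + 1000L + i)
    calls[[i]] <- call_insertions(reads, reference$families,
                                  reference$genome, params, index = index)
  }
  calls
}

#' Compare caller output with simulator truth
#'
#' Matches calls to truth records by exact
#' (accession, chromosome, position, family).
#'
#' @param calls named list of per-accession call frames from
#'   [call_population()].
#' @param truth truth data frame from [simulate_population()].
#' @return list with `sensitivity` (fraction of truth records recovered at
#'   the exact position), `n_truth`, `n_recovered`, `n_false` (calls
#'   without a truth record) and `false_calls`.
#' @export
evaluate_recovery <- function(calls, truth) {
  call_df <- do.call(rbind, lapply(names(calls), function(a) {
    df <- calls[[a]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(accession = a, chrom = df$chrom, pos = df$position,
               family = df$family, stringsAsFactors = FALSE)
  }))
  tkey <- with(truth, paste(accession, chrom, pos, family))
  ckey <- if (is.null(call_df)) character(0) else
    with(call_df, paste(accession, chrom, pos, family))
  list(sensitivity = if (nrow(truth)) mean(tkey %in% ckey) else NA_real_,
       n_truth = nrow(truth),
       n_recovered = sum(tkey %in% ckey),
       n_false = sum(!ckey %in% tkey),
       false_calls = if (is.null(call_df)) call_df else
         call_df[!ckey %in% tkey, , drop = FALSE])
}
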