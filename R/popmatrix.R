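site_key <- function(chrom, position, family) {
  paste(chrom, position, family, sep = ":")
}

parse_site_keys <- function(keys) {
  if (length(keys) == 0L)
    return(data.frame(chrom = character(0), position = integer(0),
                      family = character(0), stringsAsFactors = FALSE))
  parts <- data.table::tstrsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = parts[[1]], position = as.integer(parts[[2]]),
             family = parts[[3]], stringsAsFactors = FALSE)
}

#' Build a sites-by-accessions presence/absence matrix
#'
#' Rows are keyed by exact `(chromosome, position, family)`; the same
#' position carrying different families yields distinct rows. Absence and
#' presence are scored 0 and 1. Duplicate calls within an accession are
#' collapsed with a warning.
#'
#' @param calls data.frame of calls with columns `accession`, `chrom` (or
#'   `chromosome`), `position` (or `pos`) and `family`; or a named list of
#'   per-accession call frames.
#' @return integer matrix with `chrom:pos:family` row names and accession
#'   column names.
#' @export
build_matrix <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(names(calls), function(a) {
      df <- calls[[a]]
      if (nrow(df) == 0L) return(NULL)
      df$accession <- a
      df
    }))
    if (is.null(calls))
      calls <- data.frame(accession = character(0), chrom = character(0),
                          position = integer(0), family = character(0))
  }
  if (!is.null(calls$chromosome) && is.null(calls$chrom))
    calls$chrom <- calls$chromosome
  if (!is.null(calls$pos) && is.null(calls$position))
    calls$position <- calls$pos
  key <- site_key(calls$chrom, calls$position, calls$family)
  if (anyDuplicated(paste(key, calls$accession))) {
    warning("duplicate calls within an accession collapsed")
    keep <- !duplicated(paste(key, calls$accession))
    calls <- calls[keep, , drop = FALSE]
    key <- key[keep]
  }
  accs <- sort(unique(calls$accession))
  sites <- sort(unique(key))
  m <- matrix(0L, nrow = length(sites), ncol = length(accs),
              dimnames = list(sites, accs))
  m[cbind(match(key, sites), match(calls$accession, accs))] <- 1L
  m
}

#' Classify matrix rows into unique, shared and fixed sites; detect PIS
#'
#' A unique insertion site (UIS) is present in exactly one accession; a
#' fixed site in all of them. Parallel insertion sites (PIS) are positions
#' where two or more rows share `(chromosome, position)` with distinct
#' families — the insertional hotspots.
#'
#' @param matrix presence matrix from [build_matrix()].
#' @return list with `sites` (per-row data frame: chrom, position, family,
#'   n_accessions, class) and `pis` (per-position data frame: chrom,
#'   position, n_families, families).
#' @export
classify_sites <- function(matrix) {
  info <- parse_site_keys(rownames(matrix))
  rs <- rowSums(matrix)
  if (any(rs < 1L)) stop("every matrix row must have at least one presence")
  info$n_accessions <- as.integer(rs)
  info$class <- ifelse(rs == 1L, "uis",
                       ifelse(rs == ncol(matrix), "fixed", "shared"))
  dt <- data.table::as.data.table(info)
  pis <- dt[, .(n_families = data.table::uniqueN(family),
                families = paste(sort(unique(family)), collapse = ",")),
            by = .(chrom, position)]
  pis <- pis[n_families >= 2L]
  data.table::setorder(pis, chrom, position)
  list(sites = info, pis = as.data.frame(pis))
}

#' Proliferation coefficient of a family
#'
#' `PrC = S * N / presences`, i.e. the number of distinct sites of the
#' family divided by its mean per-accession insertion count (zero-count
#' accessions included). PrC is 1 when every site is fixed and N when every
#' site is unique, indexing recent family expansion.
#'
#' @param matrix presence matrix from [build_matrix()].
#' @param family family name.
#' @return the PrC ratio.
#' @export
prc <- function(matrix, family) {
  info <- parse_site_keys(rownames(matrix))
  rows <- which(info$family == family)
  if (length(rows) == 0L) stop("family not present in the matrix: ", family)
  S <- length(rows)
  total <- sum(matrix[rows, , drop = FALSE])
  S * ncol(matrix) / total
}

#' Per-family site counts, unique-site counts and PrC
#'
#' @param matrix presence matrix from [build_matrix()].
#' @return data.frame with `family`, `total_sites`, `uis_count`, `prc`.
#' @export
family_stats <- function(matrix) {
  info <- parse_site_keys(rownames(matrix))
  rs <- rowSums(matrix)
  dt <- data.table::data.table(family = info$family, uis = rs == 1L,
                               presences = rs)
  st <- dt[, .(total_sites = .N, uis_count = sum(uis),
               presences = sum(presences)), by = family]
  st[, prc := total_sites * ncol(matrix) / presences]
  data.table::setorder(st, family)
  as.data.frame(st[, .(family, total_sites, uis_count, prc)])
}

#' Pearson chi-squared contingency test with a Monte-Carlo p-value
#'
#' Computes `X^2 = sum (O-E)^2 / E` under the independence model and a
#' simulated p-value over tables drawn with both margins fixed, using the
#' add-one estimator `(1 + #{X^2_sim >= X^2_obs}) / (B + 1)`. Pearson
#' residuals `(O-E)/sqrt(E)` are returned per cell. Zero-margin rows or
#' columns are dropped with a warning.
#'
#' @param observed non-negative integer matrix.
#' @param n_replicates Monte-Carlo replicates B.
#' @param seed optional seed for the Monte-Carlo draw.
#' @return list with `observed`, `expected`, `statistic`, `p_value`,
#'   `n_replicates`, `residuals`.
#' @export
contingency_test <- function(observed, n_replicates = 2000L, seed = NULL) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("observed counts must be non-negative")
  rz <- rowSums(observed) == 0
  cz <- colSums(observed) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero row(s) and ", sum(cz),
            " zero column(s)")
    observed <- observed[!rz, !cz, drop = FALSE]
  }
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("need at least a 2x2 table after dropping zero margins")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ct <- suppressWarnings(stats::chisq.test(observed, simulate.p.value = TRUE,
                                           B = as.integer(n_replicates)))
  list(observed = observed, expected = ct$expected,
       statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       n_replicates = as.integer(n_replicates), residuals = ct$residuals)
}

#' Jaccard distances between accessions
#'
#' `d(a,b) = 1 - |Sa intersect Sb| / |Sa union Sb|` over presence sets:
#' only shared presences are informative, shared absences never contribute.
#' Two accessions with empty presence sets are at distance 0.
#'
#' @param matrix presence matrix from [build_matrix()].
#' @return symmetric accession-by-accession distance matrix.
#' @export
jaccard_distances <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least 2 accessions")
  d <- as.matrix(vegan::vegdist(t(matrix), method = "jaccard",
                                binary = TRUE))
  if (any(is.nan(d))) {
    message("accession pairs with empty presence sets set to distance 0")
    d[is.nan(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical scaling: the squared distances are double-centred
#' (`-1/2 J D^2 J`), eigendecomposed, and coordinates are eigenvectors
#' scaled by the square root of each positive eigenvalue. Variance explained
#' is each positive eigenvalue over the sum of positive eigenvalues;
#' negative eigenvalues are reported but excluded from both.
#'
#' @param d symmetric distance matrix with a zero diagonal.
#' @return list with `coordinates` (rows follow `d`'s labels),
#'   `eigenvalues`, `variance_explained`, `negative_eigenvalues`.
#' @export
pcoa_coords <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  list(coordinates = coords, eigenvalues = e$values,
       variance_explained = e$values[pos] / sum(e$values[pos]),
       negative_eigenvalues = e$values[e$values < -tol])
}

#' Spearman correlation between sequencing effort and detected sites
#'
#' Rank-based correlation with average ranks for ties and a two-sided
#' p-value; Shapiro-Wilk normality p-values for both vectors are attached
#' as diagnostics only.
#'
#' @param read_counts,site_counts equal-length numeric vectors (n >= 4).
#' @return list with `rho`, `p_value`, `normality_p`.
#' @export
coverage_correlation <- function(read_counts, site_counts) {
  if (length(read_counts) != length(site_counts))
    stop("vectors must have equal length")
  if (length(read_counts) < 4L) stop("need at least 4 observations")
  if (length(unique(read_counts)) == 1L || length(unique(site_counts)) == 1L)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(read_counts, site_counts,
                                         method = "spearman",
                                         exact = FALSE))
  norm_p <- c(read_counts = stats::shapiro.test(read_counts)$p.value,
              site_counts = stats::shapiro.test(site_counts)$p.value)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       normality_p = norm_p)
}

#' Family-pair co-occurrence at parallel insertion sites
#'
#' For every family pair, counts the parallel insertion sites where both
#' families occur, sums the two families' site totals, and measures the
#' p-distance between their TIR sequences; then reports pairwise Pearson
#' correlations (with two-sided p-values) among the three columns. The
#' expectation under shared transposition machinery is a positive
#' correlation of PIS co-occurrence with cumulative copy number and a
#' negative one with TIR distance.
#'
#' @param matrix presence matrix from [build_matrix()].
#' @param pis PIS data frame from [classify_sites()].
#' @param family_tirs named character vector of per-family TIR sequences.
#' @return list with `pairs` (data frame: family_a, family_b, cooccurrence,
#'   cumulative_sites, tir_distance), `correlations` and `p_values`
#'   (3x3 matrices, or NULL with a warning when fewer than 3 pairs exist).
#' @export
pis_cooccurrence <- function(matrix, pis, family_tirs) {
  info <- parse_site_keys(rownames(matrix))
  fams <- sort(unique(info$family))
  if (length(fams) < 2L) stop("need at least 2 families")
  totals <- table(factor(info$family, levels = fams))
  pairs <- t(utils::combn(fams, 2L))
  co <- integer(nrow(pairs))
  if (nrow(pis)) {
    fam_sets <- strsplit(pis$families, ",", fixed = TRUE)
    for (r in seq_len(nrow(pairs)))
      co[r] <- sum(vapply(fam_sets, function(fs)
        all(pairs[r, ] %in% fs), logical(1)))
  }
  tir_d <- vapply(seq_len(nrow(pairs)), function(r)
    p_distance(family_tirs[[pairs[r, 1]]],
               family_tirs[[pairs[r, 2]]])$distance, numeric(1))
  out <- data.frame(family_a = pairs[, 1], family_b = pairs[, 2],
                    cooccurrence = co,
                    cumulative_sites = as.integer(totals[pairs[, 1]] +
                                                    totals[pairs[, 2]]),
                    tir_distance = tir_d, stringsAsFactors = FALSE)
  if (nrow(out) < 3L) {
    warning("fewer than 3 family pairs; correlations not computed")
    return(list(pairs = out, correlations = NULL, p_values = NULL))
  }
  vars <- c("cooccurrence", "cumulative_sites", "tir_distance")
  cm <- pm <- matrix(NA_real_, 3L, 3L, dimnames = list(vars, vars))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) { cm[i, j] <- 1; pm[i, j] <- 0; next }
    ct <- suppressWarnings(stats::cor.test(out[[vars[i]]], out[[vars[j]]]))
    cm[i, j] <- unname(ct$estimate)
    pm[i, j] <- ct$p.value
  }
  list(pairs = out, correlations = cm, p_values = pm)
}

#' Export insertion sites as GFF3 under the TA coordinate convention
#'
#' Each feature starts on the A of the reference TA target site; the end is
#' the following base — the first nucleotide of the element for
#' reference-borne insertions and the first nucleotide after the target
#' site otherwise. Attributes carry the family, the comma-separated carrier
#' accessions, and the adjacent gene when the site lies within 2 kb of one.
#' Rows whose reference context violates the TA convention are skipped with
#' a message.
#'
#' @param matrix presence matrix from [build_matrix()].
#' @param reference named character vector of chromosome sequences.
#' @param annotation optional annotation (see [classify_insertion()]) for
#'   gene attributes.
#' @param path optional output file.
#' @return the GFF3 data frame, invisibly written to `path` when given.
#' @export
export_insertion_gff <- function(matrix, reference, annotation = NULL,
                                 path = NULL) {
  info <- parse_site_keys(rownames(matrix))
  keep <- vapply(seq_len(nrow(info)), function(i) {
    p <- info$position[i]
    ch <- reference[[info$chrom[i]]]
    !is.null(ch) && p >= 2L && substring(ch, p - 1L, p) == "TA"
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " site(s) without a valid TA reference placement skipped")
  info <- info[keep, , drop = FALSE]
  m <- matrix[keep, , drop = FALSE]
  attrs <- vapply(seq_len(nrow(info)), function(i) {
    carriers <- colnames(m)[m[i, ] == 1L]
    a <- sprintf("ID=%s_%d;family=%s;accessions=%s", info$family[i], i,
                 info$family[i], paste(carriers, collapse = ","))
    if (!is.null(annotation)) {
      cl <- classify_insertion(info$chrom[i], info$position[i], annotation)
      if (!is.null(cl$gene))
        a <- paste0(a, sprintf(";gene=%s;distance=%d", cl$gene$gene_id,
                               cl$gene$distance))
    }
    a
  }, character(1))
  n <- nrow(info)
  df <- data.frame(seqid = info$chrom, source = rep("mitepop", n),
                   type = rep("TE_insertion_site", n), start = info$position,
                   end = info$position + 1L, score = rep(".", n),
                   strand = rep(".", n), phase = rep(".", n),
                   attributes = attrs, stringsAsFactors = FALSE)
  if (!is.null(path)) write_gff3(df, path)
  invisible(df)
}
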