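#' p-distance between two aligned sequences
#'
#' Proportion of differing positions over the positions where both
#' sequences carry a plain A/C/G/T symbol (pairwise deletion of ambiguous
#' or gap positions).
#'
#' @param seq_a,seq_b equal-length sequences.
#' @return list with `distance` and `effective_sites`.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- seq_chars(seq_a)
  b <- seq_chars(seq_b)
  if (length(a) != length(b)) stop("sequences must be of equal length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable positions")
  list(distance = sum(a[ok] != b[ok]) / n, effective_sites = n)
}

#' All-pairs p-distance matrix
#'
#' @param seqs named character vector of equal-length sequences.
#' @return list with `distances` (symmetric matrix) and `effective_sites`.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  labs <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  es <- matrix(nchar(seqs[1]), n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pd <- p_distance(seqs[[i]], seqs[[j]])
    d[i, j] <- d[j, i] <- pd$distance
    es[i, j] <- es[j, i] <- pd$effective_sites
  }
  list(distances = d, effective_sites = es)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion; taxa are ordered
#' by label before joining so that ties break deterministically, and
#' negative branch lengths are clamped to zero with the total deficit
#' recorded in the `clamped_deficit` attribute.
#'
#' @param d symmetric distance matrix with at least 3 labelled taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  tr <- ape::nj(stats::as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  if (deficit > 0) {
    message("clamped negative branch length totalling ", signif(deficit, 4))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds a
#' p-distance/neighbour-joining tree per replicate, and reports for each
#' internal bipartition of the point-estimate tree the percentage of
#' replicates containing it (stored as node labels).
#'
#' @param alignment named character vector of aligned equal-length
#'   sequences.
#' @param n_replicates bootstrap replicates.
#' @param seed seed for the resampling.
#' @return a `phylo` tree with `node.label` support percentages in
#'   `[0, 100]` (NA at the root).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("sequences must be aligned to equal length")
  if (len < 2L) stop("alignment must have at least 2 columns")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  build <- function(m) {
    seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    nj_tree(p_distance_matrix(seqs)$distances)
  }
  point <- build(mat)
  set.seed(as.integer(seed))
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boots[[b]] <- build(mat[, cols, drop = FALSE])
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / n_replicates, 1)
  point
}

#' Within-family similarity summary over element copies
#'
#' Mean pairwise identity (1 - p-distance) and the pairwise distance
#' histogram, whose shape (unimodal vs multimodal) distinguishes a single
#' recent amplification burst from repeated older ones.
#'
#' @param copies named character vector of aligned copies (>= 2).
#' @param breaks histogram breaks passed to [graphics::hist()] semantics;
#'   a count vector over `[0,1]` bins of this width is returned.
#' @return list with `mean_similarity`, `mean_distance`, `distances`
#'   (all pairwise values) and `histogram` (named bin counts).
#' @export
intra_family_similarity <- function(copies, breaks = 0.02) {
  if (length(copies) < 2L) stop("need at least 2 copies")
  pd <- p_distance_matrix(copies)
  dv <- pd$distances[upper.tri(pd$distances)]
  edges <- seq(0, 1, by = breaks)
  cut_idx <- pmin(findInterval(dv, edges, rightmost.closed = TRUE),
                  length(edges) - 1L)
  hist <- setNames(tabulate(cut_idx, nbins = length(edges) - 1L),
                   sprintf("[%.2f,%.2f)", edges[-length(edges)],
                           edges[-1]))
  list(mean_similarity = 1 - mean(dv), mean_distance = mean(dv),
       distances = dv, histogram = hist)
}

#' Concatenated terminal alignment for family phylogenetics
#'
#' Builds the fixed-length comparison sequence for each element: the first
#' `n` bases concatenated with the reverse complement of the last `n`
#' bases, so that near-fixed-length TIR/terminal regions are compared
#' without a gapped alignment step.
#'
#' @param seqs named character vector of element sequences (each at least
#'   `2n` long).
#' @param n terminal window (nt).
#' @return named character vector of `2n`-length sequences.
#' @export
terminal_alignment <- function(seqs, n = 100L) {
  vapply(seqs, function(s) {
    ts <- terminal_sequences(s, n)
    paste0(ts$five_prime, revcomp(ts$three_prime))
  }, character(1))
}
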