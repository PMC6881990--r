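SEGMENT_LABELS <- c("upstream_2kb", "utr5", "cds", "intron", "utr3",
                    "downstream_2kb", "intergenic")

#' Read a gene annotation from GFF3
#'
#' Accepts `gene`/`mRNA`/`exon`/`CDS`/`five_prime_UTR`/`three_prime_UTR`
#' features with 1-based inclusive coordinates and `ID`/`Parent`
#' attributes, as written by [write_annotation_gff3()].
#'
#' @param path GFF3 file.
#' @return annotation list with `genes` and `features` data frames.
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(list(genes = data.frame(gene_id = character(0),
                                   chrom = character(0), start = integer(0),
                                   end = integer(0), strand = character(0)),
                features = data.frame(gene_id = character(0),
                                      chrom = character(0),
                                      type = character(0), start = integer(0),
                                      end = integer(0), strand = character(0))))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  df <- data.frame(chrom = f[, 1], type = f[, 3],
                   start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                   strand = f[, 7], attributes = f[, 9],
                   stringsAsFactors = FALSE)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    sub(paste0(key, "="), "", m)
  }
  g <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = get_attr(g$attributes, "ID"),
                      chrom = g$chrom, start = g$start, end = g$end,
                      strand = g$strand, stringsAsFactors = FALSE)
  fe <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                          "three_prime_UTR"), , drop = FALSE]
  features <- data.frame(
    gene_id = sub("\\.t[0-9]+$", "", get_attr(fe$attributes, "Parent")),
    chrom = fe$chrom, type = fe$type, start = fe$start, end = fe$end,
    strand = fe$strand, stringsAsFactors = FALSE)
  list(genes = genes, features = features)
}

# Nearest flanking gene with the deterministic tie rule: the gene whose
# boundary is closer wins; on an exact tie the following gene (greater
# coordinate) is taken.
nearest_flanking_gene <- function(position, genes_chrom) {
  prev <- genes_chrom[genes_chrom$end < position, , drop = FALSE]
  nxt <- genes_chrom[genes_chrom$start > position, , drop = FALSE]
  prev <- if (nrow(prev)) prev[which.max(prev$end), , drop = FALSE] else NULL
  nxt <- if (nrow(nxt)) nxt[which.min(nxt$start), , drop = FALSE] else NULL
  d_prev <- if (is.null(prev)) Inf else position - prev$end
  d_next <- if (is.null(nxt)) Inf else nxt$start - position
  if (is.infinite(d_prev) && is.infinite(d_next)) return(NULL)
  if (d_next <= d_prev) list(gene = nxt, distance = d_next, before = TRUE)
  else list(gene = prev, distance = d_prev, before = FALSE)
}

#' Classify an insertion position against a gene annotation
#'
#' Positions inside a transcript resolve to `utr5`/`cds`/`utr3` when inside
#' the respective exonic sub-feature and to `intron` otherwise; a gene body
#' always beats the flank window of a neighbouring gene. Outside genes, the
#' strand-aware `upstream_2kb`/`downstream_2kb` label of the nearest gene
#' within `flank` bp applies (nearest boundary wins; exact ties go to the
#' following gene); everything else is `intergenic`.
#'
#' @param chrom,position insertion coordinate (the A of the TA site).
#' @param annotation list with `genes` and `features` data frames.
#' @param flank flank window (bp).
#' @return list with `label` and `gene` (list of `gene_id`, signed
#'   `distance` — 0 inside the gene, negative upstream, positive downstream
#'   of it — and `strand`; NULL for intergenic positions).
#' @export
classify_insertion <- function(chrom, position, annotation, flank = 2000L) {
  genes <- annotation$genes[annotation$genes$chrom == chrom, , drop = FALSE]
  if (nrow(annotation$features)) {
    gi <- match(annotation$features$gene_id, annotation$genes$gene_id)
    if (anyNA(gi) ||
        any(annotation$features$start < annotation$genes$start[gi]) ||
        any(annotation$features$end > annotation$genes$end[gi]))
      stop("malformed annotation: sub-feature outside its gene")
  }
  inside <- genes[genes$start <= position & genes$end >= position, ,
                  drop = FALSE]
  if (nrow(inside)) {
    g <- inside[1, , drop = FALSE]
    fe <- annotation$features[annotation$features$gene_id == g$gene_id, ,
                              drop = FALSE]
    at <- function(type) {
      sub <- fe[fe$type == type, , drop = FALSE]
      any(sub$start <= position & sub$end >= position)
    }
    label <- if (at("CDS")) "cds"
    else if (at("five_prime_UTR")) "utr5"
    else if (at("three_prime_UTR")) "utr3"
    else "intron"
    return(list(label = label,
                gene = list(gene_id = g$gene_id, distance = 0L,
                            strand = g$strand)))
  }
  nf <- nearest_flanking_gene(position, genes)
  if (is.null(nf) || nf$distance > flank)
    return(list(label = "intergenic", gene = NULL))
  g <- nf$gene
  upstream <- (nf$before && g$strand == "+") || (!nf$before && g$strand == "-")
  list(label = if (upstream) "upstream_2kb" else "downstream_2kb",
       gene = list(gene_id = g$gene_id,
                   distance = if (upstream) -as.integer(nf$distance)
                   else as.integer(nf$distance),
                   strand = g$strand))
}

#' Cumulative length of each genic segment class
#'
#' Partitions every base of the genome into the seven labels under exactly
#' the [classify_insertion()] precedence rules (gene bodies beat flanks,
#' nearest gene wins overlapping flank windows, flanks truncate at
#' chromosome ends), so the label lengths always sum to the genome length.
#'
#' @param annotation list with `genes` and `features` data frames.
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param flank flank window (bp).
#' @return named numeric vector of cumulative bp per label.
#' @export
segment_lengths <- function(annotation, genome_lengths, flank = 2000L) {
  out <- setNames(numeric(length(SEGMENT_LABELS)), SEGMENT_LABELS)
  for (ch in names(genome_lengths)) {
    L <- as.integer(genome_lengths[[ch]])
    genes <- annotation$genes[annotation$genes$chrom == ch, , drop = FALSE]
    feats <- annotation$features[annotation$features$chrom == ch, ,
                                 drop = FALSE]
    bp <- c(1L, L + 1L,
            genes$start, genes$end + 1L,
            pmax(1L, genes$start - flank), pmin(L + 1L, genes$end + flank + 1L),
            feats$start, feats$end + 1L)
    if (nrow(genes) >= 2L) {
      go <- genes[order(genes$start), , drop = FALSE]
      mids <- floor((go$end[-nrow(go)] + go$start[-1]) / 2)
      bp <- c(bp, mids, mids + 1L)
    }
    bp <- sort(unique(pmax(1L, pmin(L + 1L, bp))))
    starts <- bp[-length(bp)]
    ends <- bp[-1] - 1L
    for (i in seq_along(starts)) {
      mid <- starts[i] + (ends[i] - starts[i]) %/% 2L
      lab <- classify_insertion(ch, mid, annotation, flank)$label
      out[lab] <- out[lab] + (ends[i] - starts[i] + 1L)
    }
  }
  out
}

#' Insertion density per 100 kb of each segment class
#'
#' @param counts named counts per label.
#' @param lengths named cumulative lengths (bp) per label.
#' @return named rates per 100 kb.
#' @export
density_per_100kb <- function(counts, lengths) {
  labs <- names(counts)
  lengths <- lengths[labs]
  if (any(counts > 0 & lengths <= 0))
    stop("non-zero count over a zero-length segment class")
  out <- ifelse(lengths > 0, counts / lengths * 1e5, 0)
  setNames(as.numeric(out), labs)
}

#' Distance-to-gene histograms for insertions near genes
#'
#' Insertions outside gene bodies whose nearest gene lies within `span` bp
#' are binned by signed distance in `window`-bp half-open bins
#' `[k*window, (k+1)*window)`, separately for the strand-aware upstream and
#' downstream sides (a distance equal to `span` falls in the last bin).
#'
#' @param insertions data.frame with `chrom` and `position`.
#' @param annotation list with `genes` and `features` data frames.
#' @param window bin width (bp); must divide `span`.
#' @param span maximum distance (bp).
#' @return list with `upstream` and `downstream` named count vectors and
#'   `breaks` (bin lower edges).
#' @export
distance_profile <- function(insertions, annotation, window = 20L,
                             span = 2000L) {
  if (span %% window != 0L) stop("window must divide span")
  nb <- span %/% window
  edges <- (seq_len(nb) - 1L) * window
  bn <- sprintf("[%d,%d)", edges, edges + window)
  up <- setNames(integer(nb), bn)
  down <- setNames(integer(nb), bn)
  for (i in seq_len(nrow(insertions))) {
    ch <- insertions$chrom[i]
    p <- insertions$position[i]
    genes <- annotation$genes[annotation$genes$chrom == ch, , drop = FALSE]
    if (any(genes$start <= p & genes$end >= p)) next
    nf <- nearest_flanking_gene(p, genes)
    if (is.null(nf) || nf$distance > span) next
    b <- min(nf$distance %/% window, nb - 1L) + 1L
    g <- nf$gene
    upstream <- (nf$before && g$strand == "+") ||
      (!nf$before && g$strand == "-")
    if (upstream) up[b] <- up[b] + 1L else down[b] <- down[b] + 1L
  }
  list(upstream = up, downstream = down, breaks = edges)
}

#' Genes associated with insertions, per accession
#'
#' For each accession, the set of genes carrying at least one insertion in
#' the gene body or within `flank` bp (using the [classify_insertion()]
#' association, one gene per insertion).
#'
#' @param matrix presence matrix from [build_matrix()].
#' @param annotation list with `genes` and `features` data frames.
#' @param flank flank window (bp).
#' @return list with `per_accession` (named list of gene-id vectors),
#'   `counts` (data frame) and `union` (all associated genes).
#' @export
associate_genes <- function(matrix, annotation, flank = 2000L) {
  info <- parse_site_keys(rownames(matrix))
  gene_of <- vapply(seq_len(nrow(info)), function(i) {
    cl <- classify_insertion(info$chrom[i], info$position[i], annotation,
                             flank)
    if (is.null(cl$gene)) NA_character_ else cl$gene$gene_id
  }, character(1))
  per <- lapply(colnames(matrix), function(a) {
    g <- gene_of[matrix[, a] == 1L]
    sort(unique(g[!is.na(g)]))
  })
  names(per) <- colnames(matrix)
  list(per_accession = per,
       counts = data.frame(accession = colnames(matrix),
                           n_genes = vapply(per, length, integer(1)),
                           row.names = NULL),
       union = sort(unique(unlist(per))))
}
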