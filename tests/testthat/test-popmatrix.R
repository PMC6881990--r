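calls_df <- function(...) {
  df <- data.frame(...)
  names(df) <- c("accession", "chrom", "position", "family")
  df
}

random_matrix <- function(n_sites, n_acc, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_acc, 1L, 0.4), n_sites, n_acc)
  m[rowSums(m) == 0, sample(n_acc, 1)] <- 1L
  fams <- sample(c("F1", "F2", "F3"), n_sites, replace = TRUE)
  rownames(m) <- paste("chr1", seq_len(n_sites) * 100L, fams, sep = ":")
  colnames(m) <- sprintf("a%02d", seq_len(n_acc))
  m
}

test_that("matrix building keys rows by chrom:pos:family", {
  one <- calls_df("A", "chr1", c(100L, 200L, 300L), "F1")
  m1 <- build_matrix(one)
  expect_equal(dim(m1), c(3L, 1L))
  expect_true(all(m1 == 1L))
  two <- rbind(calls_df(c("A", "B"), "chr1", 100L, "F1"),
               calls_df("A", "chr1", 200L, "F1"),
               calls_df("B", "chr1", 300L, "F2"))
  m2 <- build_matrix(two)
  expect_equal(dim(m2), c(3L, 2L))
  expect_equal(unname(colSums(m2)), c(2L, 2L))
  pis <- rbind(calls_df("A", "chr1", 500L, "F1"),
               calls_df("B", "chr1", 500L, "F2"))
  m3 <- build_matrix(pis)
  expect_equal(nrow(m3), 2L)
  expect_warning(build_matrix(rbind(one, one)), "duplicate")
})

test_that("site classification matches brute-force row sums and finds PIS", {
  m <- build_matrix(calls_df("solo", "chr1", c(10L, 20L), c("F1", "F2")))
  expect_true(all(classify_sites(m)$sites$class == "uis"))
  m5 <- matrix(c(1, 0, 0, 0,
                 1, 1, 0, 0,
                 1, 1, 1, 1,
                 0, 1, 0, 0,
                 1, 1, 1, 0), 5, 4, byrow = TRUE,
               dimnames = list(c("chr1:100:F1", "chr1:200:F1", "chr1:300:F2",
                                 "chr1:300:F1", "chr2:100:F2"),
                               c("a", "b", "c", "d")))
  cl <- classify_sites(m5)
  expect_equal(cl$sites$class,
               unname(ifelse(rowSums(m5) == 1, "uis",
                             ifelse(rowSums(m5) == 4, "fixed", "shared"))))
  expect_equal(nrow(cl$pis), 1L)
  expect_equal(cl$pis$position, 300L)
  expect_equal(cl$pis$n_families, 2L)
  # three co-located families yield one record with 3 families
  m3 <- build_matrix(rbind(calls_df("A", "chr1", 700L, "F1"),
                           calls_df("B", "chr1", 700L, "F2"),
                           calls_df("C", "chr1", 700L, "F3")))
  cl3 <- classify_sites(m3)
  expect_equal(cl3$pis$n_families, 3L)
})

test_that("PrC follows the sites-over-mean-presences formula and bounds", {
  fixed <- matrix(1L, 4, 31,
                  dimnames = list(paste0("chr1:", 1:4 * 100, ":F1"),
                                  sprintf("a%02d", 1:31)))
  expect_equal(prc(fixed, "F1"), 1)
  uis <- matrix(0L, 4, 31,
                dimnames = dimnames(fixed))
  uis[cbind(1:4, 1:4)] <- 1L
  expect_equal(prc(uis, "F1"), 31)
  m <- random_matrix(20, 8, seed = 1)
  for (f in c("F1", "F2", "F3")) {
    rows <- grepl(paste0(":", f, "$"), rownames(m))
    if (!any(rows)) next
    S <- sum(rows); tot <- sum(m[rows, ])
    expect_equal(prc(m, f), S * 8 / tot)
    expect_gte(prc(m, f), 1)
    expect_lte(prc(m, f), 8)
  }
  expect_error(prc(m, "nope"), "not present")
  fs <- family_stats(m)
  info <- do.call(rbind, strsplit(rownames(m), ":"))
  expect_equal(sum(fs$total_sites), nrow(m))
  expect_equal(sum(fs$uis_count), sum(rowSums(m) == 1))
})

test_that("chi-squared contingency test matches closed forms and oracle", {
  indep <- outer(c(10, 20), c(5, 15)) / 5
  r <- contingency_test(indep, n_replicates = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- contingency_test(matrix(c(10, 0, 0, 10), 2, 2), seed = 2)
  expect_equal(r2$statistic, 20)
  expect_lte(r2$p_value, 0.01)
  expect_equal(r2$n_replicates, 2000L)
  set.seed(3)
  tab <- matrix(rpois(12, 20), 3, 4)
  r3 <- contingency_test(tab, n_replicates = 100, seed = 4)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(r3$residuals), unname((tab - E) / sqrt(E)),
               tolerance = 1e-12)
  expect_equal(r3$statistic, sum((tab - E)^2 / E))
  expect_warning(contingency_test(rbind(tab, 0), n_replicates = 100,
                                  seed = 5), "zero")
})

test_that("Jaccard distances use presences only and form a semimetric", {
  m <- build_matrix(rbind(calls_df("A", "chr1", c(1, 2, 3) * 100L, "F1"),
                          calls_df("B", "chr1", c(2, 3, 4) * 100L, "F1")))
  d <- jaccard_distances(m)
  expect_equal(d["A", "B"], 0.5)       # 1 - 2/4
  ident <- build_matrix(rbind(calls_df("A", "chr1", c(100L, 200L), "F1"),
                              calls_df("B", "chr1", c(100L, 200L), "F1")))
  expect_equal(jaccard_distances(ident)["A", "B"], 0)
  disj <- build_matrix(rbind(calls_df("A", "chr1", 100L, "F1"),
                             calls_df("B", "chr1", 200L, "F1")))
  expect_equal(jaccard_distances(disj)["A", "B"], 1)
  for (s in 1:5) {
    dm <- jaccard_distances(random_matrix(15, 6, seed = s))
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
    n <- nrow(dm)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("PCoA recovers planted configurations up to rotation", {
  # two points at distance d
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- pcoa_coords(d2)
  expect_equal(ncol(p2$coordinates), 1L)
  expect_equal(unname(sort(abs(p2$coordinates[, 1]))), c(1.5, 1.5))
  expect_equal(p2$variance_explained, 1)
  # planted planar configuration
  set.seed(6)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(letters[1:10], letters[1:10])
  p <- pcoa_coords(D)
  Y <- p$coordinates[, 1:2]
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(t(Yc) %*% Xc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(sqrt(mean((Yc %*% rot - Xc)^2)), 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(sum(p$variance_explained), 1)
  expect_error(pcoa_coords(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Spearman correlation handles monotone and tied inputs", {
  x <- 1:10
  expect_equal(coverage_correlation(x, x * 3 + 2)$rho, 1)
  expect_equal(coverage_correlation(x, rev(x))$rho, -1)
  set.seed(7)
  a <- sample(1:5, 20, replace = TRUE)
  b <- sample(1:5, 20, replace = TRUE)
  got <- coverage_correlation(a, b)
  expect_equal(got$rho, unname(cor(rank(a), rank(b))), tolerance = 1e-12)
  expect_error(coverage_correlation(rep(1, 5), 1:5), "constant")
  expect_error(coverage_correlation(1:3, 1:3), "at least 4")
})

test_that("PIS co-occurrence counts equal brute-force pair enumeration", {
  calls <- rbind(calls_df("A", "chr1", 100L, "F1"),
                 calls_df("B", "chr1", 100L, "F2"),
                 calls_df("A", "chr1", 300L, "F1"),
                 calls_df("C", "chr1", 300L, "F3"),
                 calls_df("B", "chr1", 500L, "F2"),
                 calls_df("C", "chr1", 500L, "F3"),
                 calls_df("A", "chr2", 100L, "F1"))
  m <- build_matrix(calls)
  cl <- classify_sites(m)
  tirs <- c(F1 = "ACGTACGTAC", F2 = "ACGTACGTAT", F3 = "TTTTACGGGG")
  res <- pis_cooccurrence(m, cl$pis, tirs)
  pr <- res$pairs
  expect_equal(pr$cooccurrence[pr$family_a == "F1" & pr$family_b == "F2"], 1L)
  expect_equal(pr$cooccurrence[pr$family_a == "F1" & pr$family_b == "F3"], 1L)
  expect_equal(pr$cooccurrence[pr$family_a == "F2" & pr$family_b == "F3"], 1L)
  expect_equal(pr$cumulative_sites[pr$family_a == "F1" & pr$family_b == "F2"],
               3L + 2L)
  expect_equal(pr$tir_distance[pr$family_a == "F1" & pr$family_b == "F2"],
               0.1)
  expect_true(is.matrix(res$correlations))
  # no PIS at all: zero co-occurrence everywhere
  m0 <- build_matrix(calls[c(1, 3, 5), ])
  cl0 <- classify_sites(m0)
  expect_warning(res0 <- pis_cooccurrence(m0, cl0$pis, tirs[1:2]),
                 "fewer than 3")
  expect_true(all(suppressWarnings(
    pis_cooccurrence(m0, cl0$pis, tirs[1:2]))$pairs$cooccurrence == 0L))
})

test_that("GFF export follows the TA coordinate convention", {
  set.seed(8)
  ref <- c(chr1 = rand_dna(5000, 0.6))
  s <- strsplit(ref[[1]], "")[[1]]
  ta <- which(s == "T" & c(s[-1], "") == "A") + 1L
  pos <- ta[ta > 100][1:3]
  m <- build_matrix(calls_df(c("A", "A", "B"), "chr1", pos, "F1"))
  gff <- export_insertion_gff(m, ref)
  expect_equal(nrow(gff), 3L)
  expect_equal(gff$start, sort(pos))
  expect_equal(gff$end, sort(pos) + 1L)
  for (i in 1:3)
    expect_identical(substring(ref[[1]], gff$start[i] - 1L, gff$start[i]),
                     "TA")
  # a site off the TA convention is skipped with a message
  bad <- build_matrix(rbind(calls_df("A", "chr1", pos[1], "F1"),
                            calls_df("A", "chr1", pos[1] + 1L, "F1")))
  expect_message(g2 <- export_insertion_gff(bad, ref), "skipped")
  expect_equal(nrow(g2), 1L)
  # empty matrix gives a header-only file
  path <- withr::local_tempfile(fileext = ".gff3")
  m0 <- m[0, , drop = FALSE]
  export_insertion_gff(m0, ref, path = path)
  expect_identical(readLines(path), "##gff-version 3")
})
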