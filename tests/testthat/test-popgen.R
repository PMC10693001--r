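test_that("folded AFS folds at half the copies and conserves locus counts", {
  dos <- matrix(0L, nrow = 3, ncol = 10)
  dos[1, 1] <- 1L            # one het -> bin 1
  dos[2, ] <- 1L             # p = 0.5 -> top folded bin (10 of 20 copies)
  # locus 3 monomorphic -> excluded
  coh <- make_cohort(dos)
  afs <- folded_afs(coh, categories = rep("INDEL", 3))
  expect_equal(afs$count[afs$bin == 1], 1L)
  expect_equal(afs$count[afs$bin == 10], 1L)
  expect_equal(attr(afs, "n_monomorphic"), 1L)

  coh2 <- make_neutral_cohort(400, 12, seed = 2)
  afs2 <- folded_afs(coh2)
  expect_equal(sum(afs2$count) + attr(afs2, "n_monomorphic"), 400L)
  expect_lte(max(afs2$bin), 12)
})

test_that("Tajima's D has the textbook signs and matches the oracle", {
  singles <- diag(1L, 12)[, 1:5]  # 12 loci, 5 diploids, one singleton each
  expect_lt(tajimas_d(singles), 0)
  common <- matrix(1L, nrow = 12, ncol = 5)
  common[, 1] <- 0L
  common[, 2] <- 2L  # keeps p = 0.5 with variation across individuals
  expect_gt(tajimas_d(common), 0)

  set.seed(21)
  toy <- matrix(rbinom(50 * 8, 2, runif(50, 0.05, 0.95)), nrow = 50)
  expect_equal(tajimas_d(toy), oracle_tajima(toy), tolerance = 1e-10)

  expect_error(tajimas_d(matrix(0L, 5, 4)), "polymorphic")
})

test_that("Hudson FST matches its printed formula and limiting cases", {
  n <- 40
  alg <- hudson_fst(0.5, n, 0.5, n)
  expect_equal(alg$numerator, -2 * 0.25 / (n - 1))
  expect_lt(alg$fst, 0)
  expect_equal(hudson_fst(1, 20, 0, 20)$fst, 1)

  set.seed(22)
  p1 <- runif(1000)
  p2 <- runif(1000)
  n1 <- sample(seq(4, 80, 2), 1000, TRUE)
  n2 <- sample(seq(4, 80, 2), 1000, TRUE)
  got <- hudson_fst(p1, n1, p2, n2)
  want <- oracle_hudson(p1, n1, p2, n2)
  expect_equal(got$numerator, want$num, tolerance = 1e-12)
  expect_equal(got$denominator, want$den, tolerance = 1e-12)

  # symmetry and allele-relabelling invariance
  sym <- hudson_fst(p2, n2, p1, n1)
  expect_equal(got$fst, sym$fst, tolerance = 1e-12)
  flip <- hudson_fst(1 - p1, n1, 1 - p2, n2)
  expect_equal(got$fst, flip$fst, tolerance = 1e-12)

  expect_error(hudson_fst(0.5, 1, 0.5, 10), "2 allele copies")
  expect_true(is.na(hudson_fst(0, 10, 0, 10)$fst))
})

test_that("genome-wide FST is the ratio of sums", {
  one <- hudson_fst(0.7, 30, 0.2, 30)
  expect_equal(fst_genomewide(one$numerator, one$denominator), one$fst)
  many <- hudson_fst(rep(0.7, 10), 30, rep(0.2, 10), 30)
  expect_equal(fst_genomewide(many$numerator, many$denominator), one$fst)
  expect_error(fst_genomewide(0, 0), "undefined")
})

test_that("PBS follows the log-transform identity and zero case", {
  dos <- matrix(rbinom(40 * 30, 2, 0.4), nrow = 40)
  coh <- make_cohort(dos)
  groups <- setNames(rep(c("NW", "SW", "SE"), each = 10),
                     colnames(coh$geno))
  res <- pbs(coh, groups)
  Tm <- -log(1 - pmin(pmax(cbind(res$fst_NW_SW, res$fst_NW_SE,
                                 res$fst_SW_SE), 0), 1 - 1e-12))
  expect_equal(res$pbs_NW + res$pbs_SW + res$pbs_SE,
               unname(rowSums(Tm)) / 2, tolerance = 1e-12)
  expect_equal(res$pbs_SE,
               unname((Tm[, 2] + Tm[, 3] - Tm[, 1]) / 2), tolerance = 1e-12)

  # hand case: fst(SE,NW) = fst(SE,SW) = 0.5, fst(NW,SW) = 0
  T5 <- -log(1 - 0.5)
  expect_equal((T5 + T5 - 0) / 2, -log(0.5), tolerance = 1e-12)
})

test_that("PBS outlier genes use the per-group quantile with brute force", {
  set.seed(30)
  m <- 100
  starts <- seq_len(m) * 5000L
  pbs_tbl <- tibble::tibble(
    id = sprintf("L%03d", 1:m), chrom = "chr1", start = starts,
    end = starts + 200L, svtype = "DEL",
    pbs_NW = rnorm(m), pbs_SW = rnorm(m), pbs_SE = rnorm(m))
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
                          start = sample(1:490000, 40), end = 0L)
  genes$end <- genes$start + sample(3000:20000, 40, TRUE)
  out <- pbs_outlier_genes(pbs_tbl, genes)
  expect_named(out, c("NW", "SW", "SE"))
  expect_equal(attr(out$NW, "n_outlier_loci"), 5L)
  thr <- quantile(pbs_tbl$pbs_SE, 0.95, names = FALSE)
  sel <- pbs_tbl[pbs_tbl$pbs_SE >= thr, ]
  brute <- oracle_overlap(sel, genes)
  expect_setequal(out$SE$gene_id, unique(genes$gene_id[brute[, 2]]))
})

test_that("LD r-squared behaves at its limits and controls avoid inversions", {
  layout <- simulate_layout(c(chr1 = 1e6))
  inversions <- tibble::tibble(chrom = "chr1", start = 100000L, end = 110000L)
  n_ind <- 40
  set.seed(31)
  inv_geno <- matrix(rbinom(n_ind, 2, 0.5), nrow = 1)
  base <- rbinom(n_ind, 2, 0.5)
  pos <- sort(sample(100000:109999, 12))
  snp_info <- tibble::tibble(chrom = "chr1", pos = pos)
  snp_geno <- matrix(rep(base, each = 12), nrow = 12)  # perfectly correlated
  ld <- ld_profile(snp_info, snp_geno, inversions, inv_geno, layout, seed = 3)
  expect_true(all(ld$mean_r2[ld$stratum != "colinear-control"] >= 1 - 1e-12))
  expect_equal(nrow(oracle_overlap(attr(ld, "control_regions"), inversions)), 0)

  # independent SNPs: mean r^2 near the 1/(n-1) null over all pairs
  set.seed(32)
  n2 <- 200
  g2 <- matrix(rbinom(40 * n2, 2, 0.5), nrow = 40)
  r2 <- cor(t(g2))^2
  expect_equal(mean(r2[upper.tri(r2)]), 1 / (n2 - 1), tolerance = 0.3)
})

test_that("PCA separates duplicated clusters and conserves variance", {
  set.seed(33)
  a <- rbinom(60, 2, 0.5)
  b <- rbinom(60, 2, 0.5)
  dos <- cbind(a, a, a, a, b, b, b, b) + 0L
  coh <- make_cohort(dos)
  pc <- sv_pca(coh, min_maf = 0.05)
  s1 <- pc$scores[1:4, 1]
  s2 <- pc$scores[5:8, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))

  dos2 <- matrix(rbinom(50 * 20, 2, runif(50, 0.2, 0.8)), nrow = 50)
  coh2 <- make_cohort(dos2)
  pc2 <- sv_pca(coh2, min_maf = 0)
  expect_equal(sum(pc2$eigenvalues), pc2$n_loci, tolerance = 1e-8)
  # scores match a direct SVD up to sign
  keep <- apply(dos2, 1, sd) > 0
  M <- scale(t(dos2[keep, , drop = FALSE]))
  sv <- svd(M)
  direct <- sv$u %*% diag(sv$d)
  for (k in 1:3) {
    expect_equal(unname(abs(pc2$scores[, k])), abs(direct[, k]),
                 tolerance = 1e-8)
  }
})
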