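#' Per-locus, per-group allele counts
#'
#' For each locus and group: `n` sampled allele copies (2 x non-missing
#' diploid individuals), `k` alternate-allele copies, and the sample
#' frequency `p = k / n`.
#'
#' @param cohort An [sv_cohort()] object.
#' @param groups Named character vector mapping individual ids (the cohort's
#'   column names) to group labels.
#' @return Tibble with `id`, `group`, `n`, `k`, `p`.
#' @export
group_allele_counts <- function(cohort, groups) {
  stopifnot(inherits(cohort, "sv_cohort"))
  inds <- colnames(cohort$geno)
  miss <- setdiff(inds, names(groups))
  if (length(miss)) stop("individuals without a group: ",
                         paste(miss, collapse = ", "))
  grp <- groups[inds]
  purrr::map_dfr(unique(grp), function(g) {
    sub <- cohort$geno[, grp == g, drop = FALSE]
    n <- 2L * rowSums(!is.na(sub))
    k <- rowSums(sub, na.rm = TRUE)
    tibble::tibble(id = cohort$loci$id, group = g, n = n, k = k,
                   p = ifelse(n > 0, k / n, NA_real_))
  })
}

# pool insertions and deletions: reference-relative polarity is arbitrary
pool_indel <- function(svtype) {
  ifelse(svtype %in% c("INS", "DEL"), "INDEL", svtype)
}

#' Folded allele-frequency spectrum
#'
#' Histograms the minor-allele copy count of each polymorphic locus, folded
#' at half the sampled copies: the allele with frequency <= 0.5 is the minor
#' allele, and a locus at exactly 0.5 falls into the highest folded bin. By
#' default loci are categorized by svtype with insertions and deletions
#' pooled as INDEL (their polarity relative to the reference is arbitrary).
#' Monomorphic loci are excluded; their count is reported as an attribute.
#'
#' @param cohort An [sv_cohort()] object.
#' @param categories Optional per-locus category labels (length = number of
#'   loci); defaults to the pooled svtype.
#' @return Tibble with `category`, `bin` (minor copies) and `count`, with
#'   attribute `n_monomorphic`.
#' @export
folded_afs <- function(cohort, categories = NULL) {
  stopifnot(inherits(cohort, "sv_cohort"))
  if (is.null(categories)) categories <- pool_indel(cohort$loci$svtype)
  stopifnot(length(categories) == nrow(cohort$geno))
  n <- 2L * rowSums(!is.na(cohort$geno))
  k <- rowSums(cohort$geno, na.rm = TRUE)
  k_minor <- pmin(k, n - k)
  poly <- k_minor > 0
  out <- tibble::tibble(category = categories[poly], bin = k_minor[poly]) |>
    dplyr::count(.data$category, .data$bin, name = "count")
  attr(out, "n_monomorphic") <- sum(!poly)
  out
}

#' Tajima's D over a set of loci
#'
#' Standard normalized difference between pairwise diversity and Watterson's
#' estimator. Loci with any missing dosage are dropped so the sample size is
#' uniform; `n` is then 2 x the number of individuals.
#'
#' @param geno Dosage matrix (loci x individuals) or an [sv_cohort()].
#' @return Tajima's D (scalar).
#' @export
tajimas_d <- function(geno) {
  if (inherits(geno, "sv_cohort")) geno <- geno$geno
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  n <- 2L * ncol(geno)
  if (n < 4) stop("need at least 2 individuals")
  p <- rowMeans(geno) / 2
  poly <- p > 0 & p < 1
  S <- sum(poly)
  if (S == 0) stop("no polymorphic loci: Tajima's D undefined")
  p <- p[poly]
  pi_hat <- sum(2 * p * (1 - p) * n / (n - 1))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Hudson's FST for two populations, per locus
#'
#' The allele-frequency estimator with finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. A locus with zero denominator (both populations
#' fixed for the same allele) is flagged undefined (`NA`).
#'
#' @param p1,p2 Per-locus sample allele frequencies.
#' @param n1,n2 Per-locus sampled allele copies (>= 2).
#' @return Tibble with `numerator`, `denominator`, `fst`.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("need at least 2 allele copies per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble::tibble(numerator = num, denominator = den,
                 fst = ifelse(den > 0, num / den, NA_real_))
}

#' Genome-wide weighted FST (ratio of averages)
#'
#' @param numerator,denominator Per-locus Hudson components; undefined loci
#'   (NA) are dropped.
#' @return Scalar weighted FST = sum(num) / sum(den).
#' @export
fst_genomewide <- function(numerator, denominator) {
  ok <- stats::complete.cases(numerator, denominator)
  den <- sum(denominator[ok])
  if (!(den > 0)) stop("sum of denominators is zero: FST undefined")
  sum(numerator[ok]) / den
}

#' Population branch statistic across three groups
#'
#' Computes per-locus Hudson FST for the three group pairs, converts each to
#' a branch-length scale `T = -ln(1 - FST)` (FST clamped to `[0, 1 - 1e-12]`
#' so T is a finite non-negative branch length) and forms, for each focal
#' group X with the others Y and Z, `PBS_X = (T_XY + T_XZ - T_YZ) / 2`.
#' Loci with an undefined FST for any pair are dropped and counted.
#'
#' @param cohort An [sv_cohort()] object.
#' @param groups Named group assignment as in [group_allele_counts()].
#' @param focal Character vector of the three group labels to contrast.
#' @return Tibble with locus info, the three pairwise `fst_*` columns and a
#'   `pbs_*` column per focal group; attribute `n_dropped` counts loci
#'   removed for undefined FST.
#' @export
pbs <- function(cohort, groups, focal = c("NW", "SW", "SE")) {
  stopifnot(length(focal) == 3)
  counts <- group_allele_counts(cohort, groups)
  counts <- counts[counts$group %in% focal, ]
  cw <- tidyr::pivot_wider(counts, names_from = "group",
                           values_from = c("n", "k", "p"))
  pairs <- utils::combn(focal, 2, simplify = FALSE)
  fst <- lapply(pairs, function(pr) {
    hudson_fst(cw[[paste0("p_", pr[1])]], cw[[paste0("n_", pr[1])]],
               cw[[paste0("p_", pr[2])]], cw[[paste0("n_", pr[2])]])$fst
  })
  names(fst) <- vapply(pairs, paste, character(1), collapse = "_")
  fst <- tibble::as_tibble(fst)
  ok <- stats::complete.cases(fst)
  Tm <- -log(1 - pmin(pmax(as.matrix(fst), 0), 1 - 1e-12))
  pair_has <- function(g) vapply(pairs, function(pr) g %in% pr, logical(1))
  out <- cohort$loci[match(cw$id, cohort$loci$id),
                     c("id", "chrom", "start", "end", "svtype")]
  names(fst) <- paste0("fst_", names(fst))
  out <- dplyr::bind_cols(out, fst)
  for (g in focal) {
    own <- pair_has(g)
    out[[paste0("pbs_", g)]] <- (rowSums(Tm[, own, drop = FALSE]) -
                                   Tm[, !own]) / 2
  }
  res <- out[ok, ]
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Genes overlapping top-quantile PBS loci
#'
#' For each focal group, selects loci at or above the group's empirical
#' `quantile` of PBS (ties at the threshold included) and returns the genes
#' overlapping them by at least one bp, deduplicated.
#'
#' @param pbs_tbl Output of [pbs()].
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param quantile Empirical quantile defining outliers (default 0.95).
#' @return Named list (per focal group) of tibbles with `gene_id` and the
#'   group's PBS threshold as attribute `threshold`.
#' @export
pbs_outlier_genes <- function(pbs_tbl, genes, quantile = 0.95) {
  pbs_cols <- grep("^pbs_", names(pbs_tbl), value = TRUE)
  out <- lapply(pbs_cols, function(cl) {
    x <- pbs_tbl[[cl]]
    thr <- stats::quantile(x, quantile, names = FALSE, type = 7)
    sel <- pbs_tbl[x >= thr, ]
    hits <- overlap_pairs(sel, genes)
    res <- tibble::tibble(gene_id = unique(genes$gene_id[hits$subject]))
    attr(res, "threshold") <- thr
    attr(res, "n_outlier_loci") <- nrow(sel)
    res
  })
  names(out) <- sub("^pbs_", "", pbs_cols)
  out
}

#' Linkage disequilibrium inside inversions versus colinear controls
#'
#' For each inversion interval, r-squared (squared Pearson correlation of
#' dosages) is computed between all SNP pairs inside the interval, binned by
#' pairwise distance, separately among major-arrangement homozygotes and
#' minor-arrangement homozygotes. A control stratum uses the same number of
#' randomly placed, size-matched colinear intervals (rejection-sampled so
#' they never overlap an inversion) with all individuals. SNP pairs where
#' either SNP is monomorphic within a stratum are skipped.
#'
#' @param snp_info Tibble of SNP positions (`chrom`, `pos`).
#' @param snp_geno Dosage matrix, SNPs x individuals, rows aligned with
#'   `snp_info`.
#' @param inversions Tibble of inversion loci (`chrom`, `start`, `end`).
#' @param inv_geno Matrix (inversions x individuals) of inversion dosages
#'   used to split individuals into homozygote classes.
#' @param layout Genome layout for control placement.
#' @param bin_width,max_dist LD distance binning in bp.
#' @param seed Seed for control placement.
#' @return Tibble with `stratum`, `bin_start`, `bin_mid`, `mean_r2`,
#'   `n_pairs`; control intervals in attribute `control_regions`.
#' @export
ld_profile <- function(snp_info, snp_geno, inversions, inv_geno, layout,
                       bin_width = 500, max_dist = 10000, seed = 1) {
  stopifnot(nrow(snp_info) == nrow(snp_geno),
            nrow(inversions) == nrow(inv_geno))
  controls <- withr_seed(seed, place_control_regions(inversions, layout))
  strata <- list()
  pair_r2 <- function(region, individuals) {
    idx <- which(snp_info$chrom == region$chrom &
                   snp_info$pos >= region$start & snp_info$pos < region$end)
    if (length(idx) < 2 || length(individuals) < 2) return(NULL)
    g <- snp_geno[idx, individuals, drop = FALSE]
    keep <- apply(g, 1, sd) > 0
    if (sum(keep) < 2) return(NULL)
    g <- g[keep, , drop = FALSE]
    pos <- snp_info$pos[idx][keep]
    r2 <- cor(t(g))^2
    ut <- upper.tri(r2)
    d <- abs(outer(pos, pos, "-"))[ut]
    tibble::tibble(dist = d, r2 = r2[ut])
  }
  for (i in seq_len(nrow(inversions))) {
    inv <- inversions[i, ]
    dos <- inv_geno[i, ]
    p_alt <- mean(dos, na.rm = TRUE) / 2
    major_dos <- if (p_alt <= 0.5) 0L else 2L
    for (st in c("inversion-major-homozygotes", "inversion-minor-homozygotes")) {
      want <- if (st == "inversion-major-homozygotes") major_dos else 2L - major_dos
      inds <- which(!is.na(dos) & dos == want)
      if (length(inds) < 2) {
        warning("fewer than 2 ", st, " for inversion ", i, "; stratum omitted")
        next
      }
      pr <- pair_r2(inv, inds)
      if (!is.null(pr)) {
        pr$stratum <- st
        strata[[length(strata) + 1]] <- pr
      }
    }
  }
  for (i in seq_len(nrow(controls))) {
    pr <- pair_r2(controls[i, ], seq_len(ncol(snp_geno)))
    if (!is.null(pr)) {
      pr$stratum <- "colinear-control"
      strata[[length(strata) + 1]] <- pr
    }
  }
  all_pairs <- dplyr::bind_rows(strata)
  if (nrow(all_pairs) == 0) stop("no SNP pairs available for LD profiling")
  all_pairs <- all_pairs[all_pairs$dist <= max_dist, ]
  all_pairs$bin_start <- (all_pairs$dist %/% bin_width) * bin_width
  out <- all_pairs |>
    dplyr::group_by(.data$stratum, .data$bin_start) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(bin_mid = .data$bin_start + bin_width / 2)
  attr(out, "control_regions") <- controls
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

place_control_regions <- function(inversions, layout, max_attempts = 10000) {
  sizes <- inversions$end - inversions$start
  placed <- inversions[0, c("chrom", "start", "end")]
  for (len in sizes) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      ci <- sample.int(nrow(layout), 1,
                       prob = pmax(layout$length - len, 0))
      if (layout$length[ci] <= len) next
      st <- sample.int(layout$length[ci] - len, 1) - 1L
      cand <- tibble::tibble(chrom = layout$chrom[ci], start = st,
                             end = st + len)
      clash <- nrow(overlap_pairs(cand, inversions)) +
        nrow(overlap_pairs(cand, placed))
      if (clash == 0) {
        placed <- dplyr::bind_rows(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place a non-overlapping control region in ",
                  max_attempts, " attempts")
  }
  placed
}

#' Principal component analysis of SV genotypes
#'
#' Loci on excluded chromosomes or below the MAF threshold are removed,
#' missing dosages are mean-imputed per locus, and loci are centered and
#' scaled to unit variance before eigendecomposition of the individuals x
#' individuals covariance (so the eigenvalue sum equals the number of loci
#' retained).
#'
#' @param cohort An [sv_cohort()] object.
#' @param exclude_chroms Chromosomes to drop (e.g. sex chromosomes).
#' @param min_maf MAF threshold applied before decomposition.
#' @return List of class `sv_pca`: `eigenvalues` (non-increasing),
#'   `scores` (individuals x PCs), `n_loci`.
#' @export
sv_pca <- function(cohort, exclude_chroms = character(), min_maf = 0.05) {
  stopifnot(inherits(cohort, "sv_cohort"))
  keep <- !(cohort$loci$chrom %in% exclude_chroms) &
    !is.na(cohort$maf) & cohort$maf >= min_maf
  g <- cohort$geno[keep, , drop = FALSE]
  if (nrow(g) == 0) stop("no loci left for PCA")
  g <- t(apply(g, 1, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }))
  sds <- apply(g, 1, sd)
  g <- g[sds > 0, , drop = FALSE]
  M <- scale(t(g))  # individuals x loci, unit variance columns
  C <- M %*% t(M) / (nrow(M) - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  scores <- eig$vectors %*% diag(sqrt(vals * (nrow(M) - 1)), nrow = length(vals))
  rownames(scores) <- rownames(M)
  structure(list(eigenvalues = vals, scores = scores, n_loci = ncol(M)),
            class = "sv_pca")
}

#' @export
tidy.sv_pca <- function(x, ...) {
  tibble::tibble(
    individual = rownames(x$scores) %||% paste0("ind_", seq_len(nrow(x$scores))),
    PC1 = x$scores[, 1],
    PC2 = if (ncol(x$scores) > 1) x$scores[, 2] else NA_real_
  )
}
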