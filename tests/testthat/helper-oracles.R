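# Independent oracles and small fixture builders. Oracles are deliberately
# written from the printed formulas, without reusing package internals.

# Hudson's FST components, transcribed directly from the estimator
oracle_hudson <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - (p1 * (1 - p1)) / (n1 - 1) - (p2 * (1 - p2)) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den, fst = num / den)
}

# Tajima's D from the textbook constants, computed step by step
oracle_tajima <- function(geno) {
  n_ind <- ncol(geno)
  n <- 2 * n_ind
  freqs <- apply(geno, 1, function(g) sum(g) / n)
  freqs <- freqs[freqs > 0 & freqs < 1]
  S <- length(freqs)
  pi_hat <- 0
  for (p in freqs) pi_hat <- pi_hat + (n / (n - 1)) * 2 * p * (1 - p)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# quadratic all-pairs interval overlap scan (half-open coordinates)
oracle_overlap <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), 0, 2))
  do.call(rbind, hits)
}

# Spearman rho via explicit average ranks and the Pearson formula on ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# loxodrome bearing/distance, second implementation of the closed form
# (meridional parts), kept separate from the package's
oracle_rhumb <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  rad <- pi / 180
  psi1 <- log(tan(pi / 4 + lat1 * rad / 2))
  psi2 <- log(tan(pi / 4 + lat2 * rad / 2))
  dlon <- ((lon2 - lon1 + 540) %% 360 - 180) * rad
  theta <- atan2(dlon, psi2 - psi1)
  dphi <- (lat2 - lat1) * rad
  q <- if (abs(psi2 - psi1) < 1e-12) cos(lat1 * rad) else dphi / (psi2 - psi1)
  list(bearing = (theta / rad) %% 360,
       distance = R * sqrt(dphi^2 + q^2 * dlon^2))
}

# small hand-made SV record tibble
make_sv <- function(id, start, end, svtype = "DEL", chrom = "chr1",
                    genotype = 1L, caller = NA_character_,
                    alt_seq = NA_character_, length = NULL) {
  if (is.null(length)) {
    svl <- rep_len(svtype, base::length(start))
    length <- ifelse(svl == "INS", 100L, as.integer(end - start))
  }
  sv_records(id, chrom, start, end, svtype, length, alt_seq = alt_seq,
             caller = caller, genotype = genotype)
}

# cohort with explicit dosage matrix over loci spaced well apart
make_cohort <- function(dosages, chrom = "chr1") {
  m <- nrow(dosages)
  loci <- sv_records(sprintf("L%03d", seq_len(m)), chrom,
                     seq_len(m) * 10000L, seq_len(m) * 10000L + 100L,
                     "DEL", 100L)
  sv_cohort(loci, dosages)
}

# neutral-spectrum cohort: unfolded minor-allele counts drawn with
# probability proportional to 1/i, alleles placed on random copies
make_neutral_cohort <- function(n_loci, n_ind, seed) {
  set.seed(seed)
  n <- 2L * n_ind
  counts <- sample(seq_len(n - 1), n_loci, replace = TRUE,
                   prob = 1 / seq_len(n - 1))
  geno <- vapply(counts, function(k) {
    copies <- integer(n)
    copies[sample.int(n, k)] <- 1L
    as.integer(colSums(matrix(copies, nrow = 2)))
  }, integer(n_ind))
  make_cohort(t(geno))
}

# selected-locus PBS percentile study: SE-specific shift of 0.6 on a
# Balding-Nichols background (F = 0.02, 20 diploids per group, 2,000 loci)
pbs_selected_locus_ranks <- local({
  cache <- list()
  function(n_seeds) {
    key <- as.character(n_seeds)
    if (!is.null(cache[[key]])) return(cache[[key]])
    truth <- sv_records(sprintf("L%04d", 1:2000), "chr1",
                        (1:2000) * 10000L, (1:2000) * 10000L + 100L,
                        "DEL", 100L)
    out <- t(vapply(seq_len(n_seeds), function(s) {
      fr <- simulate_group_frequencies(
        2000, c("NW", "SW", "SE"), F = 0.02,
        selected = tibble::tibble(locus = 1000L, group = "SE", shift = 0.6),
        seed = 1000 + s)
      gt <- simulate_genotypes(truth, fr$freq, c(NW = 20, SW = 20, SE = 20),
                               seed = 2000 + s)
      grp <- setNames(sub("_.*", "", colnames(gt$cohort$geno)),
                      colnames(gt$cohort$geno))
      res <- pbs(gt$cohort, grp)
      i <- match("L1000", res$id)
      c(se_pct = mean(res$pbs_SE <= res$pbs_SE[i]),
        nw_pct = mean(res$pbs_NW <= res$pbs_NW[i]),
        sw_pct = mean(res$pbs_SW <= res$pbs_SW[i]))
    }, numeric(3)))
    cache[[key]] <<- tibble::as_tibble(out)
    cache[[key]]
  }
})
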