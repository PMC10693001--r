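# Synthetic cohorts with known truth: every generator is deterministic given
# (seed, arguments) and the truth objects fully determine the expected
# downstream answers (consensus recall, FST, PBS outliers, PVE, PIP ranking,
# migration timing).

#' Simulate a genome layout
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @param sequence Generate random A/C/G/T sequence (for GC analyses)?
#' @param gc Target GC fraction of the generated sequence.
#' @param seed Seed (`NULL`: use the current RNG state).
#' @return A [genome_layout()] tibble.
#' @export
simulate_layout <- function(lengths, sequence = FALSE, gc = 0.42,
                            seed = NULL) {
  gen <- function() {
    seqs <- NULL
    if (sequence) {
      prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      seqs <- vapply(lengths, function(L) {
        paste(sample(names(prob), L, replace = TRUE, prob = prob),
              collapse = "")
      }, character(1))
    }
    genome_layout(names(lengths) %||% paste0("chr", seq_along(lengths)),
                  lengths, sequence = seqs)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Simulate a truth set of structural variants
#'
#' Positions are uniform within chromosomes (loci allotted proportionally to
#' chromosome length) with a minimum inter-locus gap of `min_gap` so that
#' distinct truth loci can never be confused by breakpoint clustering.
#' Lengths are log-normal with a configurable median per type; insertions
#' get a 1-bp breakpoint interval.
#'
#' @param layout Genome layout.
#' @param n_loci Number of truth loci.
#' @param type_mix Named proportions over DEL/INS/DUP/INV/TRA (sum 1).
#' @param size_median Named per-type median length in bp.
#' @param size_sdlog Log-normal sdlog of lengths.
#' @param min_gap Minimum gap in bp between consecutive truth intervals.
#' @param seed Seed.
#' @return Tibble of SV records (ids `truth_00001`, ...).
#' @export
simulate_svs <- function(layout, n_loci,
                         type_mix = c(DEL = 0.6, INS = 0.4),
                         size_median = c(DEL = 250, INS = 250, DUP = 272,
                                         INV = 2500, TRA = 10000),
                         size_sdlog = 1.1, min_gap = 2000, seed = 1) {
  stopifnot(abs(sum(type_mix) - 1) < 1e-8)
  withr_seed(seed, {
    share <- layout$length / sum(layout$length)
    n_per <- drop(stats::rmultinom(1, n_loci, share))
    out <- purrr::map_dfr(seq_len(nrow(layout)), function(ci) {
      m <- n_per[ci]
      if (m == 0) return(NULL)
      types <- sample(names(type_mix), m, replace = TRUE, prob = type_mix)
      len <- pmin(pmax(round(rlnorm(m, log(size_median[types]), size_sdlog)),
                       50L), 65000L)
      # sorted uniform starts, then shift each locus past the cumulative
      # span + gap of its predecessors so consecutive intervals keep min_gap
      offset <- (seq_len(m) - 1) * min_gap + c(0, cumsum(len)[-m])
      avail <- layout$length[ci] - (sum(len) + m * min_gap)
      if (avail <= 0) stop("layout too small for ", m, " loci on ",
                           layout$chrom[ci], " at the required spacing")
      pos <- sort(runif(m, 0, avail)) + offset
      start <- as.integer(round(pos))
      end <- as.integer(ifelse(types == "INS", start + 1L, start + len))
      tibble::tibble(chrom = layout$chrom[ci], start = start, end = end,
                     svtype = types, length = as.integer(len))
    })
    out <- out[order(match(out$chrom, layout$chrom), out$start), ]
    out$id <- sprintf("truth_%05d", seq_len(nrow(out)))
    sv_records(out$id, out$chrom, out$start, out$end, out$svtype, out$length)
  })
}

#' Simulate per-group allele frequencies under Balding-Nichols divergence
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each group's frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), giving expected FST close to `F`. Selected
#' loci are then shifted toward fixation in their group by the stated
#' amount, clamped to `[0, 1]`.
#'
#' @param n_loci Number of loci.
#' @param groups Character vector of group names.
#' @param F Balding-Nichols divergence parameter, in (0, 1).
#' @param selected Optional tibble with `locus` (index), `group`, `shift`:
#'   the group's frequency moves by `shift` away from the ancestral value,
#'   towards whichever boundary is further.
#' @param seed Seed.
#' @return List with `ancestral` (length `n_loci`) and `freq` (loci x
#'   groups matrix).
#' @export
simulate_group_frequencies <- function(n_loci, groups, F = 0.02,
                                       selected = NULL, seed = 1) {
  stopifnot(F > 0, F < 1)
  withr_seed(seed, {
    p <- runif(n_loci, 0.05, 0.95)
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    freq <- vapply(groups, function(g) rbeta(n_loci, a, b),
                   numeric(n_loci))
    dimnames(freq) <- list(NULL, groups)
    if (!is.null(selected) && nrow(selected)) {
      for (i in seq_len(nrow(selected))) {
        li <- selected$locus[i]
        g <- selected$group[i]
        dirn <- if (p[li] < 0.5) 1 else -1
        freq[li, g] <- min(1, max(0, freq[li, g] + dirn * selected$shift[i]))
      }
    }
    list(ancestral = p, freq = freq)
  })
}

#' Simulate Hardy-Weinberg genotypes from group frequencies
#'
#' Dosage ~ Binomial(2, p_group) per individual.
#'
#' @param truth_svs Tibble of truth SV records (one per frequency row).
#' @param freq Loci x groups frequency matrix.
#' @param group_sizes Named integer vector of diploid counts per group.
#' @param seed Seed.
#' @return List with `cohort` (an [sv_cohort()]) and `groups` (named vector
#'   individual -> group).
#' @export
simulate_genotypes <- function(truth_svs, freq, group_sizes, seed = 1) {
  stopifnot(nrow(truth_svs) == nrow(freq), all(group_sizes >= 2))
  withr_seed(seed, {
    n_loci <- nrow(freq)
    cols <- list()
    grp <- character(0)
    for (g in names(group_sizes)) {
      for (i in seq_len(group_sizes[[g]])) {
        cols[[length(cols) + 1]] <- rbinom(n_loci, 2, freq[, g])
        grp <- c(grp, g)
      }
    }
    geno <- do.call(cbind, cols)
    ids <- sprintf("%s_%02d", grp, stats::ave(seq_along(grp), grp,
                                              FUN = seq_along))
    colnames(geno) <- ids
    names(grp) <- ids
    list(cohort = sv_cohort(truth_svs, geno), groups = grp)
  })
}

#' Emulate noisy caller output for one individual
#'
#' Every truth variant the individual carries (dosage >= 1) is emitted by
#' each caller independently, subject to per-caller dropout; retained calls
#' get a shared start/end breakpoint shift (rounded Normal(0, jitter_sd), so
#' the length stays exact) and a 1 <-> 2 genotype flip with probability
#' `genotype_error`.
#'
#' @param truth_svs Tibble of truth SV records.
#' @param dosages Integer vector of the individual's true dosages.
#' @param jitter_sd Breakpoint jitter sd in bp (keep below the merge radius).
#' @param dropout Per-caller per-call dropout probability.
#' @param genotype_error Probability of flipping a genotype 1 <-> 2.
#' @param n_callers Number of emulated callers.
#' @param seed Seed.
#' @return Named list (`callerA`, ...) of SV record tibbles.
#' @export
simulate_caller_callsets <- function(truth_svs, dosages, jitter_sd = 150,
                                     dropout = 0.2, genotype_error = 0.02,
                                     n_callers = 3, seed = 1) {
  stopifnot(length(dosages) == nrow(truth_svs))
  withr_seed(seed, {
    carried <- which(!is.na(dosages) & dosages >= 1)
    callers <- paste0("caller", LETTERS[seq_len(n_callers)])
    out <- lapply(callers, function(cl) {
      keep <- carried[runif(length(carried)) >= dropout]
      if (!length(keep)) {
        df <- truth_svs[0, ]
        df$caller <- character(0)
        return(df)
      }
      df <- truth_svs[keep, ]
      shift <- as.integer(round(rnorm(length(keep), 0, jitter_sd)))
      shift <- pmax(shift, -df$start)  # never before the chromosome start
      df$start <- df$start + shift
      df$end <- df$end + shift
      gt <- dosages[keep]
      flip <- runif(length(keep)) < genotype_error
      gt[flip] <- 3L - gt[flip]
      df$genotype <- as.integer(gt)
      df$caller <- cl
      df$id <- paste(cl, df$id, sep = ":")
      df
    })
    names(out) <- callers
    out
  })
}

# repeat-class mix of the curated songbird library the landscape analyses
# emulate (published shares sum to 100.03% from rounding; renormalized)
blackcap_repeat_mix <- local({
  x <- c(Simple = 0.478, LTR = 0.255, `LINE/CR1` = 0.175,
         LowComplexity = 0.082, DNA = 0.0079, SINE = 0.0024)
  x / sum(x)
})

#' Simulate repeat and gene annotations
#'
#' Places non-overlapping repeat intervals until roughly `repeat_density` of
#' the genome is covered, drawing class labels from `classes_mix`, and
#' `n_genes` non-overlapping gene intervals.
#'
#' @param layout Genome layout.
#' @param repeat_density Target genome fraction covered by repeats.
#' @param classes_mix Named class proportions (sum 1).
#' @param n_genes Number of genes.
#' @param repeat_median,gene_median Median interval lengths in bp.
#' @param seed Seed.
#' @return List with `repeats` and `genes` tibbles.
#' @export
simulate_annotations <- function(layout, repeat_density = 0.1,
                                 classes_mix = blackcap_repeat_mix,
                                 n_genes = 200, repeat_median = 400,
                                 gene_median = 10000, seed = 1) {
  stopifnot(abs(sum(classes_mix) - 1) < 1e-6, repeat_density < 0.5)
  withr_seed(seed, {
    place <- function(n_iv, med, sdlog) {
      share <- layout$length / sum(layout$length)
      n_per <- drop(stats::rmultinom(1, n_iv, share))
      purrr::map_dfr(seq_len(nrow(layout)), function(ci) {
        m <- n_per[ci]
        if (m == 0) return(NULL)
        len <- pmax(round(rlnorm(m, log(med), sdlog)), 20L)
        offset <- (seq_len(m) - 1) + c(0, cumsum(len)[-m])
        avail <- layout$length[ci] - (sum(len) + m)
        if (avail <= 0) stop("annotation density infeasible on ",
                             layout$chrom[ci])
        pos <- sort(runif(m, 0, avail)) + offset
        st <- as.integer(round(pos))
        tibble::tibble(chrom = layout$chrom[ci], start = st,
                       end = st + as.integer(len))
      })
    }
    n_rep <- round(repeat_density * sum(layout$length) / repeat_median)
    repeats <- place(n_rep, repeat_median, 0.7)
    repeats$repeat_class <- sample(names(classes_mix), nrow(repeats),
                                   replace = TRUE, prob = classes_mix)
    genes <- place(n_genes, gene_median, 0.4)
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    list(repeats = repeats,
         genes = genes[, c("gene_id", "chrom", "start", "end", "strand")])
  })
}

#' Simulate a genotype-driven quantitative trait
#'
#' `trait = baseline + focal effects + polygenic term + noise`, with each
#' realized component rescaled so its sample-variance share matches the
#' configuration exactly: `focal_share` for the focal loci jointly, `h2` for
#' the polygenic background (effects Normal(0, sd/p) over all loci) and the
#' remainder for the Gaussian noise. Shares must sum to at most 1.
#'
#' @param genotypes An [sv_cohort()] or individuals x loci dosage matrix.
#' @param focal_ids Locus ids (or column indices) of the focal variants.
#' @param focal_effects Per-copy effects of the focal variants (used for
#'   their relative weights and signs).
#' @param focal_share,h2 Variance shares of the focal and polygenic parts.
#' @param baseline Trait mean.
#' @param trait_sd Total trait standard deviation.
#' @param seed Seed.
#' @return List with `trait` (numeric vector) and `truth` (the realized
#'   components and shares).
#' @export
simulate_phenotypes <- function(genotypes, focal_ids = NULL,
                                focal_effects = NULL, focal_share = 0,
                                h2 = 0.5, baseline = 0, trait_sd = 1,
                                seed = 1) {
  if (focal_share + h2 > 1) stop("focal_share + h2 must not exceed 1")
  X <- as_dosage_matrix(genotypes)
  n <- nrow(X)
  withr_seed(seed, {
    scale_to <- function(x, share) {
      if (share == 0) return(rep(0, n))
      s <- sd(x)
      if (s == 0) stop("component with zero variance cannot carry a share")
      (x - mean(x)) / s * sqrt(share) * trait_sd
    }
    focal <- rep(0, n)
    if (focal_share > 0) {
      idx <- if (is.numeric(focal_ids)) focal_ids else match(focal_ids, colnames(X))
      if (anyNA(idx)) stop("focal locus not present in genotypes")
      eff <- focal_effects %||% rep(1, length(idx))
      focal <- scale_to(drop(X[, idx, drop = FALSE] %*% eff), focal_share)
    }
    poly <- rep(0, n)
    if (h2 > 0) {
      b <- rnorm(ncol(X), 0, 1 / sqrt(ncol(X)))
      Ximp <- standardize_loci(X, scale = FALSE)$X
      poly <- scale_to(drop(Ximp %*% b[seq_len(ncol(Ximp))]), h2)
    }
    noise <- scale_to(rnorm(n), 1 - focal_share - h2)
    trait <- baseline + focal + poly + noise
    list(trait = trait,
         truth = list(focal = focal, polygenic = poly, noise = noise,
                      focal_share = focal_share, h2 = h2,
                      baseline = baseline, trait_sd = trait_sd))
  })
}

# rhumb-line destination: travel dist_km at constant bearing from (lat, lon)
rhumb_destination <- function(lat, lon, bearing, dist_km) {
  delta <- dist_km / EARTH_RADIUS_KM
  theta <- deg2rad(bearing)
  phi1 <- deg2rad(lat)
  dphi <- delta * cos(theta)
  phi2 <- phi1 + dphi
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  q <- ifelse(abs(dpsi) < 1e-12, cos(phi1), dphi / dpsi)
  dlam <- delta * sin(theta) / q
  tibble::tibble(lat = phi2 * 180 / pi,
                 lon = normalize_lon(lon + dlam * 180 / pi))
}

# constant-speed great-circle interpolation via 3D slerp
gc_interpolate <- function(lat1, lon1, lat2, lon2, frac) {
  to_xyz <- function(lat, lon) {
    la <- deg2rad(lat); lo <- deg2rad(lon)
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(lat1, lon1)
  b <- to_xyz(lat2, lon2)
  omega <- acos(min(1, max(-1, sum(a * b))))
  t(vapply(frac, function(f) {
    if (omega < 1e-12) return(a)
    v <- (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
    v / sqrt(sum(v^2))
  }, numeric(3)))
}

xyz_to_latlon <- function(m) {
  tibble::tibble(lat = asin(pmin(1, pmax(-1, m[, 3]))) * 180 / pi,
                 lon = atan2(m[, 2], m[, 1]) * 180 / pi)
}

#' Simulate daily geolocator tracks at constant speed
#'
#' Positions are interpolated along the great circle from origin to
#' destination at the bird's speed (one position per day, staying at the
#' destination after arrival), with optional isotropic position noise.
#'
#' @param routes Tibble with `bird_id`, `origin_lat`, `origin_lon`,
#'   `dest_lat`, `dest_lon`, `departure` (Date), `speed_km_day`.
#' @param season Season label attached to the track rows.
#' @param position_noise_km Isotropic daily position noise (km sd).
#' @param extra_days Stationary days appended after arrival.
#' @param seed Seed.
#' @return Tibble with `bird_id`, `season`, `date`, `lat`, `lon`.
#' @export
simulate_tracks <- function(routes, season = "fall", position_noise_km = 0,
                            extra_days = 2, seed = 1) {
  stopifnot(all(routes$speed_km_day > 0))
  withr_seed(seed, {
    purrr::map_dfr(seq_len(nrow(routes)), function(i) {
      r <- routes[i, ]
      total <- great_circle_distance(r$origin_lat, r$origin_lon,
                                     r$dest_lat, r$dest_lon)
      n_days <- ceiling(total / r$speed_km_day) + extra_days
      day <- 0:n_days
      frac <- pmin(1, day * r$speed_km_day / total)
      pos <- xyz_to_latlon(gc_interpolate(r$origin_lat, r$origin_lon,
                                          r$dest_lat, r$dest_lon, frac))
      if (position_noise_km > 0) {
        pos$lat <- pos$lat + rnorm(nrow(pos), 0, position_noise_km / 111.32)
        km_per_deg <- 111.32 * pmax(cos(deg2rad(pos$lat)), 0.05)
        pos$lon <- pos$lon + rnorm(nrow(pos), 0, position_noise_km / km_per_deg)
      }
      tibble::tibble(bird_id = r$bird_id, season = season,
                     date = r$departure + day, lat = pos$lat,
                     lon = normalize_lon(pos$lon))
    })
  })
}

#' Simulate a correlated SNP haplotype panel for LD analyses
#'
#' Haplotypes are built by founder copying along the SNP positions: each
#' haplotype starts from one of `n_founders` founder haplotypes and switches
#' founders between adjacent SNPs with probability
#' `1 - exp(-distance / switch_scale)`. Inside a non-recombining inversion
#' set `switch_scale = Inf` equivalent behaviour with `n_founders` per
#' arrangement by calling with `switch_prob = 0` (no switching), which keeps
#' r-squared near its maximum at any distance; finite scales give
#' distance-decaying LD (the colinear-control behaviour).
#'
#' @param positions Sorted SNP positions in bp.
#' @param n_ind Number of diploid individuals.
#' @param n_founders Size of the founder haplotype pool.
#' @param switch_scale Copying switch scale in bp; `Inf` = no recombination.
#' @param maf_min Founder allele frequencies drawn from
#'   Uniform(maf_min, 1 - maf_min).
#' @param seed Seed.
#' @return Dosage matrix SNPs x individuals.
#' @export
simulate_ld_panel <- function(positions, n_ind, n_founders = 4,
                              switch_scale = Inf, maf_min = 0.2, seed = 1) {
  withr_seed(seed, {
    m <- length(positions)
    founders <- matrix(rbinom(n_founders * m, 1,
                              runif(m, maf_min, 1 - maf_min)),
                       nrow = m, ncol = n_founders)
    switch_p <- if (is.infinite(switch_scale)) rep(0, max(m - 1, 0)) else
      1 - exp(-diff(positions) / switch_scale)
    hap <- function() {
      f <- sample.int(n_founders, 1)
      idx <- integer(m)
      for (s in seq_len(m)) {
        if (s > 1 && runif(1) < switch_p[s - 1]) f <- sample.int(n_founders, 1)
        idx[s] <- f
      }
      founders[cbind(seq_len(m), idx)]
    }
    geno <- vapply(seq_len(n_ind), function(i) hap() + hap(), numeric(m))
    matrix(as.integer(geno), nrow = m)
  })
}
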