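# End-to-end driver on the blackcap-shaped synthetic profile.

#' Default blackcap-shaped simulation and analysis profile
#'
#' Parameter set emulating the study design the package targets: 79 birds in
#' four migratory groups (19 NW / 28 SW / 12 SE / 20 S), ~15,000 SV loci
#' dominated by small deletions/insertions with a handful of kb-scale
#' inversions, weak Balding-Nichols population structure, one 710-bp focal
#' deletion on a microchromosome that is frequency-shifted in SE birds and
#' drives migratory direction, and constant-speed daily migration tracks.
#' The genome is a scaled-down seven-chromosome layout (~85 Mb) so the full
#' pipeline stays desk-runnable.
#'
#' @param ... Named overrides of any default; unknown names are rejected.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    chrom_lengths = c(chr1 = 25e6, chr2 = 20e6, chr3 = 15e6, chr4 = 10e6,
                      chr5 = 5e6, chr27 = 2e6, chrZ = 8e6),
    n_loci = 15000,
    type_mix = c(DEL = 0.5925, INS = 0.4055, INV = 0.0015, DUP = 0.0003,
                 TRA = 0.0002),
    size_median = c(DEL = 245, INS = 265, DUP = 272, INV = 2485, TRA = 10456),
    size_sdlog = 1.1,
    min_gap = 2000,
    fst = 0.025,
    group_sizes = c(NW = 19, SW = 28, SE = 12, S = 20),
    focal_chrom = "chr27", focal_length = 710L,
    focal_group_freq = c(NW = 0.9, SW = 0.9, SE = 0.02, S = 0.5),
    focal_effect_deg = 14, direction_h2 = 0.5, direction_sd = 10,
    n_selected_per_group = 5, selected_shift = 0.5,
    group_direction = c(NW = 296, SW = 233, SE = 144, S = 192),
    group_distance = c(NW = 1300, SW = 1950, SE = 2050, S = 1300),
    breeding_site = c(lat = 47.5, lon = 14), breeding_spread = 1.0,
    speed_mean = 60, speed_sd = 8,
    fall_departure = as.Date("2020-09-05"), spring_departure = as.Date("2021-04-10"),
    departure_spread_days = 8, track_noise_km = 50,
    jitter_sd = 150, dropout = 0.2, genotype_error = 0.02, n_callers = 3,
    max_dist = 1000, min_size = 50, min_support_individuals = 4,
    min_maf = 0.05, window = 200000,
    repeat_density = 0.08, n_genes = 300,
    pbs_groups = c("NW", "SW", "SE"), exclude_chroms = "chrZ",
    gwas_control = bslmm_control(burnin = 2000, steps = 20000, thin = 10,
                                 n_chains = 2, geno_updates = 60)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Simulate the full blackcap-shaped cohort with known truth
#'
#' Generates the genome layout, truth SV set (with the focal deletion forced
#' onto the configured microchromosome), group allele frequencies with the
#' SE-specific shift at the focal locus, Hardy-Weinberg genotypes, repeat
#' and gene annotations, genotype-driven migratory directions, per-bird
#' routes and noisy daily tracks, and the per-individual noisy caller call
#' sets.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed; all generator seeds derive from it.
#' @return List with `layout`, `truth_svs`, `focal_id`, `freq`, `cohort`
#'   (truth genotypes), `groups` (genetic group per individual),
#'   `annotations`, `birds` (nested tracked-bird tibble), `true_direction`,
#'   `callsets` (per individual), and the component `truth` of the
#'   direction trait.
#' @export
simulate_blackcap_cohort <- function(config = pipeline_config(), seed = 1) {
  cfg <- config
  layout <- simulate_layout(cfg$chrom_lengths)
  truth <- simulate_svs(layout, cfg$n_loci, cfg$type_mix, cfg$size_median,
                        cfg$size_sdlog, cfg$min_gap, seed = seed)
  # force the focal deletion: the median DEL on the focal microchromosome
  cand <- which(truth$chrom == cfg$focal_chrom & truth$svtype == "DEL")
  if (!length(cand)) stop("no deletion available on ", cfg$focal_chrom)
  focal <- cand[ceiling(length(cand) / 2)]
  truth$length[focal] <- cfg$focal_length
  truth$end[focal] <- truth$start[focal] + cfg$focal_length
  focal_id <- truth$id[focal]

  grp_names <- names(cfg$group_sizes)
  fr <- simulate_group_frequencies(nrow(truth), grp_names, F = cfg$fst,
                                   seed = seed + 1)
  # the focal deletion runs along a frequency cline across the migratory
  # divide: common in the western groups, segregating in S birds, nearly
  # fixed for the reference allele in SE migrants
  fr$ancestral[focal] <- mean(cfg$focal_group_freq)
  fr$freq[focal, ] <- cfg$focal_group_freq[grp_names]
  # branch-specific selected loci (PBS outliers): frequency-shifted toward
  # fixation in their own group, neutral for the phenotypes
  sel_groups <- c("NW", "SW", "SE")
  n_sel <- cfg$n_selected_per_group
  sel_pool <- withr_seed(seed + 8, sample(setdiff(which(
    truth$chrom != cfg$focal_chrom), focal), n_sel * length(sel_groups)))
  selected <- split(sel_pool, rep(sel_groups, each = n_sel))
  for (g in sel_groups) {
    dirn <- ifelse(fr$ancestral[selected[[g]]] < 0.5, 1, -1)
    fr$freq[selected[[g]], g] <- pmin(1, pmax(0,
      fr$freq[selected[[g]], g] + dirn * cfg$selected_shift))
  }
  gt <- simulate_genotypes(truth, fr$freq, cfg$group_sizes, seed = seed + 2)
  ann <- simulate_annotations(layout, cfg$repeat_density,
                              n_genes = cfg$n_genes, seed = seed + 3)

  # genotype-driven migratory direction: deletion copies push the bearing
  # west by focal_effect_deg per copy on the absolute scale (reference
  # homozygotes orient furthest east; homozygote classes separate by twice
  # the per-copy effect, the scale seen in the field data), on top of group
  # baselines (geography) and a polygenic + noise term of within-group
  # scale direction_sd. The expected per-group focal shift is absorbed into
  # the baselines so realized group mean bearings match group_direction.
  ph <- simulate_phenotypes(gt$cohort, focal_share = 0,
                            h2 = cfg$direction_h2, baseline = 0,
                            trait_sd = cfg$direction_sd, seed = seed + 4)
  exp_dosage <- 2 * fr$freq[focal, gt$groups]
  direction <- cfg$group_direction[gt$groups] +
    cfg$focal_effect_deg * (gt$cohort$geno[focal_id, ] - exp_dosage) +
    ph$trait

  n <- length(gt$groups)
  birds <- withr_seed(seed + 5, {
    b_lat <- cfg$breeding_site["lat"] + runif(n, -1, 1) * cfg$breeding_spread
    b_lon <- cfg$breeding_site["lon"] + runif(n, -1, 1) * cfg$breeding_spread
    dist <- cfg$group_distance[gt$groups] * exp(rnorm(n, 0, 0.06))
    w <- rhumb_destination(b_lat, b_lon, direction, dist)
    speed <- pmax(20, rnorm(n, cfg$speed_mean, cfg$speed_sd))
    dep_f <- cfg$fall_departure +
      round(runif(n, -1, 1) * cfg$departure_spread_days)
    dep_s <- cfg$spring_departure +
      round(runif(n, -1, 1) * cfg$departure_spread_days)
    tibble::tibble(
      bird_id = names(gt$groups), sex = sample(c("M", "F"), n, TRUE),
      breeding_lat = b_lat, breeding_lon = b_lon,
      wintering_lat = w$lat, wintering_lon = w$lon,
      speed_km_day = speed, fall_departure = dep_f, spring_departure = dep_s)
  })
  fall <- simulate_tracks(
    tibble::tibble(bird_id = birds$bird_id, origin_lat = birds$breeding_lat,
                   origin_lon = birds$breeding_lon,
                   dest_lat = birds$wintering_lat,
                   dest_lon = birds$wintering_lon,
                   departure = birds$fall_departure,
                   speed_km_day = birds$speed_km_day),
    season = "fall", position_noise_km = cfg$track_noise_km, seed = seed + 6)
  spring <- simulate_tracks(
    tibble::tibble(bird_id = birds$bird_id, origin_lat = birds$wintering_lat,
                   origin_lon = birds$wintering_lon,
                   dest_lat = birds$breeding_lat,
                   dest_lon = birds$breeding_lon,
                   departure = birds$spring_departure,
                   speed_km_day = birds$speed_km_day),
    season = "spring", position_noise_km = cfg$track_noise_km,
    seed = seed + 7)
  tracks <- dplyr::bind_rows(fall, spring)
  birds$track <- lapply(birds$bird_id, function(b) {
    tracks[tracks$bird_id == b, c("season", "date", "lat", "lon")]
  })

  callsets <- lapply(seq_len(n), function(i) {
    simulate_caller_callsets(truth, gt$cohort$geno[, i], cfg$jitter_sd,
                             cfg$dropout, cfg$genotype_error, cfg$n_callers,
                             seed = seed + 100 + i)
  })
  names(callsets) <- names(gt$groups)

  list(layout = layout, truth_svs = truth, focal_id = focal_id,
       selected_ids = lapply(selected, function(ix) truth$id[ix]), freq = fr,
       cohort = gt$cohort, groups = gt$groups, annotations = ann,
       birds = birds, true_direction = direction, callsets = callsets,
       direction_truth = ph$truth, config = cfg, seed = seed)
}

#' Run the full analysis chain on a simulated blackcap-shaped cohort
#'
#' Executes, in dependency order: caller emulation, per-individual consensus
#' genotyping, cohort merging and MAF filtering, landscape summaries,
#' population-genetic statistics (AFS, Tajima's D, pairwise FST, PBS with
#' outlier genes, PCA), migratory-trait extraction from the tracks, and the
#' sparse Bayesian LMM GWAS on migratory direction. Writes per-stage JSON
#' summaries and a run manifest when `output_dir` is given.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed controlling simulation and inference.
#' @param output_dir Optional directory for JSON stage summaries.
#' @param sim Optionally, a pre-built [simulate_blackcap_cohort()] result.
#' @return A report list; see the `summary` element for headline numbers.
#' @export
run_blackcap_pipeline <- function(config = pipeline_config(), seed = 1,
                                  output_dir = NULL, sim = NULL) {
  cfg <- config
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))

  stage("simulate")
  if (is.null(sim)) sim <- simulate_blackcap_cohort(cfg, seed)

  stage("consensus")
  consensus <- lapply(sim$callsets, consensus_individual,
                      max_dist = cfg$max_dist, min_size = cfg$min_size)
  n_consensus <- vapply(consensus, nrow, integer(1))
  consensus <- lapply(consensus, filter_n_runs)

  stage("merge")
  cohort <- merge_cohort(consensus, max_dist = cfg$max_dist,
                         min_support_individuals = cfg$min_support_individuals,
                         min_size = cfg$min_size)
  n_merged <- nrow(cohort$geno)
  cohort_f <- maf_filter(cohort, cfg$min_maf)
  n_maf <- nrow(cohort_f$geno)

  stage("landscape")
  loci_f <- tidy(cohort_f)
  dens <- window_density(loci_f, sim$layout, cfg$window)
  sizes <- size_spectrum(loci_f)
  rpt <- repeat_overlap(loci_f, sim$annotations$repeats)

  stage("phenotypes")
  phen <- derive_phenotypes(sim$birds)

  stage("popgen")
  afs <- folded_afs(cohort)
  tajd <- tajimas_d(cohort_f)
  groups <- setNames(phen$group, phen$bird_id)
  counts_ok <- table(groups)[cfg$pbs_groups]
  pbs_tbl <- pbs(cohort_f, groups, focal = cfg$pbs_groups)
  genes_out <- pbs_outlier_genes(pbs_tbl, sim$annotations$genes)
  ac <- group_allele_counts(cohort_f, groups)
  fst_pairs <- utils::combn(cfg$pbs_groups, 2, simplify = FALSE)
  fst_gw <- vapply(fst_pairs, function(pr) {
    a <- ac[ac$group == pr[1], ]
    b <- ac[ac$group == pr[2], ]
    hf <- hudson_fst(a$p, a$n, b$p, b$n)
    fst_genomewide(hf$numerator, hf$denominator)
  }, numeric(1))
  names(fst_gw) <- vapply(fst_pairs, paste, character(1), collapse = "_")
  pca <- sv_pca(cohort_f, exclude_chroms = cfg$exclude_chroms)

  # locate the focal deletion among the merged loci (nearest DEL breakpoint
  # on the focal chromosome)
  truth_focal <- sim$truth_svs[sim$truth_svs$id == sim$focal_id, ]
  cand <- which(cohort_f$loci$chrom == truth_focal$chrom &
                  cohort_f$loci$svtype == "DEL" &
                  abs(cohort_f$loci$start - truth_focal$start) <= cfg$max_dist)
  focal_locus <- if (length(cand)) {
    cohort_f$loci$id[cand[which.min(abs(cohort_f$loci$start[cand] -
                                          truth_focal$start))]]
  } else NA_character_
  pbs_se <- pbs_tbl[[paste0("pbs_", "SE")]]
  focal_pbs_pct <- if (!is.na(focal_locus) && focal_locus %in% pbs_tbl$id) {
    mean(pbs_se <= pbs_se[match(focal_locus, pbs_tbl$id)])
  } else NA_real_

  stage("gwas")
  y <- prepare_trait(phen$direction, phen$sex)
  fit <- bslmm_fit(y, cohort_f, control = cfg$gwas_control, seed = seed + 500)
  top_pip_id <- fit$variants$id[which.max(fit$variants$pip)]

  report <- list(
    counts = list(truth_loci = nrow(sim$truth_svs),
                  consensus_per_individual = unname(n_consensus),
                  merged_loci = n_merged, maf_filtered_loci = n_maf),
    landscape = list(mean_sv_per_window = mean(dens$sv_count),
                     sizes = sizes,
                     repeat_fraction = rpt$fraction_overlapping),
    popgen = list(tajimas_d = tajd, fst_weighted = fst_gw,
                  pbs_mean = vapply(cfg$pbs_groups, function(g)
                    mean(pbs_tbl[[paste0("pbs_", g)]]), numeric(1)),
                  group_counts = as.list(counts_ok),
                  pc1_share = pca$eigenvalues[1] / sum(pca$eigenvalues),
                  outlier_genes = vapply(genes_out, nrow, integer(1))),
    gwas = list(pve = fit$pve_mean, pve_sd = fit$pve_sd,
                top_pip_id = top_pip_id, top_pip = max(fit$variants$pip)),
    focal = list(truth_id = sim$focal_id, merged_id = focal_locus,
                 is_top_pip = identical(top_pip_id, focal_locus),
                 pbs_se_percentile = focal_pbs_pct),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = seed
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("migrasv")),
                     r_version = R.version.string, seed = seed,
                     config_hash = rlang::hash(unclass(cfg)),
                     timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    cfg_out <- unclass(cfg)
    cfg_out$gwas_control <- unclass(cfg_out$gwas_control)
    cfg_out$fall_departure <- as.character(cfg_out$fall_departure)
    cfg_out$spring_departure <- as.character(cfg_out$spring_departure)
    jsonlite::write_json(cfg_out, file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    rep_out <- report
    rep_out$landscape$sizes <- as.data.frame(sizes)
    jsonlite::write_json(rep_out, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  }
  structure(c(report,
              list(cohort = cohort_f, pbs = pbs_tbl, fit = fit,
                   phenotypes = phen, pca = pca, sim = sim)),
            class = "blackcap_pipeline")
}

#' @exportS3Method base::print
print.blackcap_pipeline <- function(x, ...) {
  cat("<blackcap_pipeline>\n")
  cat(sprintf("  loci: %d truth -> %d merged -> %d after MAF filter\n",
              x$counts$truth_loci, x$counts$merged_loci,
              x$counts$maf_filtered_loci))
  cat(sprintf("  weighted FST: %s\n",
              paste(names(x$popgen$fst_weighted),
                    sprintf("%.3f", x$popgen$fst_weighted), collapse = ", ")))
  cat(sprintf("  direction GWAS: PVE %.2f +/- %.2f, top PIP %s (%.2f)\n",
              x$gwas$pve, x$gwas$pve_sd, x$gwas$top_pip_id, x$gwas$top_pip))
  cat(sprintf("  focal deletion: merged as %s, top-PIP %s, PBS_SE percentile %.3f\n",
              x$focal$merged_id, x$focal$is_top_pip,
              x$focal$pbs_se_percentile))
  invisible(x)
}
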