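test_that("generators are deterministic given a seed", {
  layout <- simulate_layout(c(chr1 = 2e6, chr2 = 1e6))
  expect_identical(simulate_svs(layout, 200, seed = 1),
                   simulate_svs(layout, 200, seed = 1))
  expect_identical(simulate_group_frequencies(100, c("A", "B"), seed = 2),
                   simulate_group_frequencies(100, c("A", "B"), seed = 2))
  tr <- simulate_svs(layout, 50, seed = 3)
  fr <- simulate_group_frequencies(50, "A", seed = 4)
  expect_identical(simulate_genotypes(tr, fr$freq, c(A = 5), seed = 5),
                   simulate_genotypes(tr, fr$freq, c(A = 5), seed = 5))
  expect_identical(simulate_annotations(layout, seed = 6),
                   simulate_annotations(layout, seed = 6))
})

test_that("truth SVs honor type mix, spacing and size law", {
  layout <- simulate_layout(c(chr1 = 5e6))
  all_del <- simulate_svs(layout, 300, type_mix = c(DEL = 1), seed = 7)
  expect_true(all(all_del$svtype == "DEL"))

  layout2 <- simulate_layout(c(chr1 = 4e7, chr2 = 2e7))
  svs <- simulate_svs(layout2, 1000, seed = 8)
  gaps <- unlist(tapply(seq_len(nrow(svs)), svs$chrom, function(ix) {
    s <- svs[ix, ]
    s$start[-1] - s$end[-nrow(s)]
  }))
  expect_true(all(gaps >= 2000))

  big <- simulate_svs(simulate_layout(c(chr1 = 3e8)), 5000,
                      type_mix = c(DEL = 1),
                      size_median = c(DEL = 250), seed = 9)
  expect_lt(abs(median(big$length) - 250) / 250, 0.2)

  expect_error(simulate_svs(simulate_layout(c(chr1 = 5e4)), 100, seed = 10),
               "too small")
})

test_that("Balding-Nichols frequencies approach the ancestral limit", {
  fr <- simulate_group_frequencies(2000, c("A", "B"), F = 1e-5, seed = 11)
  expect_lt(max(abs(fr$freq[, "A"] - fr$ancestral)), 0.05)
  sel <- tibble::tibble(locus = 7L, group = "B", shift = 0.6)
  fr2 <- simulate_group_frequencies(100, c("A", "B"), F = 0.02,
                                    selected = sel, seed = 12)
  expect_gt(abs(fr2$freq[7, "B"] - fr2$ancestral[7]), 0.3)
})

test_that("genotypes follow Hardy-Weinberg within groups", {
  tr <- simulate_svs(simulate_layout(c(chr1 = 1e7)), 3, seed = 13)
  freq <- cbind(A = c(0, 1, 0.5))
  gt <- simulate_genotypes(tr, freq, c(A = 1000), seed = 14)
  expect_true(all(gt$cohort$geno[1, ] == 0))
  expect_true(all(gt$cohort$geno[2, ] == 2))
  tab <- table(gt$cohort$geno[3, ])
  expect_lt(max(abs(as.numeric(tab) / 1000 - c(0.25, 0.5, 0.25))), 0.05)
})

test_that("caller emulation is exact without noise and respects dropout", {
  tr <- simulate_svs(simulate_layout(c(chr1 = 5e6)), 100, seed = 15)
  dos <- rep(c(0L, 1L, 2L), length.out = 100)
  clean <- simulate_caller_callsets(tr, dos, jitter_sd = 0, dropout = 0,
                                    genotype_error = 0, seed = 16)
  for (cs in clean) {
    expect_equal(nrow(cs), sum(dos >= 1))
    expect_equal(cs$start, tr$start[dos >= 1])
    expect_equal(cs$genotype, dos[dos >= 1])
  }
  gone <- simulate_caller_callsets(tr, dos, dropout = 1, seed = 17)
  expect_true(all(vapply(gone, nrow, integer(1)) == 0))
})

test_that("annotations hit the class mix and stay within bounds", {
  layout <- simulate_layout(c(chr1 = 2e7, chr2 = 1e7))
  ann <- simulate_annotations(layout, repeat_density = 0.05,
                              classes_mix = c(Simple = 0.7, LTR = 0.3),
                              n_genes = 100, seed = 18)
  expect_true(all(ann$repeats$repeat_class %in% c("Simple", "LTR")))
  share <- mean(ann$repeats$repeat_class == "Simple")
  expect_equal(share, 0.7, tolerance = 0.05)
  lens <- layout$length[match(ann$repeats$chrom, layout$chrom)]
  expect_true(all(ann$repeats$start >= 0 & ann$repeats$end <= lens))
  # non-overlap within chromosome
  for (ch in layout$chrom) {
    r <- ann$repeats[ann$repeats$chrom == ch, ]
    r <- r[order(r$start), ]
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
})

test_that("trait generator realizes the configured variance decomposition", {
  set.seed(19)
  X <- matrix(rbinom(1000 * 50, 2, runif(50, 0.2, 0.8)), 1000, 50,
              byrow = TRUE)
  colnames(X) <- paste0("v", 1:50)
  sim <- simulate_phenotypes(X, focal_ids = "v7", focal_effects = 1,
                             focal_share = 0.2, h2 = 0.3, seed = 20)
  # each component is rescaled to its exact share of trait_sd^2 = 1
  expect_equal(var(sim$truth$focal), 0.2, tolerance = 1e-10)
  expect_equal(var(sim$truth$polygenic), 0.3, tolerance = 1e-10)
  expect_equal(var(sim$truth$noise), 0.5, tolerance = 1e-10)
  # sampling cross-covariances keep the total within 10% of configured
  expect_equal(var(sim$trait), 1, tolerance = 0.25)
  expect_error(simulate_phenotypes(X, focal_ids = "v7", focal_share = 0.6,
                                   h2 = 0.5), "exceed")

  # zero total scale -> constant trait at the baseline
  flat <- simulate_phenotypes(X, focal_share = 0, h2 = 0, baseline = 3,
                              trait_sd = 0, seed = 21)
  expect_true(all(flat$trait == 3))

  # pure focal trait is exactly linear in dosage
  lin <- simulate_phenotypes(X, focal_ids = "v7", focal_effects = 1,
                             focal_share = 1, h2 = 0, seed = 22)
  means <- tapply(lin$trait, X[, 7], mean)
  expect_equal(unname(means["2"] - means["1"]),
               unname(means["1"] - means["0"]), tolerance = 1e-10)
})

test_that("constant-speed tracks close the loop with trait extraction", {
  routes <- tibble::tibble(bird_id = c("b1", "b2"),
                           origin_lat = 48, origin_lon = 13,
                           dest_lat = 36, dest_lon = -5,
                           departure = as.Date("2020-09-03"),
                           speed_km_day = c(60, 120))
  tr <- simulate_tracks(routes, "fall", position_noise_km = 0, seed = 23)
  total <- great_circle_distance(48, 13, 36, -5)
  for (i in 1:2) {
    t1 <- tr[tr$bird_id == routes$bird_id[i], ]
    fr <- route_fraction_series(t1[, c("date", "lat", "lon")], c(48, 13),
                                c(36, -5))
    td <- timing_and_duration(fr)
    expect_equal(td$timing,
                 routes$departure[1] +
                   ceiling(0.5 * total / routes$speed_km_day[i]))
    expect_equal(td$duration_days,
                 ceiling(0.7 * total / routes$speed_km_day[i]) -
                   ceiling(0.3 * total / routes$speed_km_day[i]))
  }
  # doubling the speed halves the span of travel days
  n1 <- sum(tr$bird_id == "b1")
  n2 <- sum(tr$bird_id == "b2")
  expect_lte(abs((n1 - 3) - 2 * (n2 - 3)), 2)  # up to rounding of day counts
})

test_that("the LD panel generator spans the no-recombination limit", {
  pos <- sort(sample(1:50000, 40))
  g0 <- simulate_ld_panel(pos, 50, n_founders = 2, switch_scale = Inf,
                          seed = 24)
  keep <- apply(g0, 1, sd) > 0
  r2 <- cor(t(g0[keep, ]))^2
  expect_gt(min(r2), 0.99)  # two founders, no switching: all SNPs in perfect LD
  g1 <- simulate_ld_panel(pos, 50, n_founders = 8, switch_scale = 200,
                          seed = 25)
  expect_identical(g1, simulate_ld_panel(pos, 50, n_founders = 8,
                                         switch_scale = 200, seed = 25))
})
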