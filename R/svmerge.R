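#' Consensus SV genotyping across callers within one individual
#'
#' Clusters the calls of several SV callers on the same individual by
#' breakpoint proximity (SURVIVOR-style: same chromosome, start and end both
#' within `max_dist` of the cluster seed) and keeps a cluster only when at
#' least two distinct callers support it with identical genotypes. Calls
#' shorter than `min_size` are dropped before clustering; a cluster never
#' contains two calls from the same caller (nearest breakpoints win, ties go
#' to the smaller start). The representative record of a consensus call is
#' the concordant supporter with the median start (lower median on ties).
#'
#' @param callsets A single tibble of SV records with a `caller` column, or a
#'   list of per-caller tibbles to be combined.
#' @param max_dist Maximum breakpoint distance in bp for clustering.
#' @param min_size Minimum SV length in bp retained before clustering.
#' @param require_type_match Require identical `svtype` within a cluster.
#' @return A tibble of consensus calls: the representative record columns
#'   plus `n_callers` and `supporting_callers` (comma-joined labels).
#' @export
consensus_individual <- function(callsets, max_dist = 1000, min_size = 50,
                                 require_type_match = FALSE) {
  if (is.data.frame(callsets)) calls <- tibble::as_tibble(callsets)
  else calls <- dplyr::bind_rows(callsets)
  calls <- validate_sv_records(calls)
  if (anyNA(calls$caller)) stop("every call must carry a caller label")
  if (dplyr::n_distinct(calls$caller) < 2) {
    stop("consensus requires call sets from at least two callers")
  }
  if (anyDuplicated(paste(calls$caller, calls$id))) {
    stop("duplicate record id within a caller's call set")
  }
  calls <- calls[calls$length >= min_size, ]
  if (nrow(calls) == 0) return(consensus_empty())
  calls$.cluster <- cluster_calls(calls, source = calls$caller,
                                  max_dist = max_dist,
                                  match_type = require_type_match)
  keep <- consensus_resolve(calls)
  keep$.cluster <- NULL
  keep[order(match(keep$chrom, unique(calls$chrom)), keep$start), ]
}

consensus_empty <- function() {
  out <- sv_records(character(), character(), integer(), integer(),
                    character(), integer())
  out$n_callers <- integer(0)
  out$supporting_callers <- character(0)
  out
}

# per cluster, keep the largest genotype-concordant subset of >= 2 callers
# (ties -> smaller dosage); representative = median-start supporter (lower
# median). Vectorized: clusters number in the hundreds of thousands.
consensus_resolve <- function(calls) {
  sup <- calls |>
    dplyr::filter(!is.na(.data$genotype)) |>
    dplyr::count(.data$.cluster, .data$genotype, name = ".n_sup") |>
    dplyr::filter(.data$.n_sup >= 2) |>
    dplyr::arrange(.data$.cluster, -.data$.n_sup, .data$genotype) |>
    dplyr::distinct(.data$.cluster, .keep_all = TRUE)
  members <- dplyr::inner_join(calls, sup,
                               by = c(".cluster", "genotype")) |>
    dplyr::arrange(.data$.cluster, .data$start)
  if (nrow(members) == 0) {
    out <- consensus_empty()
    out$.cluster <- integer(0)
    return(out)
  }
  reps <- members |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      .rep = dplyr::cur_group_rows()[ceiling(dplyr::n() / 2)],
      n_callers = dplyr::n(),
      supporting_callers = paste(sort(.data$caller), collapse = ","),
      .groups = "drop"
    )
  out <- members[reps$.rep, ]
  out$n_callers <- reps$n_callers
  out$supporting_callers <- reps$supporting_callers
  out$.n_sup <- NULL
  out
}

# shared wrapper around the compiled greedy clustering
cluster_calls <- function(calls, source, max_dist, match_type) {
  src <- as.integer(factor(source))
  typ <- as.integer(factor(calls$svtype, levels = sv_types))
  cl <- integer(nrow(calls))
  offset <- 0L
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    ord <- idx[order(calls$start[idx], calls$end[idx], src[idx])]
    ids <- cluster_breakpoints_cpp(calls$start[ord], calls$end[ord],
                                   src[ord], typ[ord],
                                   as.integer(max_dist), match_type)
    cl[ord] <- ids + offset
    offset <- offset + max(ids, 0L)
  }
  cl
}

#' Remove calls whose alternate sequence contains long N runs
#'
#' Drops calls whose `alt_seq` contains a run of more than `max_run`
#' consecutive N characters (scaffolding-gap artifacts). Calls without an
#' alternate sequence are retained.
#'
#' @param calls Tibble of SV records or consensus calls.
#' @param max_run Longest tolerated N run (default 10: calls with > 10 Ns in
#'   a row are removed).
#' @return The filtered tibble.
#' @export
filter_n_runs <- function(calls, max_run = 10) {
  if (nrow(calls) == 0) return(calls)
  pat <- sprintf("N{%d}", max_run + 1L)
  hit <- !is.na(calls$alt_seq) & grepl(pat, calls$alt_seq)
  calls[!hit, ]
}

#' A cohort of merged SV loci with a dosage matrix
#'
#' Container pairing a tibble of merged locus records with a loci-by-
#' individuals dosage matrix (entries 0, 1, 2 or NA) and per-locus minor
#' allele frequencies. Loci are sorted by (chrom, start).
#'
#' @param loci Tibble of SV records describing the merged loci (the
#'   per-record `genotype` field is unused here).
#' @param geno Integer matrix, loci in rows (named by locus id), individuals
#'   in columns.
#' @return An object of class `sv_cohort`.
#' @export
sv_cohort <- function(loci, geno) {
  loci <- validate_sv_records(loci)
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(loci)) stop("geno must have one row per locus")
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("ind_", seq_len(ncol(geno)))
  }
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$start)
  loci <- loci[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(geno) <- loci$id
  structure(list(loci = loci, geno = geno, maf = cohort_maf(geno)),
            class = "sv_cohort")
}

cohort_maf <- function(geno) {
  p <- rowMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' @exportS3Method base::print
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort> %d loci x %d individuals\n", nrow(x$geno),
              ncol(x$geno)))
  if (nrow(x$loci)) {
    tab <- table(x$loci$svtype)
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat(sprintf("  MAF: median %.3f, range %.3f-%.3f\n",
                median(x$maf, na.rm = TRUE), min(x$maf, na.rm = TRUE),
                max(x$maf, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
tidy.sv_cohort <- function(x, ...) {
  out <- x$loci
  out$maf <- x$maf
  out$n_carriers <- rowSums(x$geno > 0, na.rm = TRUE)
  out
}

#' Merge per-individual consensus calls into a cohort matrix
#'
#' Clusters consensus calls across individuals (same chromosome and svtype,
#' start and end within `max_dist`) and keeps loci supported by at least
#' `min_support_individuals` individuals. The representative locus is the
#' member call with the median start (lower median on ties); individuals
#' without a call at a retained locus receive dosage 0 (homozygous
#' reference).
#'
#' @param consensus Named list (individual id -> tibble) of consensus calls
#'   from [consensus_individual()].
#' @param max_dist Maximum breakpoint distance in bp.
#' @param min_support_individuals Minimum number of carrying individuals.
#' @param min_size Minimum SV length in bp.
#' @return An [sv_cohort()] object.
#' @export
merge_cohort <- function(consensus, max_dist = 1000,
                         min_support_individuals = 4, min_size = 50) {
  if (!length(consensus)) stop("no individuals supplied")
  if (is.null(names(consensus))) {
    names(consensus) <- paste0("ind_", seq_along(consensus))
  }
  if (length(consensus) < min_support_individuals) {
    stop("fewer individuals than min_support_individuals")
  }
  calls <- dplyr::bind_rows(consensus, .id = ".individual")
  calls <- calls[calls$length >= min_size, ]
  if (nrow(calls) == 0) stop("no calls to merge")
  calls$.cluster <- cluster_calls(calls, source = calls$.individual,
                                  max_dist = max_dist, match_type = TRUE)
  inds <- names(consensus)
  calls <- calls[order(calls$.cluster, calls$start), ]
  reps <- calls |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      .rep = dplyr::cur_group_rows()[ceiling(dplyr::n() / 2)],
      .support = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$.support >= min_support_individuals)
  if (nrow(reps) == 0) {
    empty <- consensus_empty()
    return(sv_cohort(empty[, c("id", "chrom", "start", "end", "svtype",
                               "length", "alt_seq", "caller", "genotype")],
                     matrix(integer(0), 0, length(inds),
                            dimnames = list(NULL, inds))))
  }
  loci <- calls[reps$.rep, ]
  locus_row <- match(calls$.cluster, loci$.cluster)
  geno <- matrix(0L, nrow = nrow(loci), ncol = length(inds),
                 dimnames = list(NULL, inds))
  member <- !is.na(locus_row)
  geno[cbind(locus_row[member], match(calls$.individual[member], inds))] <-
    calls$genotype[member]
  loci$id <- sprintf("locus_%05d", seq_len(nrow(loci)))
  loci$caller <- NA_character_
  loci$genotype <- NA_integer_
  keep_cols <- c("id", "chrom", "start", "end", "svtype", "length",
                 "alt_seq", "caller", "genotype")
  sv_cohort(loci[, keep_cols], geno)
}

#' Filter cohort loci by minor allele frequency
#'
#' Removes loci with MAF below `min_maf` (computed over non-missing
#' dosages); the MAF retained is recomputed and stored. The boundary is
#' kept: a locus at exactly `min_maf` survives.
#'
#' @param cohort An [sv_cohort()] object.
#' @param min_maf Minimum minor allele frequency.
#' @return The filtered `sv_cohort`.
#' @export
maf_filter <- function(cohort, min_maf = 0.05) {
  stopifnot(inherits(cohort, "sv_cohort"))
  keep <- !is.na(cohort$maf) & cohort$maf >= min_maf
  if (!any(keep)) warning("all loci removed by the MAF filter")
  sv_cohort(cohort$loci[keep, , drop = FALSE],
            cohort$geno[keep, , drop = FALSE])
}
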