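#' Tile a genome into fixed windows and count SVs
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp (the
#' terminal window keeps the remainder) and counts the SVs whose start
#' coordinate falls inside each window. Intervals are half-open, so an SV
#' starting exactly at a window boundary belongs to the right-hand window.
#'
#' @param loci Tibble of SV records (e.g. `tidy(cohort)`).
#' @param layout Genome layout.
#' @param window Window width in bp (default 200 kb).
#' @return Tibble with `chrom`, `start`, `end`, `sv_count` per window.
#' @export
window_density <- function(loci, layout, window = 200000) {
  window <- as.integer(window)
  stopifnot(window > 0)
  wins <- genome_windows(layout, window)
  if (nrow(loci)) {
    check_bounds(loci$chrom, loci$start, pmin(loci$end, loci$start + 1L),
                 layout, "SV")
    key <- paste(loci$chrom, loci$start %/% window)
    cnt <- table(key)
    wkey <- paste(wins$chrom, wins$start %/% window)
    wins$sv_count <- as.integer(cnt[wkey])
    wins$sv_count[is.na(wins$sv_count)] <- 0L
  } else {
    wins$sv_count <- 0L
  }
  wins
}

genome_windows <- function(layout, window) {
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    starts <- seq.int(0L, layout$length[i] - 1L, by = window)
    tibble::tibble(chrom = layout$chrom[i], start = starts,
                   end = pmin(starts + window, layout$length[i]))
  })
}

#' Per-window GC fraction
#'
#' Computes (G + C) / (A + C + G + T) in each window of the layout's
#' sequence. N bases are excluded from the denominator; a window of only Ns
#' yields `NA`.
#'
#' @param layout Genome layout carrying a `sequence` column.
#' @param window Window width in bp.
#' @return Tibble with `chrom`, `start`, `end`, `gc_fraction`.
#' @export
gc_content <- function(layout, window = 200000) {
  if (is.null(layout$sequence)) stop("layout carries no sequence")
  wins <- genome_windows(layout, as.integer(window))
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(wins)), function(i) {
    substr(layout$sequence[match(wins$chrom[i], layout$chrom)],
           wins$start[i] + 1L, wins$end[i])
  }, character(1)))
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  wins$gc_fraction <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom,
                             NA_real_)
  wins
}

#' Spearman rank correlation with large-sample p value
#'
#' Average ranks are used for ties and the p value comes from the
#' large-sample t approximation. Pairs with a missing member are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs).
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("rank correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Overlap of SVs with a repeat annotation
#'
#' An SV overlaps a repeat element when they share at least one bp
#' (half-open intervals; insertions contribute their 1-bp breakpoint
#' interval). Per-class shares are computed over (SV, element) overlap
#' pairs, each overlapping element counted once per SV.
#'
#' @param loci Tibble of SV records.
#' @param repeats Repeat annotation tibble (`chrom`, `start`, `end`,
#'   `repeat_class`).
#' @return List with `fraction_overlapping` (share of SVs touching >= 1
#'   element), `class_shares` (tibble of per-class shares summing to 1) and
#'   `n_pairs`.
#' @export
repeat_overlap <- function(loci, repeats) {
  hits <- overlap_pairs(loci, repeats)
  frac <- length(unique(hits$query)) / max(nrow(loci), 1L)
  cls <- repeats$repeat_class[hits$subject]
  shares <- tibble::as_tibble(as.data.frame(table(cls),
                                            stringsAsFactors = FALSE))
  names(shares) <- c("repeat_class", "n")
  shares$share <- shares$n / sum(shares$n)
  list(fraction_overlapping = frac,
       class_shares = shares[order(-shares$share), ],
       n_pairs = nrow(hits))
}

# 1-bp-minimum interval overlap on half-open coordinates, via IRanges
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  out <- purrr::map_dfr(intersect(unique(query$chrom), unique(subject$chrom)),
    function(ch) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      # half-open [start, end) -> 1-based closed [start + 1, end]
      q <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
      s <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
      h <- IRanges::findOverlaps(q, s, minoverlap = 1L)
      tibble::tibble(query = qi[S4Vectors::queryHits(h)],
                     subject = si[S4Vectors::subjectHits(h)])
    })
  out
}

#' Per-type SV size summary
#'
#' @param loci Tibble of SV records.
#' @return Tibble with per-svtype `n`, `median` (lower of the middle pair
#'   for even counts), `min`, `max`. Types with no loci are omitted.
#' @export
size_spectrum <- function(loci) {
  loci |>
    dplyr::group_by(.data$svtype) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = lower_median(.data$length),
      min = min(.data$length),
      max = max(.data$length),
      .groups = "drop"
    )
}

lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}
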