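#' Describe a genome as a table of chromosomes
#'
#' A genome layout is a tibble with one row per chromosome. It carries the
#' chromosome lengths every interval operation validates against and,
#' optionally, the nucleotide sequence used for GC content.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @param sequence Optional character vector of chromosome sequences
#'   (A/C/G/T/N), each of the stated length.
#' @return A tibble with columns `chrom`, `length` and, when supplied,
#'   `sequence`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length, sequence = NULL) {
  chrom <- as.character(chrom)
  length <- as.integer(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(is.na(length)) || any(length <= 0L)) {
    stop("chromosome lengths must be positive")
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  if (!is.null(sequence)) {
    if (any(nchar(sequence) != length)) {
      stop("sequence lengths disagree with stated chromosome lengths")
    }
    out$sequence <- as.character(sequence)
  }
  out
}

sv_types <- c("DEL", "INS", "DUP", "INV", "TRA")

#' Assemble and validate a table of SV records
#'
#' One row per structural-variant call. Coordinates are 0-based half-open.
#' Insertions occupy a 1-bp breakpoint interval (`end = start + 1`) and carry
#' the inserted length in `length`; for all other types
#' `length = end - start`.
#'
#' @param id,chrom,start,end,svtype Call identity and interval. `svtype` is
#'   one of DEL, INS, DUP, INV, TRA.
#' @param length Variant length in bp (>= 1).
#' @param alt_seq Optional alternate sequence (NA when absent).
#' @param caller Label of the producing caller.
#' @param genotype Dosage of the alternate allele: 0, 1, 2 or NA (missing).
#' @return A validated tibble of SV records.
#' @export
sv_records <- function(id, chrom, start, end, svtype, length,
                       alt_seq = NA_character_, caller = NA_character_,
                       genotype = NA_integer_) {
  out <- tibble::tibble(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    svtype = as.character(svtype), length = as.integer(length),
    alt_seq = as.character(alt_seq), caller = as.character(caller),
    genotype = as.integer(genotype)
  )
  validate_sv_records(out)
}

#' @rdname sv_records
#' @param records A data frame with the columns of [sv_records()].
#' @export
validate_sv_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("id", "chrom", "start", "end", "svtype", "length")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing SV record columns: ",
                         paste(miss, collapse = ", "))
  if (!"alt_seq" %in% names(records)) records$alt_seq <- NA_character_
  if (!"caller" %in% names(records)) records$caller <- NA_character_
  if (!"genotype" %in% names(records)) records$genotype <- NA_integer_
  if (nrow(records) == 0) return(records)
  bad_type <- setdiff(unique(records$svtype), sv_types)
  if (length(bad_type)) stop("unknown svtype: ", paste(bad_type, collapse = ", "))
  if (any(records$end < records$start)) stop("end < start in SV records")
  if (any(records$length < 1L)) stop("SV length must be >= 1")
  ins <- records$svtype == "INS"
  if (any(records$end[ins] != records$start[ins] + 1L)) {
    stop("insertions must occupy a 1-bp breakpoint interval")
  }
  span <- records$svtype %in% c("DEL", "INV", "DUP")
  if (any(records$length[span] != records$end[span] - records$start[span])) {
    stop("length must equal end - start for DEL/INV/DUP records")
  }
  gt <- records$genotype
  if (any(!is.na(gt) & !(gt %in% 0:2))) stop("genotype dosage must be 0, 1, 2 or NA")
  records
}

gt_to_dosage <- function(gt, id) {
  gt1 <- sub(":.*", "", gt)
  gt1[is.na(gt1)] <- "./."  # absent genotype field -> missing
  alleles <- strsplit(gt1, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) != 2 || !all(a %in% c("0", "1", "."))) {
      stop("malformed genotype '", gt[i], "' for record ", id[i])
    }
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Read structural variants from a VCF file
#'
#' Parses a single-sample VCF 4.x with `SVTYPE` and `END`/`SVLEN` INFO tags
#' into the internal 0-based half-open representation (`start = POS - 1`).
#' A missing `END` is reconstructed from `SVLEN`; insertions are normalized
#' to a 1-bp breakpoint interval. Records with an SVTYPE outside
#' DEL/INS/DUP/INV/TRA are skipped with a warning giving the count.
#'
#' @param path Path to the VCF file.
#' @param caller_label Caller label to attach; an INFO `CALLER` tag, when
#'   present, takes precedence (so writer output round-trips).
#' @return A tibble of SV records (see [sv_records()]).
#' @export
read_sv_vcf <- function(path, caller_label = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(sv_records(character(), character(), integer(), integer(),
                      character(), integer()))
  }
  info1 <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else as.character(x)
  }
  svtype <- info1("SVTYPE")
  endv <- suppressWarnings(as.integer(info1("END")))
  svlen <- suppressWarnings(as.integer(info1("SVLEN")))
  seqv <- info1("SEQ")
  callv <- info1("CALLER")
  if (ncol(vcf@gt) < 2) stop("VCF has no genotype (GT) sample column")
  gt <- vcf@gt[, 2]
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("sv_", which(is.na(id) | id == "."))
  keep <- svtype %in% sv_types
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with unknown SVTYPE skipped")
  }
  pos <- as.integer(fix$POS)
  start <- pos - 1L
  len <- abs(svlen)
  is_ins <- svtype == "INS"
  end <- ifelse(is_ins, start + 1L, ifelse(!is.na(endv), endv, start + len))
  len <- ifelse(is_ins, len, end - start)
  if (any(keep & is.na(len))) stop("cannot determine SV length (need END or SVLEN)")
  caller <- ifelse(!is.na(callv), callv, caller_label)
  dosage <- gt_to_dosage(gt[keep], id[keep])
  sv_records(id[keep], fix$CHROM[keep], start[keep], end[keep], svtype[keep],
             len[keep], alt_seq = seqv[keep], caller = caller[keep],
             genotype = dosage)
}

#' Write structural variants to a VCF file
#'
#' Emits VCF 4.2 with `SVTYPE`, `END`, `SVLEN`, `CALLER` and optional `SEQ`
#' INFO tags and one GT sample column, converting internal 0-based half-open
#' coordinates back to 1-based POS. Records are sorted by the chromosome
#' order of `layout`, then start. `read_sv_vcf(write_sv_vcf(x))` returns `x`.
#'
#' @param records Tibble of SV records.
#' @param layout Genome layout ([genome_layout()]).
#' @param path Output path.
#' @param sample_name Sample column header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, layout, path, sample_name = "SAMPLE") {
  records <- validate_sv_records(records)
  bad_chrom <- setdiff(unique(records$chrom), layout$chrom)
  if (length(bad_chrom)) stop("records on chromosomes absent from layout: ",
                              paste(bad_chrom, collapse = ", "))
  if (nrow(records)) {
    lens <- layout$length[match(records$chrom, layout$chrom)]
    if (any(records$end > lens)) stop("record extends beyond chromosome length")
    ord <- order(match(records$chrom, layout$chrom), records$start, records$end)
    records <- records[ord, ]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom, layout$length),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Producing caller\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Alternate sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  lines <- character(0)
  if (nrow(records)) {
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", records$svtype, records$end,
                    records$length)
    has_caller <- !is.na(records$caller)
    info[has_caller] <- paste0(info[has_caller], ";CALLER=",
                               records$caller[has_caller])
    has_seq <- !is.na(records$alt_seq)
    info[has_seq] <- paste0(info[has_seq], ";SEQ=", records$alt_seq[has_seq])
    gt <- c("0/0", "0/1", "1/1")[records$genotype + 1L]
    gt[is.na(gt)] <- "./."
    lines <- paste(records$chrom, records$start + 1L, records$id, "N",
                   paste0("<", records$svtype, ">"), ".", "PASS", info, "GT",
                   gt, sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

check_bounds <- function(chrom, start, end, layout, what) {
  if (is.null(layout)) return(invisible())
  lens <- layout$length[match(chrom, layout$chrom)]
  if (any(is.na(lens))) stop(what, " on chromosome absent from layout")
  if (any(start < 0L) || any(end > lens)) {
    stop(what, " interval outside chromosome bounds")
  }
  invisible()
}

#' Read a repeat annotation from a BED4 file
#'
#' BED intervals are already 0-based half-open and are kept as-is; the name
#' column supplies the repeat class.
#'
#' @param path Path to the BED file.
#' @param layout Optional genome layout for bounds checking.
#' @return Tibble with `chrom`, `start`, `end`, `repeat_class`.
#' @export
read_bed_repeats <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  cls <- gr$name
  if (is.null(cls) || anyNA(cls)) stop("BED repeat track must carry a class label")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    repeat_class = as.character(cls)
  )
  check_bounds(out$chrom, out$start, out$end, layout, "repeat")
  out
}

#' Read gene intervals from a GFF3 file
#'
#' GFF3 coordinates (1-based, closed) are converted to the internal 0-based
#' half-open convention. Only features of type `gene` are kept.
#'
#' @inheritParams read_bed_repeats
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  gid <- gr$ID
  if (is.null(gid)) gid <- paste0("gene_", seq_along(gr))
  out <- tibble::tibble(
    gene_id = as.character(gid),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  check_bounds(out$chrom, out$start, out$end, layout, "gene")
  out
}

normalize_lon <- function(lon) {
  lon <- (lon + 180) %% 360 - 180
  ifelse(lon == -180, 180, lon)
}

#' Read tracked birds from phenotype and track tables
#'
#' `birds_path` is a CSV with columns `bird_id`, `sex` (M/F/unknown),
#' `breeding_lat`, `breeding_lon`, `wintering_lat`, `wintering_lon`.
#' `tracks_path` (optional) is a long CSV with columns `bird_id`, `season`
#' (fall/spring), `date` (ISO-8601), `lat`, `lon` of daily geolocator
#' positions. Longitudes are normalized to (-180, 180]; dates must increase
#' strictly within a bird and season.
#'
#' @param birds_path,tracks_path CSV paths; `tracks_path` may be `NULL`.
#' @return A nested tibble with one row per bird and a `track` list-column.
#' @export
read_tracked_birds <- function(birds_path, tracks_path = NULL) {
  birds <- readr::read_csv(birds_path, show_col_types = FALSE)
  needed <- c("bird_id", "sex", "breeding_lat", "breeding_lon",
              "wintering_lat", "wintering_lon")
  miss <- setdiff(needed, names(birds))
  if (length(miss)) stop("birds table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(birds$bird_id)) {
    stop("duplicate bird_id in phenotype table: ",
         paste(unique(birds$bird_id[duplicated(birds$bird_id)]), collapse = ", "))
  }
  lat_cols <- c("breeding_lat", "wintering_lat")
  if (any(abs(unlist(birds[lat_cols])) > 90)) stop("latitude outside [-90, 90]")
  birds$breeding_lon <- normalize_lon(birds$breeding_lon)
  birds$wintering_lon <- normalize_lon(birds$wintering_lon)
  birds <- tibble::as_tibble(birds)
  if (!is.null(tracks_path)) {
    tracks <- readr::read_csv(tracks_path, show_col_types = FALSE)
    tracks$lon <- normalize_lon(tracks$lon)
    if (any(abs(tracks$lat) > 90)) stop("track latitude outside [-90, 90]")
    tracks$date <- as.Date(tracks$date)
    split_tracks <- split(tracks, tracks$bird_id)
    for (b in names(split_tracks)) {
      tr <- split_tracks[[b]]
      for (s in unique(tr$season)) {
        d <- tr$date[tr$season == s]
        if (any(diff(d) <= 0)) stop("track dates not strictly increasing for ", b)
      }
    }
    birds$track <- lapply(birds$bird_id, function(b) {
      tr <- split_tracks[[as.character(b)]]
      if (is.null(tr)) {
        tibble::tibble(season = character(), date = as.Date(character()),
                       lat = numeric(), lon = numeric())
      } else {
        tibble::as_tibble(tr[order(tr$season, tr$date),
                             c("season", "date", "lat", "lon")])
      }
    })
  }
  birds
}
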