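#' Read a FASTA file into a tibble of genome records
#'
#' Sequences are uppercased and validated against the alphabet `{A,C,G,T,N}`.
#' Letters outside the alphabet are either rejected with an error naming the
#' offending character and position, or silently mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @param illegal How to treat letters outside `{A,C,G,T,N}`: `"error"`
#'   (default) or `"to_n"`.
#' @return A tibble with columns `id` (first word of each header) and
#'   `sequence`, one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, illegal = c("error", "to_n")) {
  illegal <- match.arg(illegal)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  # BStringSet accepts arbitrary letters so that alphabet policy stays ours
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- vapply(seq_along(seqs), function(i) {
    validate_dna(seqs[[i]], id = ids[[i]], illegal = illegal)
  }, character(1))
  if (any(!nzchar(seqs))) {
    stop("empty sequence in FASTA record", call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

# Enforce the {A,C,G,T,N} alphabet on one uppercase sequence string.
validate_dna <- function(seq, id = "?", illegal = "error") {
  bad <- gregexpr("[^ACGTN]", seq)[[1]]
  if (bad[1] != -1) {
    if (illegal == "error") {
      ch <- substr(seq, bad[1], bad[1])
      stop(sprintf(
        "illegal character '%s' at position %d of sequence '%s'",
        ch, bad[1], id
      ), call. = FALSE)
    }
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Read features of one type from a GFF3 annotation
#'
#' Coordinates are kept 1-based inclusive as in the file; conversion to the
#' package's internal 0-based half-open convention happens in
#' [partition_regions()].
#'
#' @param path Path to a GFF/GFF3 file.
#' @param feature_type Feature type to keep (third GFF column), e.g. `"CDS"`.
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based inclusive)
#'   and `strand`; zero rows when no feature matches (not an error).
#' @export
read_gff <- function(path, feature_type = "CDS") {
  if (!file.exists(path)) {
    stop("GFF file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) == feature_type
  gr <- gr[keep]
  tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Partition a genome into coding and non-coding regions
#'
#' Converts 1-based inclusive features to 0-based half-open coordinates,
#' merges overlapping coding intervals, and takes the complement as
#' non-coding. Together the regions tile the genome exactly: they are
#' disjoint, ordered, and their lengths sum to the genome length. The coding
#' definition is the strand-insensitive union of the supplied features; all
#' extracted sequence is reported on the forward strand.
#'
#' @param genome A one-row tibble (or list) with fields `id` and `sequence`,
#'   as returned by [read_fasta()].
#' @param features A tibble as returned by [read_gff()]; only rows whose
#'   `seq_id` equals `genome$id` are used. May have zero rows.
#' @param merge_overlaps Merge overlapping/adjacent features (default TRUE;
#'   FALSE raises an error if overlaps are present rather than producing an
#'   invalid partition).
#' @return A tibble of regions with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `kind` (`"coding"`/`"noncoding"`) and `sequence`.
#' @examples
#' g <- tibble::tibble(id = "chr1", sequence = "ACGTACGTAC")
#' f <- tibble::tibble(seq_id = "chr1", start = 2, end = 5, strand = "+")
#' partition_regions(g, f)
#' @export
partition_regions <- function(genome, features, merge_overlaps = TRUE) {
  id <- genome$id[[1]]
  seq <- genome$sequence[[1]]
  n <- nchar(seq)
  if (is.null(seq) || n == 0) stop("empty genome sequence", call. = FALSE)

  if (nrow(features) > 0) {
    features <- dplyr::filter(features, .data$seq_id == id)
  }
  if (nrow(features) > 0) {
    if (any(features$end < features$start)) {
      stop("feature with end < start", call. = FALSE)
    }
    if (any(features$start < 1) || any(features$end > n)) {
      stop("feature exceeds sequence bounds [1, ", n, "]", call. = FALSE)
    }
    ir <- IRanges::IRanges(start = features$start, end = features$end)
    red <- IRanges::reduce(ir)
    if (!merge_overlaps && length(red) != length(ir)) {
      stop("overlapping features present and merge_overlaps = FALSE",
           call. = FALSE)
    }
    coding <- tibble::tibble(
      start = IRanges::start(red) - 1L,   # 1-based inclusive -> 0-based half-open
      end = IRanges::end(red),
      kind = "coding"
    )
    gaps <- IRanges::gaps(red, start = 1L, end = n)
    noncoding <- tibble::tibble(
      start = IRanges::start(gaps) - 1L,
      end = IRanges::end(gaps),
      kind = "noncoding"
    )
    regions <- dplyr::bind_rows(coding, noncoding)
  } else {
    regions <- tibble::tibble(start = 0L, end = n, kind = "noncoding")
  }
  regions <- dplyr::arrange(regions, .data$start)
  regions$seq_id <- id
  regions$sequence <- substring(seq, regions$start + 1L, regions$end)
  dplyr::select(regions, "seq_id", "start", "end", "kind", "sequence")
}

#' Extract the first qualifying analysis windows from a partition
#'
#' Returns the first contiguous non-coding stretch of length `nc_len` and the
#' first contiguous coding stretch of length `c_len`, e.g. a 100 bp
#' non-coding plus 100 bp coding window for the tunneling experiment.
#'
#' @param partition Region tibble from [partition_regions()].
#' @param nc_len,c_len Window lengths in bp (0 yields an empty segment).
#' @return A list with elements `noncoding` and `coding`, each a character
#'   scalar of the requested length.
#' @export
extract_window <- function(partition, nc_len = 100, c_len = 100) {
  stopifnot(nc_len >= 0, c_len >= 0)
  take_first <- function(kind, len) {
    if (len == 0) return("")
    rows <- dplyr::filter(partition, .data$kind == !!kind,
                          .data$end - .data$start >= len)
    if (nrow(rows) == 0) {
      stop("no contiguous ", kind, " region of length >= ", len, call. = FALSE)
    }
    substr(rows$sequence[[1]], 1, len)
  }
  list(
    noncoding = take_first("noncoding", nc_len),
    coding = take_first("coding", c_len)
  )
}

#' Write a region partition to BED
#'
#' BED uses 0-based half-open coordinates, matching the internal convention,
#' so intervals round-trip exactly; the region kind is stored in the BED name
#' column.
#'
#' @param partition Region tibble from [partition_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(partition, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = partition$seq_id,
    ranges = IRanges::IRanges(start = partition$start + 1L,
                              end = partition$end),
    name = partition$kind
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file of regions written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return A tibble with `seq_id`, `start`, `end` (0-based half-open), `kind`.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    kind = as.character(gr$name)
  )
}

#' Summarise a partition's coding and non-coding content
#'
#' @param partition Region tibble from [partition_regions()].
#' @return A tibble with one row per region kind: total bp, region count and
#'   the fraction of the genome covered.
#' @export
partition_summary <- function(partition) {
  partition |>
    dplyr::mutate(len = .data$end - .data$start) |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(bp = sum(.data$len), n_regions = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$bp / sum(.data$bp))
}

#' Non-coding fraction from coding and non-coding base-pair totals
#'
#' Convenience arithmetic for genome-composition summaries:
#' `noncoding_bp / (coding_bp + noncoding_bp)`.
#'
#' @param coding_bp,noncoding_bp Base-pair totals (non-negative, sum > 0).
#' @return The non-coding fraction in `[0, 1]`.
#' @examples
#' noncoding_fraction(4034041, 394851)
#' @export
noncoding_fraction <- function(coding_bp, noncoding_bp) {
  stopifnot(coding_bp >= 0, noncoding_bp >= 0, coding_bp + noncoding_bp > 0)
  noncoding_bp / (coding_bp + noncoding_bp)
}
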