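#' Construct a transcript model
#'
#' A transcript model is one isoform: an ordered chain of exons on one
#' chromosome and strand, with an integer read-support count (number of long
#' reads collapsed into the model). All coordinates are 0-based half-open;
#' exons must be sorted by start, disjoint, and separated by introns of at
#' least 1 bp.
#'
#' @param transcript_id,gene_id Non-empty identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`. Unstranded models are not allowed: the
#'   transcription start site and splice-site orientation depend on strand.
#' @param exons Two-column matrix or data frame of 0-based half-open
#'   `start`/`end` coordinates, one row per exon.
#' @param read_support Non-negative integer; defaults to 1.
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- transcript_model("T1", "G1", "chr1", "+",
#'                        cbind(start = c(100, 300), end = c(200, 400)),
#'                        read_support = 7)
#' tx_introns(tx)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             read_support = 1L) {
  exons <- .as_exon_matrix(exons)
  obj <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = as.character(strand),
         exons = exons,
         read_support = as.integer(read_support)),
    class = "transcript_model")
  validate_transcript_model(obj)
}

.as_exon_matrix <- function(exons) {
  if (is.data.frame(exons)) exons <- as.matrix(exons[, c("start", "end")])
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  storage.mode(exons) <- "integer"
  exons
}

#' Validate a transcript model's invariants
#'
#' Checks the exon-chain invariants: at least one exon, `0 <= start < end`
#' for every exon, exons sorted ascending by start, disjoint, and separated
#' by introns of length >= 1.
#'
#' @param x A `transcript_model`.
#' @return `x`, invisibly usable; errors describe the violated invariant.
#' @export
validate_transcript_model <- function(x) {
  if (!nzchar(x$transcript_id) || !nzchar(x$gene_id) || !nzchar(x$chrom))
    stop("transcript_id, gene_id and chrom must be non-empty")
  if (!x$strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", x$transcript_id)
  ex <- x$exons
  if (nrow(ex) < 1L) stop("transcript ", x$transcript_id, " has no exons")
  if (any(ex[, "start"] < 0L) || any(ex[, "end"] <= ex[, "start"]))
    stop("invalid exon coordinates (need 0 <= start < end) in transcript ",
         x$transcript_id)
  if (is.unsorted(ex[, "start"], strictly = TRUE) && nrow(ex) > 1L)
    stop("exons of transcript ", x$transcript_id,
         " are not sorted by ascending start")
  if (nrow(ex) > 1L) {
    gap <- ex[-1L, "start"] - ex[-nrow(ex), "end"]
    if (any(gap < 1L))
      stop("overlapping or abutting exons (intron length < 1) in transcript ",
           x$transcript_id)
  }
  if (is.na(x$read_support) || x$read_support < 0L)
    stop("read_support must be a non-negative integer")
  x
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s %d exon(s), support %d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$read_support))
  invisible(x)
}

#' Intron chain of a transcript
#'
#' @param x A `transcript_model`.
#' @return Integer matrix with columns `start`, `end` (0-based half-open),
#'   one row per intron; zero rows for a single-exon transcript.
#' @export
tx_introns <- function(x) {
  ex <- x$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
}

#' Bundle transcripts into a per-sample container
#'
#' @param sample_id Sample label.
#' @param transcripts List of `transcript_model` objects with unique
#'   `transcript_id`s.
#' @return An object of class `sample_transcriptome`.
#' @export
sample_transcriptome <- function(sample_id, transcripts) {
  stopifnot(nzchar(sample_id), is.list(transcripts))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate transcript_id(s) in sample ", sample_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(sample_id = sample_id, transcripts = transcripts),
            class = "sample_transcriptome")
}

#' @export
print.sample_transcriptome <- function(x, ...) {
  cat(sprintf("<sample_transcriptome> %s: %d transcript(s), %d gene(s)\n",
              x$sample_id, length(x$transcripts),
              length(unique(vapply(x$transcripts, function(t) t$gene_id,
                                   character(1))))))
  invisible(x)
}

#' Construct a genomic feature track
#'
#' A named set of genomic intervals (e.g. CAGE peaks or histone-mark
#' regions) used for TSS-proximity queries. Intervals are 0-based half-open.
#'
#' @param name Track name, e.g. `"CAGE"` or `"H3K4me3"`.
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `strand` (defaults to `"."`; feature strand is not used by
#'   distance queries).
#' @return An object of class `feature_track`.
#' @export
feature_track <- function(name, intervals) {
  stopifnot(nzchar(name))
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), strand = character(0))
  } else {
    if (!all(c("chrom", "start", "end") %in% names(intervals)))
      stop("intervals need columns chrom, start, end")
    if (is.null(intervals$strand)) intervals$strand <- "."
    intervals <- data.frame(chrom = as.character(intervals$chrom),
                            start = as.integer(intervals$start),
                            end = as.integer(intervals$end),
                            strand = as.character(intervals$strand),
                            stringsAsFactors = FALSE)
    if (any(intervals$start < 0L) || any(intervals$end <= intervals$start))
      stop("invalid interval (need 0 <= start < end) in track ", name)
  }
  structure(list(name = name, intervals = intervals), class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %s: %d interval(s) on %d chromosome(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' A lncRNA catalog entry
#'
#' A reference-catalog transcript together with the set of tissues the
#' catalog annotates it in (possibly empty).
#'
#' @param transcript A `transcript_model`.
#' @param tissues Character vector of tissue labels; may be empty.
#' @return Object of class `catalog_entry`.
#' @export
catalog_entry <- function(transcript, tissues = character(0)) {
  stopifnot(inherits(transcript, "transcript_model"))
  structure(list(transcript = transcript,
                 tissues = sort(unique(as.character(tissues)))),
            class = "catalog_entry")
}

# Internal: GRanges from a feature_track / exon matrix (1-based closed).
.track_granges <- function(track) {
  iv <- track$intervals
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
}
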