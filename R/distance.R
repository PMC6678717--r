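# TSS-proximity analysis: strand-aware TSS extraction, nearest-feature
# distances against regulatory tracks, distance distributions, and the
# distance-cutoff transcript filter used to flag spurious long-read models.

#' Transcription start site of a transcript model
#'
#' The genomic position (0-based) of the first transcribed nucleotide:
#' the first exon's start for `+` strand, the last exon's final base
#' (`end - 1`) for `-` strand.
#'
#' @param x A `transcript_model`.
#' @return Integer genomic position.
#' @examples
#' tx <- transcript_model("T1", "G1", "chr1", "-",
#'                        cbind(start = c(100, 300), end = c(200, 400)))
#' tss_of(tx)  # 399
#' @export
tss_of <- function(x) {
  stopifnot(inherits(x, "transcript_model"))
  unname(if (x$strand == "+") x$exons[1L, "start"]
         else x$exons[nrow(x$exons), "end"] - 1L)
}

# Vectorized nearest-feature query. For each (tss, chrom, strand) triple,
# returns the track interval minimizing the edge distance
#   gap = 0                         if start <= tss < end
#   gap = min(|tss-(end-1)|, |tss-start|) otherwise
# with the sign assigned by transcription direction (upstream negative).
# Candidate features come from GenomicRanges (overlap hit, nearest interval
# ending before the TSS, nearest interval starting after); ties between an
# upstream and a downstream candidate at equal |distance| resolve to the
# downstream one.
.nearest_distances <- function(tss, chrom, strand, track) {
  n <- length(tss)
  out <- data.frame(distance = rep(NA_integer_, n),
                    feature_chrom = NA_character_,
                    feature_start = NA_integer_, feature_end = NA_integer_,
                    stringsAsFactors = FALSE)
  iv <- track$intervals
  if (nrow(iv) == 0L || n == 0L) return(out)
  subj <- .track_granges(track)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss + 1L, tss + 1L))
  suppressWarnings({
    ov <- GenomicRanges::findOverlaps(q, subj)
    i_down <- GenomicRanges::precede(q, subj, ignore.strand = TRUE)
    i_up <- GenomicRanges::follow(q, subj, ignore.strand = TRUE)
  })
  # containment: distance 0; deterministic pick = smallest (start, end)
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ord <- order(qh, iv$start[sh], iv$end[sh])
    first <- !duplicated(qh[ord])
    qi <- qh[ord][first]; si <- sh[ord][first]
    out$distance[qi] <- 0L
    out$feature_chrom[qi] <- iv$chrom[si]
    out$feature_start[qi] <- iv$start[si]
    out$feature_end[qi] <- iv$end[si]
  }
  todo <- which(is.na(out$distance))
  for (k in todo) {
    cand <- c(i_down[k], i_up[k])
    cand <- cand[!is.na(cand)]
    if (length(cand) == 0L) next
    goff <- ifelse(iv$start[cand] > tss[k],
                   iv$start[cand] - tss[k],              # genome-right
                   (iv$end[cand] - 1L) - tss[k])         # genome-left, < 0
    # transcription-direction sign: downstream positive
    d_tx <- if (strand[k] == "+") goff else -goff
    best <- which(abs(goff) == min(abs(goff)))
    if (length(best) > 1L) best <- best[which.max(d_tx[best])]  # downstream tie-break
    ci <- cand[best]
    out$distance[k] <- as.integer(d_tx[best])
    out$feature_chrom[k] <- iv$chrom[ci]
    out$feature_start[k] <- iv$start[ci]
    out$feature_end[k] <- iv$end[ci]
  }
  out
}

#' Distance from a TSS to the nearest feature of a track
#'
#' Distance is measured TSS-to-nearest-edge: 0 when the TSS lies inside a
#' feature, otherwise the smallest gap to a feature edge. The sign follows
#' transcription direction: negative when the nearest feature lies upstream
#' of the TSS, positive downstream. When upstream and downstream candidates
#' tie in absolute distance, the downstream feature is reported (the
#' absolute distance is unaffected).
#'
#' @param tss 0-based genomic position.
#' @param chrom Chromosome of the TSS.
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @param track A [feature_track()].
#' @return List with `distance` (signed integer, or `NA` when the track has
#'   no feature on that chromosome) and `feature` (list `chrom`/`start`/`end`,
#'   or `NULL`).
#' @export
nearest_feature_distance <- function(tss, chrom, strand, track) {
  stopifnot(strand %in% c("+", "-"), inherits(track, "feature_track"))
  r <- .nearest_distances(as.integer(tss), chrom, strand, track)
  if (is.na(r$distance[1]))
    list(distance = NA_integer_, feature = NULL)
  else
    list(distance = r$distance[1],
         feature = list(chrom = r$feature_chrom[1],
                        start = r$feature_start[1], end = r$feature_end[1]))
}

#' TSS distance report for a sample against feature tracks
#'
#' Computes, for every (transcript, track) pair, the signed distance from the
#' transcript's TSS to the nearest feature, plus per-track histograms of
#' absolute distance. The histograms summarize how well the start sites of
#' the sequenced transcripts are supported by promoter-associated evidence.
#'
#' @param sample A [sample_transcriptome()].
#' @param tracks List of [feature_track()]s.
#' @param bins Ascending absolute-distance bin edges; last edge may be `Inf`.
#' @return Object of class `distance_summary`: `records` (data frame
#'   transcript_id/track/distance/feature coordinates; `NA` distance when a
#'   track has no feature on the transcript's chromosome), `histogram`
#'   (tracks x bins count matrix over finite `|distance|`), `bins`.
#' @export
distance_summary <- function(sample, tracks,
                             bins = c(0, 100, 500, 1000, 5000, 10000, Inf)) {
  stopifnot(inherits(sample, "sample_transcriptome"), length(tracks) >= 1L,
            length(sample$transcripts) >= 1L)
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly ascending")
  txs <- sample$transcripts
  tss <- vapply(txs, tss_of, integer(1))
  chrom <- vapply(txs, function(t) t$chrom, character(1))
  strand <- vapply(txs, function(t) t$strand, character(1))
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  recs <- lapply(tracks, function(tr) {
    r <- .nearest_distances(tss, chrom, strand, tr)
    cbind(data.frame(transcript_id = ids, track = tr$name,
                     stringsAsFactors = FALSE), r)
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  nb <- length(bins) - 1L
  lab <- sprintf("[%s,%s)", bins[-length(bins)], bins[-1L])
  hist <- matrix(0L, nrow = length(tracks), ncol = nb,
                 dimnames = list(vapply(tracks, function(t) t$name,
                                        character(1)), lab))
  for (tr in seq_along(tracks)) {
    d <- abs(records$distance[records$track == rownames(hist)[tr]])
    d <- d[!is.na(d)]
    if (length(d))
      hist[tr, ] <- as.vector(table(cut(d, breaks = bins, right = FALSE,
                                        labels = lab)))
  }
  structure(list(records = records, histogram = hist, bins = bins),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary>", nrow(x$records), "record(s) over",
      nrow(x$histogram), "track(s)\n")
  print(x$histogram)
  invisible(x)
}

#' Filter transcripts by TSS proximity to regulatory features
#'
#' Implements the full-length-transcript validation filter: a transcript is
#' kept when regulatory evidence (a CAGE peak or histone-mark region) lies
#' within `cutoff_bp` of its first nucleotide, upstream or downstream;
#' otherwise it is flagged as a likely spurious model. The boundary is
#' inclusive (`|distance| <= cutoff_bp` keeps). Default cutoff 1000 bp.
#'
#' @param sample A [sample_transcriptome()].
#' @param tracks Non-empty list of [feature_track()]s.
#' @param cutoff_bp Positive distance cutoff in bp (default 1000).
#' @param mode `"any"` (default): evidence in at least one track suffices;
#'   `"all"`: every track must have a feature within the cutoff.
#' @return Object of class `filter_report`: `kept` and `discarded`
#'   transcript-id vectors (a partition of the input), `cutoff_bp`, `mode`,
#'   `tracks_used`, and `min_abs_distance` (named per-transcript minimum
#'   absolute distance across tracks; `NA` when no track has a feature on
#'   the transcript's chromosome).
#' @export
filter_by_distance <- function(sample, tracks, cutoff_bp = 1000L,
                               mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (length(tracks) == 0L) stop("at least one feature track is required")
  if (!is.numeric(cutoff_bp) || cutoff_bp <= 0)
    stop("cutoff_bp must be a positive integer")
  txs <- sample$transcripts
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  tss <- vapply(txs, tss_of, integer(1))
  chrom <- vapply(txs, function(t) t$chrom, character(1))
  strand <- vapply(txs, function(t) t$strand, character(1))
  dmat <- vapply(tracks, function(tr)
    abs(.nearest_distances(tss, chrom, strand, tr)$distance),
    numeric(length(ids)))
  dmat <- matrix(dmat, nrow = length(ids))
  within <- !is.na(dmat) & dmat <= cutoff_bp
  keep <- if (mode == "any") rowSums(within) >= 1L
          else rowSums(within) == length(tracks)
  min_d <- apply(dmat, 1L, function(r)
    if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  structure(list(kept = ids[keep], discarded = ids[!keep],
                 cutoff_bp = as.integer(cutoff_bp), mode = mode,
                 tracks_used = vapply(tracks, function(t) t$name, character(1)),
                 min_abs_distance = stats::setNames(min_d, ids)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> cutoff %d bp (mode %s, tracks: %s): kept %d, discarded %d\n",
    x$cutoff_bp, x$mode, paste(x$tracks_used, collapse = ", "),
    length(x$kept), length(x$discarded)))
  invisible(x)
}
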