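# Long noncoding RNA triage: combining coding-potential predictions from two
# external classifiers, matching candidate transcripts against a lncRNA
# reference catalog, and extracting tissue-specific novel lncRNAs.

#' Combine noncoding calls from two classifiers
#'
#' Builds the four noncoding-call sets users choose between: each tool's own
#' set, their intersection (higher precision) and their union (higher
#' recall). Transcripts scored by only one tool are excluded from the
#' intersection and enter the union through the calling tool alone.
#'
#' @param a,b `prediction_set` objects from [read_predictions()].
#' @return Named list of four `lnc_callset`s (`tool_a`, `tool_b`,
#'   `intersection`, `union`), each with `source`, `tool`, and sorted
#'   `transcript_ids`.
#' @export
combine_predictions <- function(a, b) {
  stopifnot(inherits(a, "prediction_set"), inherits(b, "prediction_set"))
  nc_a <- sort(names(a$calls)[a$calls == "noncoding"])
  nc_b <- sort(names(b$calls)[b$calls == "noncoding"])
  mk <- function(source, tool, ids)
    structure(list(source = source, tool = tool,
                   transcript_ids = sort(unique(ids))),
              class = "lnc_callset")
  list(tool_a = mk("tool_a", a$tool_name, nc_a),
       tool_b = mk("tool_b", b$tool_name, nc_b),
       intersection = mk("intersection",
                         paste(a$tool_name, b$tool_name, sep = "&"),
                         intersect(nc_a, nc_b)),
       union = mk("union", paste(a$tool_name, b$tool_name, sep = "|"),
                  union(nc_a, nc_b)))
}

#' @export
print.lnc_callset <- function(x, ...) {
  cat(sprintf("<lnc_callset> %s (%s): %d transcript(s)\n", x$source, x$tool,
              length(x$transcript_ids)))
  invisible(x)
}

# total exonic overlap (bp) between two exon matrices on the same chrom
.exonic_overlap <- function(ex1, ex2) {
  tot <- 0L
  for (i in seq_len(nrow(ex1))) {
    s <- pmax(ex1[i, "start"], ex2[, "start"])
    e <- pmin(ex1[i, "end"], ex2[, "end"])
    tot <- tot + sum(pmax(0L, e - s))
  }
  tot
}

.intron_key <- function(tx) {
  iv <- tx_introns(tx)
  paste(tx$chrom, tx$strand,
        paste(iv[, "start"], iv[, "end"], sep = "-", collapse = ","),
        sep = ":")
}

#' Match candidate transcripts against a lncRNA reference catalog
#'
#' A candidate is called `known` when the catalog already contains its
#' structure, else `novel`. The default criterion is intron-chain identity
#' on the same chromosome and strand — robust to the ragged 5'/3' transcript
#' ends typical of long reads, which should not create spurious novel calls.
#' Single-exon candidates (no intron chain) fall back to reciprocal exonic
#' overlap. `exon_overlap` mode uses reciprocal overlap throughout: known
#' when overlap/exonic-length >= `min_overlap` for both candidate and entry.
#'
#' @param candidates List of `transcript_model`.
#' @param catalog List of [catalog_entry()]s (or bare `transcript_model`s,
#'   which get empty tissue sets).
#' @param mode `"intron_chain"` (default) or `"exon_overlap"`.
#' @param min_overlap Reciprocal-overlap threshold in (0, 1]; default 0.5.
#' @return Object of class `catalog_match`: data frame with `transcript_id`,
#'   `verdict` (`known`/`novel`), `matched_entries` (semicolon-joined ids);
#'   the full candidate->entries map is in `attr(, "matches")`.
#' @export
match_to_catalog <- function(candidates, catalog,
                             mode = c("intron_chain", "exon_overlap"),
                             min_overlap = 0.5) {
  mode <- match.arg(mode)
  if (min_overlap <= 0 || min_overlap > 1)
    stop("min_overlap must be in (0, 1]")
  catalog <- lapply(catalog, function(e)
    if (inherits(e, "catalog_entry")) e else catalog_entry(e))
  cat_tx <- lapply(catalog, function(e) e$transcript)
  cat_ids <- vapply(cat_tx, function(t) t$transcript_id, character(1))
  cat_chain <- vapply(cat_tx, .intron_key, character(1))
  cat_multi <- vapply(cat_tx, function(t) nrow(t$exons) > 1L, logical(1))
  cat_loc <- vapply(cat_tx, function(t) paste(t$chrom, t$strand), character(1))

  overlap_hits <- function(cand) {
    hits <- character(0)
    len_c <- sum(cand$exons[, "end"] - cand$exons[, "start"])
    for (i in which(cat_loc == paste(cand$chrom, cand$strand))) {
      ov <- .exonic_overlap(cand$exons, cat_tx[[i]]$exons)
      len_e <- sum(cat_tx[[i]]$exons[, "end"] - cat_tx[[i]]$exons[, "start"])
      if (ov / len_c >= min_overlap && ov / len_e >= min_overlap)
        hits <- c(hits, cat_ids[i])
    }
    hits
  }

  matches <- lapply(candidates, function(cand) {
    if (mode == "intron_chain" && nrow(cand$exons) > 1L) {
      cat_ids[cat_multi & cat_chain == .intron_key(cand)]
    } else {
      overlap_hits(cand)
    }
  })
  ids <- vapply(candidates, function(t) t$transcript_id, character(1))
  names(matches) <- ids
  df <- data.frame(
    transcript_id = ids,
    verdict = ifelse(lengths(matches) > 0L, "known", "novel"),
    matched_entries = vapply(matches, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "matches") <- matches
  attr(df, "mode") <- mode
  class(df) <- c("catalog_match", "data.frame")
  df
}

#' Extract tissue-specific matches from catalog verdicts
#'
#' A matched candidate is tissue-specific when the union of tissue labels
#' over all catalog entries it matches has size exactly one. Candidates
#' whose matched entries carry no tissue labels at all are reported
#' separately as unassigned rather than called specific.
#'
#' @param matched A `catalog_match` from [match_to_catalog()].
#' @param catalog The same catalog list (entries must carry tissue labels).
#' @return List with `by_tissue` (named list tissue -> sorted transcript
#'   ids), `unassigned`, and `not_specific` (matched in >= 2 tissues).
#' @export
tissue_specific <- function(matched, catalog) {
  stopifnot(inherits(matched, "catalog_match"))
  catalog <- lapply(catalog, function(e)
    if (inherits(e, "catalog_entry")) e else catalog_entry(e))
  ent_ids <- vapply(catalog, function(e) e$transcript$transcript_id,
                    character(1))
  tiss_of <- function(entry_ids) {
    sort(unique(unlist(lapply(catalog[match(entry_ids, ent_ids)],
                              function(e) e$tissues))))
  }
  matches <- attr(matched, "matches")
  by_tissue <- list(); unassigned <- character(0); not_specific <- character(0)
  for (id in names(matches)) {
    ents <- matches[[id]]
    if (length(ents) == 0L) next            # novel: no catalog tissue info
    ts <- tiss_of(ents)
    if (length(ts) == 0L) unassigned <- c(unassigned, id)
    else if (length(ts) == 1L) by_tissue[[ts]] <- c(by_tissue[[ts]], id)
    else not_specific <- c(not_specific, id)
  }
  if (length(by_tissue)) by_tissue <- by_tissue[order(names(by_tissue))]
  list(by_tissue = lapply(by_tissue, sort),
       unassigned = sort(unassigned), not_specific = sort(not_specific))
}
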