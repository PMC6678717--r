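# Readers and writers for the plain-text formats the toolkit consumes.
# Internal convention is uniformly 0-based half-open; GTF (1-based inclusive)
# converts at this boundary and nowhere else.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

# Parse one GTF attribute column accepting both `key "value";` and
# `key=value` dialects (Ensembl-style vs tool-emitted GTFs).
.parse_gtf_attrs <- function(s) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  out <- character(0)
  for (tk in toks) {
    m <- regmatches(tk, regexec('^(\\S+)\\s+"([^"]*)"$', tk))[[1]]
    if (length(m) == 0L)
      m <- regmatches(tk, regexec('^(\\S+?)\\s*=\\s*"?([^"]*?)"?$', tk))[[1]]
    if (length(m) == 3L) out[m[2]] <- m[3]
  }
  out
}

#' Read transcript models from a GTF file
#'
#' Parses exon features of a GTF2-style file into [transcript_model]
#' objects. GTF's 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention (`start - 1`, `end`). Attribute
#' columns may use either the `key "value";` or the `key=value` dialect.
#' Transcripts without a definite strand (`.`) are dropped with a message
#' reporting how many, since TSS extraction and splice-site orientation
#' require strand.
#'
#' @param path GTF file path.
#' @param read_support_attr Attribute key holding the per-transcript long-read
#'   count. Long-read collapse pipelines name this inconsistently, hence
#'   configurable; transcripts lacking the attribute get support 1.
#' @return List of `transcript_model`, ordered by transcript_id. The number
#'   of strand-less transcripts dropped is attached as attribute
#'   `"n_dropped_no_strand"`.
#' @seealso [write_gtf()], [read_bed12_transcripts()]
#' @export
read_gtf <- function(path, read_support_attr = "read_count") {
  lines <- .read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  recs <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    if (f[3] != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("malformed GTF line ", i, ": non-integer coordinates")
    if (end < start)
      stop("invalid exon on GTF line ", i, ": end < start")
    at <- .parse_gtf_attrs(f[9])
    if (is.na(at["gene_id"]) || is.na(at["transcript_id"]))
      stop("malformed GTF line ", i, ": missing gene_id or transcript_id")
    recs[[length(recs) + 1L]] <- list(
      chrom = f[1], start = start - 1L, end = end, strand = f[7],
      gene_id = unname(at["gene_id"]),
      transcript_id = unname(at["transcript_id"]),
      support = unname(at[read_support_attr]))
  }
  if (length(recs) == 0L)
    return(structure(list(), n_dropped_no_strand = 0L))
  df <- do.call(rbind, lapply(recs, as.data.frame, stringsAsFactors = FALSE))
  out <- list()
  dropped <- 0L
  for (tid in sort(unique(df$transcript_id))) {
    d <- df[df$transcript_id == tid, , drop = FALSE]
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L)
      stop("transcript ", tid, " has exons on multiple chromosomes/strands")
    if (!d$strand[1] %in% c("+", "-")) { dropped <- dropped + 1L; next }
    if (length(unique(d$gene_id)) > 1L)
      stop("transcript ", tid, " assigned to multiple genes")
    d <- d[order(d$start), , drop = FALSE]
    sup <- suppressWarnings(as.integer(d$support[!is.na(d$support)][1]))
    out[[length(out) + 1L]] <- transcript_model(
      tid, d$gene_id[1], d$chrom[1], d$strand[1],
      cbind(start = d$start, end = d$end),
      read_support = if (is.na(sup)) 1L else sup)
  }
  if (dropped > 0L)
    message("read_gtf: dropped ", dropped, " transcript(s) without strand")
  attr(out, "n_dropped_no_strand") <- dropped
  out
}

#' Write transcript models to GTF
#'
#' Emits one `exon` feature line per exon, converting back to GTF 1-based
#' inclusive coordinates. Records are sorted by (chrom, start, transcript_id)
#' so output is deterministic; a round trip through [read_gtf()] reproduces
#' coordinates exactly.
#'
#' @param transcripts List of `transcript_model`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @param read_support_attr Attribute key used for the read-support count.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "splicescope",
                      read_support_attr = "read_count") {
  rows <- lapply(transcripts, function(t) {
    data.frame(chrom = t$chrom, start = t$exons[, "start"] + 1L,
               end = t$exons[, "end"], strand = t$strand,
               gene_id = t$gene_id, transcript_id = t$transcript_id,
               support = t$read_support, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$transcript_id), , drop = FALSE]
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; %s "%d";',
    df$chrom, source, df$start, df$end, df$strand, df$gene_id,
    df$transcript_id, read_support_attr, df$support)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file as a feature track
#'
#' BED is already 0-based half-open, so coordinates are taken verbatim.
#' Strand comes from column 6 when present, else `"."`.
#'
#' @param path BED3+ file path.
#' @param name Track name to attach (e.g. `"CAGE"`).
#' @return A [feature_track()]. An empty file yields a valid empty track.
#' @export
read_bed <- function(path, name) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(feature_track(name, NULL))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("malformed BED line ", i, ": non-integer coordinates")
    if (start >= end) stop("invalid interval on BED line ", i, ": start >= end")
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    data.frame(chrom = f[1], start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  })
  feature_track(name, do.call(rbind, rows))
}

#' Write a feature track as BED6
#'
#' @param track A `feature_track`.
#' @param path Output path.
#' @return `path`, invisibly. Records sorted by (chrom, start).
#' @export
write_bed <- function(track, path) {
  iv <- track$intervals
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", iv$chrom, iv$start, iv$end,
                     track$name, iv$strand), path)
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' Reconstructs the exon chain from the block columns; the BED score column
#' maps to read support. BED12 carries no gene grouping, so `gene_id` is set
#' equal to `transcript_id`; regroup downstream if gene structure is needed.
#'
#' @param path BED12 file path.
#' @return List of `transcript_model`, ordered by transcript_id.
#' @export
read_bed12_transcripts <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("malformed BED12 line ", i, ": need 12 fields")
    chrom_start <- as.integer(f[2]); chrom_end <- as.integer(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      stop("BED12 line ", i, ": blockCount does not match block lists")
    ex_start <- chrom_start + starts
    ex_end <- ex_start + sizes
    if (ex_start[1] != chrom_start || ex_end[n_blocks] != chrom_end)
      stop("BED12 line ", i, ": blocks do not span chromStart..chromEnd")
    if (!f[6] %in% c("+", "-"))
      stop("BED12 line ", i, ": transcript without strand")
    out[[length(out) + 1L]] <- transcript_model(
      f[4], f[4], f[1], f[6], cbind(start = ex_start, end = ex_end),
      read_support = as.integer(f[5]))
  }
  out[order(vapply(out, function(t) t$transcript_id, character(1)))]
}

#' Write transcript models as BED12
#'
#' @param transcripts List of `transcript_model`.
#' @param path Output path.
#' @return `path`, invisibly. Records sorted by (chrom, start, id).
#' @export
write_bed12 <- function(transcripts, path) {
  rows <- vapply(transcripts, function(t) {
    ex <- t$exons
    cs <- ex[1, "start"]; ce <- ex[nrow(ex), "end"]
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            t$chrom, cs, ce, t$transcript_id, t$read_support, t$strand,
            cs, ce, nrow(ex),
            paste0(ex[, "end"] - ex[, "start"], collapse = ","),
            paste0(ex[, "start"] - cs, collapse = ","))
  }, character(1))
  key <- t(vapply(transcripts, function(t)
    c(t$chrom, sprintf("%012d", t$exons[1, "start"]), t$transcript_id),
    character(3)))
  writeLines(rows[order(key[, 1], key[, 2], key[, 3])], path)
  invisible(path)
}

#' Read a coding-potential prediction table
#'
#' Normalizes the output tables of external coding-potential classifiers
#' onto a single two-level label vocabulary (`coding` / `noncoding`).
#' Supported dialects: `plek` (label, score, id), `cnci` (id, index, score;
#' optional header), and `generic` (id TAB label).
#'
#' @param path Tabular file path.
#' @param dialect One of `"generic"`, `"plek"`, `"cnci"`.
#' @param tool_name Name recorded for the prediction set; defaults to the
#'   dialect name.
#' @return Object of class `prediction_set`: `tool_name`, `calls` (named
#'   character vector of `coding`/`noncoding`), `score` (named numeric or
#'   `NULL`).
#' @export
read_predictions <- function(path, dialect = c("generic", "plek", "cnci"),
                             tool_name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(tool_name)) tool_name <- dialect
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); labels <- character(0); scores <- numeric(0)
  norm_label <- function(x, line) {
    lx <- tolower(gsub("[-_ ]", "", x))
    if (lx == "coding") return("coding")
    if (lx %in% c("noncoding", "noncoding")) return("noncoding")
    stop("unknown coding-potential label '", x, "' on line ", line)
  }
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "cnci" && i == 1L && grepl("^Transcript", f[1],
                                              ignore.case = TRUE)) next
    if (dialect == "generic") {
      if (length(f) < 2L) stop("malformed prediction line ", i)
      ids <- c(ids, f[1]); labels <- c(labels, norm_label(f[2], i))
      scores <- c(scores, NA_real_)
    } else if (dialect == "plek") {
      if (length(f) < 3L) stop("malformed prediction line ", i)
      ids <- c(ids, sub("^>", "", f[3]))
      labels <- c(labels, norm_label(f[1], i))
      scores <- c(scores, suppressWarnings(as.numeric(f[2])))
    } else {
      if (length(f) < 3L) stop("malformed prediction line ", i)
      ids <- c(ids, f[1]); labels <- c(labels, norm_label(f[2], i))
      scores <- c(scores, suppressWarnings(as.numeric(f[3])))
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in prediction table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  calls <- stats::setNames(labels, ids)
  sc <- if (all(is.na(scores))) NULL else stats::setNames(scores, ids)
  structure(list(tool_name = tool_name, calls = calls, score = sc),
            class = "prediction_set")
}

#' Write a prediction set in the generic dialect
#'
#' @param pred A `prediction_set`.
#' @param path Output path (`id TAB label`, sorted by id).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  ids <- sort(names(pred$calls))
  writeLines(sprintf("%s\t%s", ids, unname(pred$calls[ids])), path)
  invisible(path)
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %s: %d call(s) (%d noncoding)\n",
              x$tool_name, length(x$calls), sum(x$calls == "noncoding")))
  invisible(x)
}

#' Read a gene-to-GO annotation map
#'
#' Accepts a simple TSV (`gene_id TAB term_id [TAB term_name]`) or GAF 2.x
#' (gene from column 2, GO term from column 5; `!` comment lines skipped,
#' short lines skipped with a message). Memberships are deduplicated and
#' terms with empty gene sets dropped.
#'
#' @param path Annotation file path.
#' @return Object of class `annotation_map`: `terms` (named list term ->
#'   character vector of genes), `term_names` (named character), and
#'   `background` (all annotated genes).
#' @export
read_annotation <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  gaf <- grepl("^!", lines[1]) ||
    length(strsplit(lines[1], "\t", fixed = TRUE)[[1]]) >= 15L
  genes <- character(0); terms <- character(0); tnames <- character(0)
  skipped <- 0L
  for (ln in lines) {
    if (grepl("^[!#]", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (gaf) {
      if (length(f) < 5L) { skipped <- skipped + 1L; next }
      genes <- c(genes, f[2]); terms <- c(terms, f[5])
      tnames <- c(tnames, NA_character_)
    } else {
      if (length(f) < 2L) { skipped <- skipped + 1L; next }
      genes <- c(genes, f[1]); terms <- c(terms, f[2])
      tnames <- c(tnames, if (length(f) >= 3L) f[3] else NA_character_)
    }
  }
  if (skipped > 0L)
    message("read_annotation: skipped ", skipped, " unparseable line(s)")
  if (length(genes) == 0L) stop("no annotation records in ", path)
  term_ids <- sort(unique(terms))
  term_list <- lapply(term_ids, function(tm) sort(unique(genes[terms == tm])))
  names(term_list) <- term_ids
  nm <- vapply(term_ids, function(tm) {
    v <- tnames[terms == tm & !is.na(tnames)]
    if (length(v)) v[1] else NA_character_
  }, character(1))
  structure(list(terms = term_list, term_names = nm,
                 background = sort(unique(genes))),
            class = "annotation_map")
}

#' Write an annotation map as TSV
#'
#' @param annot An `annotation_map`.
#' @param path Output path (`gene TAB term [TAB name]`, sorted).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  rows <- unlist(lapply(names(annot$terms), function(tm) {
    nm <- annot$term_names[[tm]]
    if (is.na(nm))
      sprintf("%s\t%s", annot$terms[[tm]], tm)
    else
      sprintf("%s\t%s\t%s", annot$terms[[tm]], tm, nm)
  }))
  writeLines(sort(rows), path)
  invisible(path)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d term(s), %d background gene(s)\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Read per-transcript tissue labels
#'
#' TSV format: `transcript_id TAB comma-joined tissue labels` (empty second
#' field = no tissue annotation).
#'
#' @param path TSV path.
#' @return Named list: transcript_id -> character vector of tissues.
#' @export
read_tissue_labels <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 1L || !nzchar(f[1]))
      stop("malformed tissue-label line ", i)
    ts <- if (length(f) >= 2L && nzchar(f[2]))
      strsplit(f[2], ",", fixed = TRUE)[[1]] else character(0)
    out[[f[1]]] <- sort(unique(trimws(ts)))
  }
  out
}

#' Attach tissue labels to catalog transcripts
#'
#' @param transcripts List of `transcript_model` (the reference catalog).
#' @param labels Named list from [read_tissue_labels()]; transcripts without
#'   an entry get an empty tissue set.
#' @return List of [catalog_entry()]s.
#' @export
build_catalog <- function(transcripts, labels = list()) {
  lapply(transcripts, function(t)
    catalog_entry(t, tissues = if (!is.null(labels[[t$transcript_id]]))
      labels[[t$transcript_id]] else character(0)))
}

#' Export classified splicing events as TSV
#'
#' Columns: event_id, type, gene_id, chrom, strand, coordinates
#' (dash-joined), inclusion and exclusion transcript lists
#' (semicolon-joined) — structurally compatible with SUPPA-style ioe
#' consumers.
#'
#' @param events List of `as_event` from [detect_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- events_to_df(events)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
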