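# Figures with machine-readable layout manifests. Every plot writes, next
# to the image, a JSON manifest carrying the exact numeric content drawn
# (element coordinates, percentages, bin counts, region counts) so tests
# assert against the upstream computation instead of pixels.

.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg" && capabilities("cairo"))
    grDevices::svg(path, width = width, height = height)
  else
    grDevices::png(path, width = width * 100, height = height * 100,
                   res = 100)
}

.manifest_path <- function(image_path) sub("\\.[^.]+$", ".json", image_path)

.write_manifest <- function(manifest, image_path) {
  jsonlite::write_json(manifest, .manifest_path(image_path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

# default style roles; overridable per call
.default_style <- function() {
  list(novel_transcripts = "red", known_tgs_transcripts = "black",
       annotation_transcripts = "blue", CAGE = "red", H3K4me1 = "red2",
       H3K4me3 = "blue2", H3K27ac = "green3", feature_default = "grey40")
}

#' Transcript overview plot for one gene
#'
#' Draws the sequenced isoforms of a gene above the known annotation, with
#' exons as filled boxes, introns as connecting lines and a strand
#' arrowhead; each transcript label carries its long-read support in
#' brackets, e.g. `T1 (17)`. CAGE peaks and histone-mark features inside the
#' plotted region are rendered as arrow glyphs below the transcripts. Track
#' stacking order: novel, known-from-long-reads, annotation, then feature
#' tracks. Colors are style roles (novel = red, long-read-known = black,
#' annotation = blue by default), overridable via `style`.
#'
#' @param gene_id Gene to display.
#' @param samples List of [sample_transcriptome()]s holding the sequenced
#'   transcripts.
#' @param annotation Optional list of `transcript_model` (known annotation).
#' @param tracks Optional list of [feature_track()]s.
#' @param out_path Image path (`.png`, or `.svg` where cairo is available).
#' @param known_ids Transcript ids among `samples` to style as known rather
#'   than novel.
#' @param flank Region flank beyond the gene span (bp, default 2000).
#' @param style Named list of role -> color overrides.
#' @return (invisibly) the layout manifest: region plus one record per drawn
#'   element (exons, introns, labels, features) with genomic coordinates and
#'   track role; elements outside the region are clipped or dropped.
#' @export
plot_transcript_overview <- function(gene_id, samples, annotation = NULL,
                                     tracks = list(), out_path,
                                     known_ids = character(0),
                                     flank = 2000L, style = list()) {
  sty <- utils::modifyList(.default_style(), style)
  seq_tx <- unlist(lapply(samples, function(s) s$transcripts),
                   recursive = FALSE)
  seq_tx <- seq_tx[vapply(seq_tx, function(t) t$gene_id == gene_id,
                          logical(1))]
  ann_tx <- annotation[vapply(annotation, function(t) t$gene_id == gene_id,
                              logical(1))]
  all_tx <- c(seq_tx, ann_tx)
  if (length(all_tx) == 0L) {
    avail <- sort(unique(c(
      unlist(lapply(samples, function(s)
        vapply(s$transcripts, function(t) t$gene_id, character(1)))),
      vapply(annotation, function(t) t$gene_id, character(1)))))
    stop("gene ", gene_id, " not found; available: ",
         paste(avail, collapse = ", "))
  }
  chrom <- all_tx[[1]]$chrom
  span <- range(unlist(lapply(all_tx, function(t) t$exons)))
  region <- c(max(0L, span[1] - flank), span[2] + flank)

  rows <- c(seq_tx, ann_tx)
  roles <- c(
    vapply(seq_tx, function(t)
      if (t$transcript_id %in% known_ids) "known_tgs_transcripts"
      else "novel_transcripts", character(1)),
    rep("annotation_transcripts", length(ann_tx)))
  elements <- list()
  add_el <- function(el) elements[[length(elements) + 1L]] <<- el

  n_rows <- length(rows) + length(tracks)
  .open_device(out_path, 8, max(2.5, 0.5 * n_rows + 1))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = region, ylim = c(0, n_rows + 1), xlab = chrom,
                 ylab = "", yaxt = "n", bty = "n",
                 main = sprintf("%s (%s:%d-%d)", gene_id, chrom,
                                region[1], region[2]))
  y <- n_rows
  for (i in seq_along(rows)) {
    t <- rows[[i]]; col <- sty[[roles[i]]]
    ex <- t$exons
    ex[, "start"] <- pmax(ex[, "start"], region[1])
    ex[, "end"] <- pmin(ex[, "end"], region[2])
    ex <- ex[ex[, "end"] > ex[, "start"], , drop = FALSE]
    graphics::segments(min(ex[, "start"]), y, max(ex[, "end"]), y, col = col)
    graphics::rect(ex[, "start"], y - 0.18, ex[, "end"], y + 0.18,
                   col = col, border = col)
    for (r in seq_len(nrow(ex)))
      add_el(list(element = "exon", track = roles[i],
                  id = t$transcript_id, chrom = chrom,
                  start = ex[r, "start"], end = ex[r, "end"]))
    iv <- tx_introns(t)
    if (nrow(iv) > 0L) for (r in seq_len(nrow(iv)))
      add_el(list(element = "intron", track = roles[i],
                  id = t$transcript_id, chrom = chrom,
                  start = iv[r, "start"], end = iv[r, "end"]))
    lab <- sprintf("%s (%d)", t$transcript_id, t$read_support)
    graphics::text(min(ex[, "start"]), y + 0.35, lab, adj = 0, cex = 0.7,
                   col = col)
    arrow_x <- if (t$strand == "+") max(ex[, "end"]) else min(ex[, "start"])
    graphics::points(arrow_x, y, pch = if (t$strand == "+") ">" else "<",
                     col = col)
    add_el(list(element = "label", track = roles[i], id = t$transcript_id,
                chrom = chrom, start = min(ex[, "start"]),
                end = min(ex[, "start"]), label = lab))
    y <- y - 1
  }
  for (tr in tracks) {
    iv <- tr$intervals
    iv <- iv[iv$chrom == chrom & iv$end > region[1] & iv$start < region[2], ,
             drop = FALSE]
    col <- if (!is.null(sty[[tr$name]])) sty[[tr$name]] else
      sty$feature_default
    graphics::text(region[1], y + 0.3, tr$name, adj = 0, cex = 0.7)
    if (nrow(iv) > 0L) for (r in seq_len(nrow(iv))) {
      s <- max(iv$start[r], region[1]); e <- min(iv$end[r], region[2])
      graphics::arrows((s + e) / 2, y + 0.25, (s + e) / 2, y - 0.05,
                       length = 0.06, col = col)
      add_el(list(element = "feature", track = tr$name, id = tr$name,
                  chrom = chrom, start = s, end = e))
    }
    y <- y - 1
  }
  manifest <- list(gene_id = gene_id, chrom = chrom,
                   region = list(start = region[1], end = region[2]),
                   elements = elements)
  .write_manifest(manifest, out_path)
}

#' Stacked percentage bars of splicing event types per sample
#'
#' One 100% stacked bar per sample, segments in the fixed type order
#' `A3, A5, AF, AL, MX, RI, SE`, annotated with the chi-squared comparison
#' when supplied. Samples with zero total events are dropped.
#'
#' @param table An `as_count_table` (or count matrix).
#' @param test_result Optional `as_chisq_test` from [compare_as_profiles()].
#' @param out_path Image path.
#' @return (invisibly) the manifest: samples, types, per-sample percentages
#'   (each row summing to 100), counts, and the chi-squared annotation.
#' @export
plot_as_proportions <- function(table, test_result = NULL, out_path) {
  m <- if (inherits(table, "as_count_table")) table$counts else
    as.matrix(table)
  keep <- rowSums(m) > 0
  if (!any(keep)) stop("all-zero count table")
  m <- m[keep, , drop = FALSE]
  types <- colnames(m)
  if (is.null(types)) types <- as_event_types()[seq_len(ncol(m))]
  pct <- sweep(m, 1L, rowSums(m), "/") * 100
  cols <- grDevices::hcl.colors(ncol(m), "Dark 3")
  .open_device(out_path, 7, 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::barplot(t(pct), col = cols, legend.text = types,
                    ylab = "% of AS events",
                    args.legend = list(x = "topright", inset = c(-0.05, 0),
                                       xpd = TRUE, cex = 0.7))
  ann <- if (!is.null(test_result))
    sprintf("chi-squared = %.3g, df = %d, p = %.3g", test_result$chi2,
            test_result$dof, test_result$p) else NULL
  if (!is.null(ann)) graphics::mtext(ann, side = 3, cex = 0.8)
  manifest <- list(
    samples = rownames(m), types = types,
    percentages = lapply(seq_len(nrow(m)), function(i)
      as.list(stats::setNames(unname(pct[i, ]), types))),
    counts = lapply(seq_len(nrow(m)), function(i)
      as.list(stats::setNames(unname(m[i, ]), types))),
    chi2 = ann)
  names(manifest$percentages) <- rownames(m)
  names(manifest$counts) <- rownames(m)
  .write_manifest(manifest, out_path)
}

#' Histogram of TSS-to-feature distances per track
#'
#' Bar panels of absolute TSS distance per feature track on the configured
#' bins of a [distance_summary()].
#'
#' @param summary A `distance_summary`.
#' @param out_path Image path.
#' @return (invisibly) the manifest with per-track bin counts and edges.
#' @export
plot_distance_distribution <- function(summary, out_path) {
  stopifnot(inherits(summary, "distance_summary"))
  if (all(is.na(summary$records$distance)))
    stop("no finite distances to plot")
  h <- summary$histogram
  .open_device(out_path, 7, 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::barplot(h, beside = TRUE, legend.text = rownames(h),
                    ylab = "transcripts", xlab = "|TSS distance| (bp)",
                    args.legend = list(x = "topright", cex = 0.7),
                    las = 2, cex.names = 0.7)
  manifest <- list(
    bins = summary$bins,
    counts = lapply(seq_len(nrow(h)), function(i)
      as.list(stats::setNames(unname(h[i, ]), colnames(h)))))
  names(manifest$counts) <- rownames(h)
  .write_manifest(manifest, out_path)
}

#' Two-set Venn plot of lncRNA calls
#'
#' Compares the noncoding transcript sets of two classifiers; region counts
#' are |A only|, |A and B|, |B only|.
#'
#' @param a,b `lnc_callset`s (from [combine_predictions()]) or plain
#'   character vectors of transcript ids.
#' @param out_path Image path.
#' @param labels Length-2 set labels; defaults to the callset tool names.
#' @return (invisibly) the manifest with labels and the three region counts.
#' @export
plot_lnc_venn <- function(a, b, out_path, labels = NULL) {
  ids_a <- if (inherits(a, "lnc_callset")) a$transcript_ids else
    unique(as.character(a))
  ids_b <- if (inherits(b, "lnc_callset")) b$transcript_ids else
    unique(as.character(b))
  if (is.null(labels))
    labels <- c(if (inherits(a, "lnc_callset")) a$tool else "A",
                if (inherits(b, "lnc_callset")) b$tool else "B")
  only_a <- length(setdiff(ids_a, ids_b))
  both <- length(intersect(ids_a, ids_b))
  only_b <- length(setdiff(ids_b, ids_a))
  .open_device(out_path, 6, 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = c(0, 10), ylim = c(0, 10), axes = FALSE,
                 xlab = "", ylab = "", asp = 1)
  graphics::symbols(c(4, 6), c(5, 5), circles = c(2.6, 2.6), inches = FALSE,
                    add = TRUE, fg = c("firebrick", "steelblue"))
  graphics::text(c(3, 5, 7), 5, c(only_a, both, only_b))
  graphics::text(c(3.2, 6.8), 8, labels, col = c("firebrick", "steelblue"))
  manifest <- list(labels = labels,
                   counts = list(only_a = only_a, intersection = both,
                                 only_b = only_b))
  .write_manifest(manifest, out_path)
}
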