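# Seeded synthetic-data generators. Every generator implants structures by
# construction (exon-template editing, planned TSS-feature offsets, catalog
# cloning) and writes both the standard-format files and a plain-text truth
# table, so every analysis operation can be checked against known ground
# truth without downloads. Identical seed + arguments give identical files.

.nb_support <- function(n, mu = 10, size = 5) {
  # negative-binomial long-read supports, shifted to >= 1 so isoform-usage
  # entropy is always defined
  stats::rnbinom(n, mu = mu, size = size) + 1L
}

# one 6-exon gene template at a given genomic offset
.gene_template <- function(start, exon_len, intron_len) {
  n <- 6L
  el <- sample(seq(exon_len[1], exon_len[2]), n, replace = TRUE)
  il <- sample(seq(intron_len[1], intron_len[2]), n - 1L, replace = TRUE)
  s <- integer(n); e <- integer(n)
  pos <- start
  for (i in seq_len(n)) {
    s[i] <- pos; e[i] <- pos + el[i]
    pos <- e[i] + if (i < n) il[i] else 0L
  }
  cbind(start = s, end = e)
}

# Variant exon chain + truth coordinates for one implanted event type.
# `ex` is the 6-exon template; the base transcript uses the chain relevant
# to the event (full chain except MX, which skips exon 4).
.implant_event <- function(type, ex, strand) {
  s <- ex[, "start"]; e <- ex[, "end"]
  shift <- 40L
  base <- ex
  if (type == "SE") {
    alt <- ex[-3L, ]
    coords <- c(e[2], s[3], e[3], s[4])
  } else if (type == "RI") {
    alt <- rbind(ex[1:2, ], c(s[3], e[4]), ex[5:6, ])
    coords <- c(s[3], e[3], s[4], e[4])
  } else if (type == "MX") {
    base <- ex[-4L, ]
    alt <- ex[-3L, ]
    coords <- c(e[2], s[3], e[3], s[4], e[4], s[5])
  } else if (type %in% c("A5", "A3")) {
    # shift the junction edge whose transcription-direction role matches the
    # requested type: donor side for A5 on "+", mirrored on "-"
    donor_side <- (type == "A5") == (strand == "+")
    alt <- ex
    if (donor_side) {
      alt[3L, "end"] <- e[3] - shift
      coords <- c(e[3] - shift, e[3], s[4])
    } else {
      alt[4L, "start"] <- s[4] + shift
      coords <- c(e[3], s[4], s[4] + shift)
    }
  } else if (type %in% c("AF", "AL")) {
    # swap in an alternative terminal exon inside the adjacent intron; the
    # genome-left end is the transcript 5' end only on "+"
    left_end <- (type == "AF") == (strand == "+")
    alt <- ex
    if (left_end) {
      ns <- e[1] + 60L; ne <- ns + 70L
      stopifnot(ne < s[2])                   # fits in intron 1
      alt[1L, ] <- c(ns, ne)
      coords <- c(s[1], e[1], ns, ne, s[2])
    } else {
      ns <- e[5] + 60L; ne <- ns + 70L
      stopifnot(ne < s[6])                   # fits in intron 5
      alt[6L, ] <- c(ns, ne)
      coords <- c(e[5], ns, ne, s[6], e[6])
    }
  } else stop("unknown event type in plan: ", type)
  colnames(alt) <- c("start", "end")
  list(base = base, alt = alt, coords = as.integer(coords))
}

#' Generate synthetic gene models with implanted splicing events
#'
#' Builds one gene per entry of `event_plan` from a 6-exon template. Genes
#' with a planned event type get two isoforms constructed by exon-template
#' editing (SE: drop an internal exon; RI: merge two exons; A5/A3: shift a
#' junction edge; MX: swap middle exons; AF/AL: swap a terminal exon), so
#' each such gene contains exactly the one implanted local event; `NA` plan
#' entries give single-isoform genes. Read supports are drawn from a shifted
#' negative binomial (mu 10, size 5, minimum 1). Output: a GTF with
#' `read_count` attributes and a tab-separated truth table listing every
#' implanted event with its type and defining coordinates.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seed + arguments give identical files.
#' @param event_plan Character vector of event types (`NA` = no event), one
#'   gene per entry. Default: one gene per each of the seven types.
#' @param exon_len,intron_len Integer ranges (min, max) for template
#'   geometry. Intron minimum must exceed 131 bp so alternative terminal
#'   exons fit.
#' @param chrom Chromosome name.
#' @param spacing Distance between consecutive gene starts (bp).
#' @return (invisibly) list with `transcripts`, `truth` (data frame:
#'   gene_id, event_type, chrom, strand, coordinates), and `paths`.
#' @export
generate_genes <- function(dir = tempfile("fixtures"), seed = 1L,
                           event_plan = c("SE", "A5", "A3", "MX", "RI",
                                          "AF", "AL"),
                           exon_len = c(80L, 200L),
                           intron_len = c(200L, 500L),
                           chrom = "chr1", spacing = 25000L) {
  stopifnot(intron_len[1] > 131L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  txs <- list(); truth <- list()
  for (gi in seq_along(event_plan)) {
    gid <- sprintf("G%03d", gi)
    strand <- sample(c("+", "-"), 1L)
    ex <- .gene_template(spacing * gi, exon_len, intron_len)
    type <- event_plan[gi]
    if (is.na(type)) {
      txs[[length(txs) + 1L]] <- transcript_model(
        paste0(gid, ".T1"), gid, chrom, strand, ex,
        read_support = .nb_support(1L))
      next
    }
    imp <- .implant_event(type, ex, strand)
    sup <- .nb_support(2L)
    txs[[length(txs) + 1L]] <- transcript_model(
      paste0(gid, ".T1"), gid, chrom, strand, imp$base, sup[1])
    txs[[length(txs) + 1L]] <- transcript_model(
      paste0(gid, ".T2"), gid, chrom, strand, imp$alt, sup[2])
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gid, event_type = type, chrom = chrom, strand = strand,
      coordinates = paste(imp$coords, collapse = "-"),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(gene_id = character(0), event_type = character(0),
                           chrom = character(0), strand = character(0),
                           coordinates = character(0))
  paths <- c(gtf = file.path(dir, "transcripts.gtf"),
             truth = file.path(dir, "truth_events.tsv"))
  write_gtf(txs, paths[["gtf"]])
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(transcripts = txs, truth = truth, paths = paths))
}

# generator-internal nearest-distance check: literal scan over all placed
# intervals with the downstream tie preference, independent of the distance
# module
.plan_check_distance <- function(tss, strand, iv) {
  gap <- ifelse(iv$start <= tss & tss < iv$end, 0L,
                pmin(abs(tss - (iv$end - 1L)), abs(tss - iv$start)))
  best <- which(gap == min(gap))
  goff <- ifelse(gap[best] == 0L, 0L,
                 ifelse(iv$start[best] > tss, iv$start[best] - tss,
                        (iv$end[best] - 1L) - tss))
  d <- if (strand == "+") goff else -goff
  if (length(d) > 1L) d <- max(d)   # downstream preferred on ties
  as.integer(d)
}

#' Generate feature tracks with planned TSS distances
#'
#' For each transcript and track, places one feature at a planned signed
#' distance from the transcript's TSS (sign in transcription direction:
#' negative = upstream), plus one decoy feature farther away than any
#' planned distance. After placement the generator re-derives every
#' transcript's nearest-feature distance by exhaustive scan; when a planned
#' distance is shadowed by another transcript's feature (isoforms of a gene
#' share or nearly share a TSS), the shadowed plan is re-placed at the
#' realized distance, for a bounded number of rounds, after which an error
#' is raised. The returned truth table always states the realized plan.
#'
#' @param transcripts List of `transcript_model` (typically from
#'   [generate_genes()]).
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param tracks Track names; defaults to CAGE plus the three histone marks.
#' @param planned Optional data frame (transcript_id, track, distance) of
#'   signed distances; by default sampled per transcript/track from
#'   `distance_pool`.
#' @param distance_pool Signed distances sampled when `planned` is `NULL`.
#' @param feature_width Width of placed features (bp).
#' @param decoy_offset Genomic offset of decoy features; must exceed the
#'   largest planned |distance|.
#' @return (invisibly) list with `tracks` (named list of [feature_track()]),
#'   `truth` (data frame transcript_id/track/distance) and `paths`.
#' @export
generate_tracks <- function(transcripts, dir = tempfile("fixtures"),
                            seed = 1L,
                            tracks = c("CAGE", "H3K4me1", "H3K4me3",
                                       "H3K27ac"),
                            planned = NULL,
                            distance_pool = c(0L, 50L, -120L, 200L, 800L,
                                              -900L, 1500L, -3000L, 5000L),
                            feature_width = 50L, decoy_offset = 8000L) {
  stopifnot(length(transcripts) >= 1L, decoy_offset > max(abs(distance_pool)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  tss <- vapply(transcripts, tss_of, integer(1))
  chrom <- vapply(transcripts, function(t) t$chrom, character(1))
  strand <- vapply(transcripts, function(t) t$strand, character(1))
  if (is.null(planned)) {
    # one draw per (gene, track): isoforms of a gene share (nearly) the same
    # TSS, so independent per-isoform plans would shadow each other
    genes <- vapply(transcripts, function(t) t$gene_id, character(1))
    planned <- expand.grid(transcript_id = ids, track = tracks,
                           stringsAsFactors = FALSE)
    key <- interaction(genes[match(planned$transcript_id, ids)],
                       planned$track, drop = TRUE)
    per_gene <- sample(distance_pool, nlevels(key), replace = TRUE)
    planned$distance <- per_gene[as.integer(key)]
  }
  place <- function(i, d) {
    g <- if (strand[i] == "+") d else -d
    if (d == 0L) {
      st <- tss[i] - 20L; en <- st + feature_width
    } else if (g > 0L) {
      st <- tss[i] + g; en <- st + feature_width
    } else {
      en <- tss[i] + g + 1L; st <- en - feature_width
    }
    c(st, en)
  }
  track_objs <- list(); paths <- character(0)
  max_tries <- 10L
  for (tr in tracks) {
    sel <- which(planned$track == tr)
    for (try in seq_len(max_tries)) {
      pl <- planned[sel, , drop = FALSE]
      rows <- list()
      for (r in seq_len(nrow(pl))) {
        i <- match(pl$transcript_id[r], ids)
        se <- place(i, pl$distance[r])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom[i], start = se[1], end = se[2], strand = ".",
          stringsAsFactors = FALSE)
        # decoy, always to the genome-right of the TSS
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom[i], start = tss[i] + decoy_offset,
          end = tss[i] + decoy_offset + feature_width, strand = ".",
          stringsAsFactors = FALSE)
      }
      iv <- unique(do.call(rbind, rows))
      collide <- integer(0)
      for (r in seq_len(nrow(pl))) {
        i <- match(pl$transcript_id[r], ids)
        got <- .plan_check_distance(tss[i], strand[i],
                                    iv[iv$chrom == chrom[i], , drop = FALSE])
        if (got != pl$distance[r]) collide <- c(collide, r)
      }
      if (length(collide) == 0L) break
      if (try == max_tries) {
        r <- collide[1]
        stop("planned distance for ", pl$transcript_id[r], " on track ", tr,
             " collides with another feature (planned ", pl$distance[r],
             "); respace the input genes or relax the plan")
      }
      # re-place: a colliding transcript's plan becomes the distance its TSS
      # actually realizes against the current layout; converges in a round
      # or two for overlapping isoforms
      for (r in collide) {
        i <- match(pl$transcript_id[r], ids)
        planned$distance[sel[r]] <- .plan_check_distance(
          tss[i], strand[i], iv[iv$chrom == chrom[i], , drop = FALSE])
      }
    }
    track_objs[[tr]] <- feature_track(tr, iv)
    p <- file.path(dir, paste0(tr, ".bed"))
    write_bed(track_objs[[tr]], p)
    paths[tr] <- p
  }
  truth <- planned[order(planned$track, planned$transcript_id), ]
  rownames(truth) <- NULL
  paths["truth"] <- file.path(dir, "truth_distances.tsv")
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(tracks = track_objs, truth = truth, paths = paths))
}

#' Generate synthetic lncRNA-analysis inputs
#'
#' Builds a reference catalog of multi-exon transcripts with tissue labels,
#' then a candidate set: `n_known` candidates cloned from catalog entries
#' with shifted terminal-exon extents (identical intron chains — what
#' ragged-ended long reads of a known lncRNA look like) and `n_novel`
#' candidates at fresh loci with unseen intron chains. Coding-potential
#' tables for two classifier dialects are written with planned calls
#' (concordant noncoding for most candidates, a discordant and a coding
#' minority). The truth table records verdicts, source entries, tissue
#' assignments and per-tool calls.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_known,n_novel Candidate counts.
#' @param tissues Tissue label vocabulary.
#' @param chrom Chromosome name.
#' @return (invisibly) list with `candidates`, `catalog` (list of
#'   [catalog_entry()]), `pred_a`/`pred_b` (prediction sets), `truth`, and
#'   `paths` (catalog GTF, tissue TSV, two prediction tables, truth TSV).
#' @export
generate_lnc_inputs <- function(dir = tempfile("fixtures"), seed = 1L,
                                n_known = 15L, n_novel = 15L,
                                tissues = c("liver", "brain", "heart"),
                                chrom = "chr2") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_catalog <- max(n_known, 12L)
  spacing <- 25000L
  cat_entries <- list()
  for (i in seq_len(n_catalog)) {
    strand <- sample(c("+", "-"), 1L)
    ex <- .gene_template(spacing * i, c(100L, 200L), c(200L, 400L))
    ex <- ex[seq_len(sample(3:5, 1L)), , drop = FALSE]
    # tissue plan: mostly single-tissue, some dual, some unannotated
    ts <- if (i %% 7L == 0L) character(0)
          else if (i %% 5L == 0L) sample(tissues, 2L)
          else sample(tissues, 1L)
    cat_entries[[i]] <- catalog_entry(
      transcript_model(sprintf("C%03d", i), sprintf("CG%03d", i), chrom,
                       strand, ex, read_support = .nb_support(1L)),
      tissues = ts)
  }
  candidates <- list(); truth <- list()
  for (i in seq_len(n_known)) {
    src <- cat_entries[[i]]
    ex <- src$transcript$exons
    ex[1L, "start"] <- max(0L, ex[1L, "start"] - 30L)
    ex[nrow(ex), "end"] <- ex[nrow(ex), "end"] + 40L
    id <- sprintf("cand%03d", i)
    candidates[[i]] <- transcript_model(id, id, chrom, src$transcript$strand,
                                        ex, read_support = .nb_support(1L))
    ts <- src$tissues
    truth[[i]] <- data.frame(
      transcript_id = id, verdict = "known",
      source_entry = src$transcript$transcript_id,
      tissues = paste(ts, collapse = ","),
      specific = if (length(ts) == 0L) "unassigned"
                 else if (length(ts) == 1L) ts else "multi",
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_novel)) {
    i <- n_known + j
    strand <- sample(c("+", "-"), 1L)
    ex <- .gene_template(spacing * (n_catalog + j + 1L), c(100L, 200L),
                         c(200L, 400L))
    ex <- ex[seq_len(sample(2:4, 1L)), , drop = FALSE]
    id <- sprintf("cand%03d", i)
    candidates[[i]] <- transcript_model(id, id, chrom, strand, ex,
                                        read_support = .nb_support(1L))
    truth[[i]] <- data.frame(transcript_id = id, verdict = "novel",
                             source_entry = "", tissues = "", specific = "",
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  # coding-potential plan: concordant noncoding majority, one-tool-only and
  # coding minorities
  n_cand <- nrow(truth)
  roll <- seq_len(n_cand) %% 10L
  truth$plek_call <- ifelse(roll == 1L, "coding", "noncoding")
  truth$cnci_call <- ifelse(roll %in% c(1L, 2L), "coding", "noncoding")
  truth$plek_call[roll == 3L] <- "coding"   # discordant the other way
  paths <- c(catalog = file.path(dir, "catalog.gtf"),
             tissues = file.path(dir, "tissues.tsv"),
             plek = file.path(dir, "plek.txt"),
             cnci = file.path(dir, "cnci.txt"),
             truth = file.path(dir, "truth_lnc.tsv"))
  write_gtf(lapply(cat_entries, function(e) e$transcript), paths[["catalog"]])
  writeLines(vapply(cat_entries, function(e)
    sprintf("%s\t%s", e$transcript$transcript_id,
            paste(e$tissues, collapse = ",")), character(1)),
    paths[["tissues"]])
  writeLines(sprintf("%s\t%.4f\t%s",
                     ifelse(truth$plek_call == "coding", "Coding",
                            "Non-coding"),
                     stats::runif(n_cand), truth$transcript_id),
             paths[["plek"]])
  writeLines(c("Transcript ID\tindex\tscore",
               sprintf("%s\t%s\t%.4f", truth$transcript_id, truth$cnci_call,
                       stats::runif(n_cand, -1, 1))),
             paths[["cnci"]])
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pred_a <- structure(list(tool_name = "plek",
                           calls = stats::setNames(truth$plek_call,
                                                   truth$transcript_id),
                           score = NULL), class = "prediction_set")
  pred_b <- structure(list(tool_name = "cnci",
                           calls = stats::setNames(truth$cnci_call,
                                                   truth$transcript_id),
                           score = NULL), class = "prediction_set")
  invisible(list(candidates = candidates, catalog = cat_entries,
                 pred_a = pred_a, pred_b = pred_b, truth = truth,
                 paths = paths))
}

#' Generate a synthetic gene-to-GO annotation map
#'
#' Disjoint or overlapping random term memberships over a synthetic gene
#' universe; used by tests and the null-calibration analysis of
#' [go_enrich()].
#'
#' @param seed Integer seed.
#' @param n_genes Background size.
#' @param n_terms Number of terms.
#' @param term_size Range (min, max) of genes per term.
#' @return An `annotation_map`.
#' @export
generate_annotation <- function(seed = 1L, n_genes = 50L, n_terms = 10L,
                                term_size = c(5L, 10L)) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  terms <- lapply(seq_len(n_terms), function(i)
    sort(sample(genes, sample(seq(term_size[1], term_size[2]), 1L))))
  names(terms) <- sprintf("GO:%07d", seq_len(n_terms))
  structure(list(terms = terms,
                 term_names = stats::setNames(
                   sprintf("synthetic term %d", seq_len(n_terms)),
                   names(terms)),
                 background = genes),
            class = "annotation_map")
}
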