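# Local alternative-splicing event classification from transcript models,
# per-sample event count tables, the chi-squared profile comparison, and the
# entropy-based isoform-diversity score used to rank differentially spliced
# genes.
#
# Event definitions follow the local-event scheme standard in the field
# (seven types: SE, A5, A3, MX, RI, AF, AL). All coordinates below are on
# the "+" genome axis; A5/A3 and AF/AL semantics flip with strand.

#' Group transcripts by gene
#'
#' Partitions a transcript list by `gene_id` and verifies that every gene's
#' transcripts share one chromosome and strand. Genes with fewer than two
#' transcripts are flagged event-free (no local event can be defined).
#'
#' @param transcripts List of `transcript_model`.
#' @return Named list (sorted by gene_id) of gene groups, each a list with
#'   `gene_id`, `chrom`, `strand`, `transcripts`, `event_free`.
#' @export
group_by_gene <- function(transcripts) {
  gid <- vapply(transcripts, function(t) t$gene_id, character(1))
  out <- lapply(sort(unique(gid)), function(g) {
    txs <- transcripts[gid == g]
    chrom <- unique(vapply(txs, function(t) t$chrom, character(1)))
    strand <- unique(vapply(txs, function(t) t$strand, character(1)))
    if (length(chrom) > 1L || length(strand) > 1L)
      stop("gene ", g, " has transcripts on multiple chromosomes/strands")
    list(gene_id = g, chrom = chrom, strand = strand, transcripts = txs,
         event_free = length(txs) < 2L)
  })
  names(out) <- vapply(out, function(g) g$gene_id, character(1))
  out
}

# Events found between one ordered transcript pair (a = "first" role).
# Returns a list of partial events: list(type, coords, inc, exc).
.pair_events <- function(a, b, strand) {
  ev <- list()
  add <- function(type, coords, inc, exc)
    ev[[length(ev) + 1L]] <<- list(type = type, coords = as.integer(coords),
                                   inc = inc, exc = exc)
  exa <- a$exons; exb <- b$exons
  ia <- tx_introns(a); ib <- tx_introns(b)
  ib_key <- paste(ib[, 1], ib[, 2])

  # SE: a carries the cassette (consecutive introns (e1,s2),(e2,s3)); b has
  # the direct junction e1->s3.
  if (nrow(ia) >= 2L && nrow(ib) >= 1L) {
    for (k in seq_len(nrow(ia) - 1L)) {
      e1 <- ia[k, 1]; s2 <- ia[k, 2]; e2 <- ia[k + 1L, 1]; s3 <- ia[k + 1L, 2]
      if (paste(e1, s3) %in% ib_key)
        add("SE", c(e1, s2, e2, s3), a$transcript_id, b$transcript_id)
    }
  }

  # RI: a splices an intron whose flanking exons' outer bounds are matched
  # exactly by a single exon of b (the retaining path).
  if (nrow(ia) >= 1L) {
    for (k in seq_len(nrow(ia))) {
      s1 <- exa[k, "start"]; e1 <- ia[k, 1]; s2 <- ia[k, 2]
      e2 <- exa[k + 1L, "end"]
      hit <- exb[, "start"] == s1 & exb[, "end"] == e2
      if (any(hit))
        add("RI", c(s1, e1, s2, e2), b$transcript_id, a$transcript_id)
    }
  }

  # A5/A3: junction pairs sharing one boundary; the exons carrying the
  # differing boundary must overlap (otherwise the variation is a distinct
  # exon, handled by SE/MX/AF/AL). Inclusion = shorter-intron path.
  if (nrow(ia) >= 1L && nrow(ib) >= 1L) {
    for (k in seq_len(nrow(ia))) for (m in seq_len(nrow(ib))) {
      la <- ia[k, 1]; ra <- ia[k, 2]; lb <- ib[m, 1]; rb <- ib[m, 2]
      if (ra == rb && la != lb) {
        sa <- exa[k, "start"]; sb <- exb[m, "start"]
        if (sa < lb && sb < la) {            # donor-side exons overlap
          type <- if (strand == "+") "A5" else "A3"
          inc <- if (la > lb) a$transcript_id else b$transcript_id
          exc <- if (la > lb) b$transcript_id else a$transcript_id
          add(type, c(min(la, lb), max(la, lb), ra), inc, exc)
        }
      }
      if (la == lb && ra != rb) {
        ea <- exa[k + 1L, "end"]; eb <- exb[m + 1L, "end"]
        if (ra < eb && rb < ea) {            # acceptor-side exons overlap
          type <- if (strand == "+") "A3" else "A5"
          inc <- if (ra < rb) a$transcript_id else b$transcript_id
          exc <- if (ra < rb) b$transcript_id else a$transcript_id
          add(type, c(la, min(ra, rb), max(ra, rb)), inc, exc)
        }
      }
    }
  }

  # MX: consecutive intron pairs sharing both outer flanks, with distinct,
  # non-overlapping middle exons. Inclusion = genome-left middle exon path.
  if (nrow(ia) >= 2L && nrow(ib) >= 2L) {
    for (k in seq_len(nrow(ia) - 1L)) for (m in seq_len(nrow(ib) - 1L)) {
      e1 <- ia[k, 1]; s4 <- ia[k + 1L, 2]
      if (ib[m, 1] != e1 || ib[m + 1L, 2] != s4) next
      mid_a <- c(ia[k, 2], ia[k + 1L, 1])    # (s2, e2)
      mid_b <- c(ib[m, 2], ib[m + 1L, 1])    # (s3, e3)
      if (identical(mid_a, mid_b)) next
      if (mid_a[2] < mid_b[1]) {
        add("MX", c(e1, mid_a, mid_b, s4), a$transcript_id, b$transcript_id)
      } else if (mid_b[2] < mid_a[1]) {
        add("MX", c(e1, mid_b, mid_a, s4), b$transcript_id, a$transcript_id)
      }
    }
  }

  # Terminal-exon events: genome-left terminal variation is AF on "+" / AL
  # on "-", genome-right is the mirror. Alternative terminal exons must be
  # non-overlapping and splice to/from the same inner boundary. Inclusion =
  # outermost terminal exon path.
  if (nrow(ia) >= 1L && nrow(ib) >= 1L) {
    fa <- exa[1L, ]; fb <- exb[1L, ]
    if (ia[1L, 2] == ib[1L, 2] &&
        (fa["end"] <= fb["start"] || fb["end"] <= fa["start"])) {
      type <- if (strand == "+") "AF" else "AL"
      left_first <- fa["start"] < fb["start"]
      pair <- if (left_first) c(fa, fb) else c(fb, fa)
      inc <- if (left_first) a$transcript_id else b$transcript_id
      exc <- if (left_first) b$transcript_id else a$transcript_id
      add(type, c(pair, ia[1L, 2]), inc, exc)
    }
    la_ <- exa[nrow(exa), ]; lb_ <- exb[nrow(exb), ]
    if (ia[nrow(ia), 1] == ib[nrow(ib), 1] &&
        (la_["end"] <= lb_["start"] || lb_["end"] <= la_["start"])) {
      type <- if (strand == "+") "AL" else "AF"
      right_last <- la_["start"] > lb_["start"]
      pair <- if (right_last) c(lb_, la_) else c(la_, lb_)
      inc <- if (right_last) a$transcript_id else b$transcript_id
      exc <- if (right_last) b$transcript_id else a$transcript_id
      add(type, c(ia[nrow(ia), 1], pair), inc, exc)
    }
  }
  ev
}

#' Classify local alternative-splicing events within a gene
#'
#' Enumerates all distinct local events over all transcript pairs of one
#' gene, deduplicated by canonical event id. The seven types:
#' \describe{
#'   \item{SE}{skipped exon: a cassette exon between shared flanking splice
#'     sites, versus the direct junction.}
#'   \item{RI}{retained intron: a single exon spanning what another isoform
#'     splices as two exons with the same outer bounds.}
#'   \item{A5/A3}{alternative 5'/3' splice site: two junctions sharing one
#'     boundary, the varying boundary lying inside overlapping exons; the
#'     label follows transcription direction.}
#'   \item{MX}{mutually exclusive exons: two non-overlapping middle exons,
#'     each joined to the same outer flanks.}
#'   \item{AF/AL}{alternative first/last exon: non-overlapping terminal
#'     exons splicing to the same inner boundary.}
#' }
#' When the same coordinates arise from several transcript pairs the event
#' counts once and the inclusion/exclusion sets are unions over supporting
#' pairs. Inclusion is the variant retaining more exonic sequence (cassette,
#' intron-retaining, shorter-intron path) or, for MX/AF/AL, a fixed
#' coordinate-based orientation; event type and coordinates never depend on
#' this labeling.
#'
#' @param gene A gene group from [group_by_gene()], or a plain list of
#'   `transcript_model`s from one gene.
#' @return List of `as_event` objects, sorted by `event_id`; each has
#'   `event_id`, `type`, `gene_id`, `chrom`, `strand`, `coordinates`
#'   (integer vector), `inclusion`, `exclusion` (disjoint transcript-id
#'   sets). Empty list when no event is found.
#' @examples
#' t1 <- transcript_model("T1", "G", "chr1", "+",
#'                        cbind(c(100, 300, 500), c(200, 400, 600)))
#' t2 <- transcript_model("T2", "G", "chr1", "+",
#'                        cbind(c(100, 500), c(200, 600)))
#' detect_events(list(t1, t2))  # one SE event at (200, 300, 400, 500)
#' @export
detect_events <- function(gene) {
  if (is.list(gene) && !is.null(gene$transcripts)) {
    txs <- gene$transcripts
  } else {
    txs <- gene
    g <- unique(vapply(txs, function(t) t$gene_id, character(1)))
    if (length(g) > 1L) stop("transcripts belong to multiple genes")
    chrom <- unique(vapply(txs, function(t) t$chrom, character(1)))
    strand <- unique(vapply(txs, function(t) t$strand, character(1)))
    if (length(chrom) > 1L || length(strand) > 1L)
      stop("gene ", g, " has transcripts on multiple chromosomes/strands")
  }
  if (length(txs) < 2L) return(list())
  gene_id <- txs[[1]]$gene_id
  chrom <- txs[[1]]$chrom
  strand <- txs[[1]]$strand
  # drop structurally duplicated transcript entries (same id): idempotence
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  txs <- txs[!duplicated(ids)]
  acc <- new.env(parent = emptyenv())
  n <- length(txs)
  # both orderings: SE/RI assign fixed roles to the first transcript, and
  # the symmetric detectors deduplicate via event_id
  pairs <- which(outer(seq_len(n), seq_len(n), "!="), arr.ind = TRUE)
  for (pr in seq_len(nrow(pairs))) {
    i <- pairs[pr, 1L]; j <- pairs[pr, 2L]
    for (e in .pair_events(txs[[i]], txs[[j]], strand)) {
      id <- sprintf("%s;%s:%s:%s:%s", gene_id, e$type, chrom,
                    paste(e$coords, collapse = "-"), strand)
      if (is.null(acc[[id]])) {
        acc[[id]] <- list(event_id = id, type = e$type, gene_id = gene_id,
                          chrom = chrom, strand = strand,
                          coordinates = e$coords,
                          inclusion = e$inc, exclusion = e$exc)
      } else {
        acc[[id]]$inclusion <- sort(unique(c(acc[[id]]$inclusion, e$inc)))
        acc[[id]]$exclusion <- sort(unique(c(acc[[id]]$exclusion, e$exc)))
      }
    }
  }
  out <- lapply(sort(ls(acc)), function(k) {
    e <- acc[[k]]
    e$inclusion <- sort(unique(e$inclusion))
    e$exclusion <- sort(unique(e$exclusion))
    structure(e, class = "as_event")
  })
  out
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("<as_event> %s  inclusion: %s | exclusion: %s\n", x$event_id,
              paste(x$inclusion, collapse = ","),
              paste(x$exclusion, collapse = ",")))
  invisible(x)
}

#' Flatten a list of events to a data frame
#'
#' @param events List of `as_event`.
#' @return Data frame with event_id, type, gene_id, chrom, strand,
#'   coordinates (dash-joined), inclusion, exclusion (semicolon-joined).
#' @export
events_to_df <- function(events) {
  if (length(events) == 0L)
    return(data.frame(event_id = character(0), type = character(0),
                      gene_id = character(0), chrom = character(0),
                      strand = character(0), coordinates = character(0),
                      inclusion = character(0), exclusion = character(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(event_id = e$event_id, type = e$type, gene_id = e$gene_id,
               chrom = e$chrom, strand = e$strand,
               coordinates = paste(e$coordinates, collapse = "-"),
               inclusion = paste(e$inclusion, collapse = ";"),
               exclusion = paste(e$exclusion, collapse = ";"),
               stringsAsFactors = FALSE)))
}

#' The fixed event-type order used in tables and plots
#' @return `c("A3","A5","AF","AL","MX","RI","SE")` (alphabetical, for
#'   cross-run comparability).
#' @export
as_event_types <- function() c("A3", "A5", "AF", "AL", "MX", "RI", "SE")

#' Count splicing events per sample
#'
#' Runs [detect_events()] over every gene of every sample and tabulates the
#' number of distinct events per type (distinct by canonical event id, so
#' duplicated transcript entries do not inflate counts).
#'
#' @param samples List of [sample_transcriptome()]s.
#' @return Object of class `as_count_table`: `counts`, a samples x 7 integer
#'   matrix with columns in [as_event_types()] order.
#' @export
count_events <- function(samples) {
  stopifnot(length(samples) >= 1L)
  types <- as_event_types()
  counts <- t(vapply(samples, function(s) {
    evs <- unlist(lapply(group_by_gene(s$transcripts), detect_events),
                  recursive = FALSE)
    tab <- table(factor(vapply(evs, function(e) e$type, character(1)),
                        levels = types))
    as.integer(tab)
  }, integer(length(types))))
  dimnames(counts) <- list(vapply(samples, function(s) s$sample_id,
                                  character(1)), types)
  as_count_table(counts)
}

#' Construct an AS count table from a matrix
#'
#' @param counts Non-negative integer matrix, samples in rows, event types
#'   in columns.
#' @return Object of class `as_count_table`.
#' @export
as_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts), class = "as_count_table")
}

#' Row-normalized event-type proportions
#' @param x An `as_count_table`.
#' @return Matrix of per-sample proportions (rows sum to 1; `NaN` for
#'   all-zero rows).
#' @export
as_proportions <- function(x) {
  stopifnot(inherits(x, "as_count_table"))
  sweep(x$counts, 1L, rowSums(x$counts), "/")
}

#' @export
print.as_count_table <- function(x, ...) {
  cat("<as_count_table>", nrow(x$counts), "sample(s)\n")
  print(x$counts)
  invisible(x)
}

#' Chi-squared comparison of splicing profiles across samples
#'
#' Pearson chi-squared test of homogeneity on the samples x event-types
#' contingency table, without continuity correction. Event types whose total
#' count is zero are dropped before testing (they carry no information and
#' would give zero expected counts); samples with zero total are dropped
#' likewise. A small p-value indicates that the composition of splicing
#' event types differs among samples.
#'
#' @param table An `as_count_table` or a plain count matrix.
#' @return Object of class `as_chisq_test`: `chi2`, `dof`, `p`,
#'   `dropped_types`, `dropped_samples`.
#' @examples
#' compare_as_profiles(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
compare_as_profiles <- function(table) {
  m <- if (inherits(table, "as_count_table")) table$counts else as.matrix(table)
  if (nrow(m) < 2L) stop("degenerate table: need at least 2 samples")
  if (sum(m) <= 0) stop("degenerate table: total count is zero")
  drop_s <- rowSums(m) == 0
  drop_t <- colSums(m) == 0
  m2 <- m[!drop_s, !drop_t, drop = FALSE]
  if (nrow(m2) < 2L || ncol(m2) < 2L)
    stop("degenerate table: fewer than 2 non-empty rows or retained columns")
  ht <- suppressWarnings(stats::chisq.test(m2, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic),
                 dof = as.integer(unname(ht$parameter)),
                 p = unname(ht$p.value),
                 dropped_types = colnames(m)[drop_t],
                 dropped_samples = rownames(m)[drop_s]),
            class = "as_chisq_test")
}

#' @export
print.as_chisq_test <- function(x, ...) {
  cat(sprintf("<as_chisq_test> X-squared = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$dof, x$p))
  invisible(x)
}

#' Isoform diversity score of a gene in one sample
#'
#' Shannon entropy (base 2) of the isoform-usage distribution: with
#' `p_i = read_support_i / sum(read_support)` over the gene's isoforms,
#' `score = -sum(p_i log2 p_i)`, zero-support isoforms excluded. The score
#' is 0 when a single isoform carries all reads and reaches `log2(n)` when
#' `n` isoforms are used uniformly, so it quantifies how evenly a sample
#' spreads expression across a gene's isoforms.
#'
#' @param gene A gene group from [group_by_gene()] or a list of
#'   `transcript_model`s from one gene (one sample's models).
#' @param sample_id Optional sample label recorded in the result.
#' @return One-row data frame: gene_id, sample_id, score (bits), n_isoforms
#'   (isoforms with nonzero support).
#' @export
diversity_score <- function(gene, sample_id = NA_character_) {
  txs <- if (is.list(gene) && !is.null(gene$transcripts)) gene$transcripts
         else gene
  stopifnot(length(txs) >= 1L)
  gid <- unique(vapply(txs, function(t) t$gene_id, character(1)))
  if (length(gid) > 1L) stop("transcripts belong to multiple genes")
  sup <- vapply(txs, function(t) t$read_support, integer(1))
  sup <- sup[sup > 0L]
  if (length(sup) == 0L) stop("no expressed isoform in gene ", gid)
  p <- sup / sum(sup)
  score <- -sum(p * log2(p))
  data.frame(gene_id = gid, sample_id = sample_id, score = score,
             n_isoforms = length(sup), stringsAsFactors = FALSE)
}

#' Diversity scores for all genes of a sample
#'
#' @param sample A [sample_transcriptome()].
#' @return Data frame (one row per gene): gene_id, sample_id, score,
#'   n_isoforms.
#' @export
diversity_scores <- function(sample) {
  stopifnot(inherits(sample, "sample_transcriptome"))
  groups <- group_by_gene(sample$transcripts)
  do.call(rbind, lapply(groups, diversity_score, sample_id = sample$sample_id))
}

#' Per-gene diversity-score difference between two samples
#'
#' For each gene, `D = |score_a - score_b|` between the two samples'
#' diversity scores. Genes present in only one sample are scored 0 in the
#' other and flagged `one_sample_only` so they can be excluded. The result
#' is sorted descending by D (ties broken by gene_id) and feeds
#' [top_spliced_genes()].
#'
#' @param scores_a,scores_b Data frames from [diversity_scores()].
#' @return Data frame of class `score_d`: gene_id, sample_a, sample_b,
#'   score_a, score_b, D, one_sample_only.
#' @export
score_d <- function(scores_a, scores_b) {
  sa <- scores_a[, c("gene_id", "score")]; names(sa)[2] <- "score_a"
  sb <- scores_b[, c("gene_id", "score")]; names(sb)[2] <- "score_b"
  m <- merge(sa, sb, by = "gene_id", all = TRUE)
  m$one_sample_only <- is.na(m$score_a) | is.na(m$score_b)
  m$score_a[is.na(m$score_a)] <- 0
  m$score_b[is.na(m$score_b)] <- 0
  m$D <- abs(m$score_a - m$score_b)
  m$sample_a <- scores_a$sample_id[1]
  m$sample_b <- scores_b$sample_id[1]
  m <- m[order(-m$D, m$gene_id), c("gene_id", "sample_a", "sample_b",
                                   "score_a", "score_b", "D",
                                   "one_sample_only")]
  rownames(m) <- NULL
  class(m) <- c("score_d", "data.frame")
  m
}

#' Select the most differentially spliced genes
#'
#' @param records A `score_d` data frame (sorted descending by D).
#' @param k Top-k cutoff (mutually exclusive with `min_d`).
#' @param min_d Keep all genes with `D >= min_d` (so `min_d = 0` returns
#'   every gene, including ties at zero).
#' @return Character vector of gene ids.
#' @export
top_spliced_genes <- function(records, k = NULL, min_d = NULL) {
  if (is.null(k) == is.null(min_d))
    stop("supply exactly one of k or min_d")
  if (!is.null(k)) {
    if (k <= 0) stop("k must be a positive integer")
    return(utils::head(records$gene_id, k))
  }
  if (min_d < 0) stop("min_d must be non-negative")
  records$gene_id[records$D >= min_d]
}
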