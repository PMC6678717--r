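# Independent brute-force oracles. These re-derive the expected answers by
# literal exhaustive scans over the definitions, sharing no code with the
# package internals they check.

# signed TSS-to-nearest-feature distance by linear scan over every interval
oracle_nearest <- function(tss, chrom, strand, track) {
  iv <- track$intervals
  iv <- iv[iv$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(NA_integer_)
  best_abs <- Inf; best_signed <- NA_integer_
  for (r in seq_len(nrow(iv))) {
    s <- iv$start[r]; e <- iv$end[r]
    if (s <= tss && tss < e) {
      gap <- 0L; goff <- 0L
    } else {
      gap <- min(abs(tss - (e - 1L)), abs(tss - s))
      goff <- if (s > tss) s - tss else (e - 1L) - tss
    }
    signed <- if (strand == "+") goff else -goff
    if (gap < best_abs || (gap == best_abs && signed > best_signed)) {
      best_abs <- gap; best_signed <- signed
    }
  }
  as.integer(best_signed)
}

# exhaustive pairwise event enumeration straight from the local-event
# definitions; returns sorted "TYPE:coords" keys
oracle_events <- function(txs) {
  strand <- txs[[1]]$strand
  keys <- character(0)
  chains <- lapply(txs, function(t) t$exons)
  jn <- lapply(chains, function(ex) {
    if (nrow(ex) < 2L) return(matrix(integer(0), ncol = 2L))
    cbind(ex[-nrow(ex), 2L], ex[-1L, 1L])
  })
  n <- length(txs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    exA <- chains[[i]]; exB <- chains[[j]]
    jA <- jn[[i]]; jB <- jn[[j]]
    has_junction <- function(J, l, r)
      any(J[, 1L] == l & J[, 2L] == r)
    # SE: cassette exon in A between an exclusion junction of B
    if (nrow(exA) >= 3L) for (k in 2L:(nrow(exA) - 1L)) {
      e1 <- exA[k - 1L, 2L]; s2 <- exA[k, 1L]; e2 <- exA[k, 2L]
      s3 <- exA[k + 1L, 1L]
      if (has_junction(jA, e1, s2) && has_junction(jA, e2, s3) &&
          has_junction(jB, e1, s3))
        keys <- c(keys, paste0("SE:", paste(c(e1, s2, e2, s3),
                                            collapse = "-")))
    }
    # RI: spanning exon of B over a spliced intron of A
    if (nrow(jA) >= 1L) for (k in seq_len(nrow(jA))) {
      s1 <- exA[k, 1L]; e1 <- jA[k, 1L]; s2 <- jA[k, 2L]; e2 <- exA[k + 1L, 2L]
      if (any(exB[, 1L] == s1 & exB[, 2L] == e2))
        keys <- c(keys, paste0("RI:", paste(c(s1, e1, s2, e2),
                                            collapse = "-")))
    }
    # A5/A3: junctions sharing one boundary, variable boundary inside
    # overlapping exons
    if (nrow(jA) >= 1L && nrow(jB) >= 1L)
      for (ka in seq_len(nrow(jA))) for (kb in seq_len(nrow(jB))) {
        la <- jA[ka, 1L]; ra <- jA[ka, 2L]
        lb <- jB[kb, 1L]; rb <- jB[kb, 2L]
        if (ra == rb && la != lb &&
            exA[ka, 1L] < lb && exB[kb, 1L] < la) {
          type <- if (strand == "+") "A5" else "A3"
          keys <- c(keys, paste0(type, ":", paste(c(min(la, lb), max(la, lb),
                                                    ra), collapse = "-")))
        }
        if (la == lb && ra != rb &&
            ra < exB[kb + 1L, 2L] && rb < exA[ka + 1L, 2L]) {
          type <- if (strand == "+") "A3" else "A5"
          keys <- c(keys, paste0(type, ":", paste(c(la, min(ra, rb),
                                                    max(ra, rb)),
                                                  collapse = "-")))
        }
      }
    # MX: middle exons joined to common flanks, non-overlapping, A's left
    if (nrow(exA) >= 3L && nrow(exB) >= 3L)
      for (ka in 2L:(nrow(exA) - 1L)) for (kb in 2L:(nrow(exB) - 1L)) {
        e1 <- exA[ka - 1L, 2L]; s4 <- exA[ka + 1L, 1L]
        if (exB[kb - 1L, 2L] != e1 || exB[kb + 1L, 1L] != s4) next
        s2 <- exA[ka, 1L]; e2 <- exA[ka, 2L]
        s3 <- exB[kb, 1L]; e3 <- exB[kb, 2L]
        if (e2 < s3)
          keys <- c(keys, paste0("MX:", paste(c(e1, s2, e2, s3, e3, s4),
                                              collapse = "-")))
      }
    # AF/AL: non-overlapping terminal exons sharing the inner boundary
    if (nrow(jA) >= 1L && nrow(jB) >= 1L) {
      fA <- exA[1L, ]; fB <- exB[1L, ]
      if (jA[1L, 2L] == jB[1L, 2L] &&
          (fA[2L] <= fB[1L] || fB[2L] <= fA[1L])) {
        type <- if (strand == "+") "AF" else "AL"
        pr <- if (fA[1L] < fB[1L]) c(fA, fB) else c(fB, fA)
        keys <- c(keys, paste0(type, ":", paste(c(pr, jA[1L, 2L]),
                                                collapse = "-")))
      }
      lA <- exA[nrow(exA), ]; lB <- exB[nrow(exB), ]
      if (jA[nrow(jA), 1L] == jB[nrow(jB), 1L] &&
          (lA[2L] <= lB[1L] || lB[2L] <= lA[1L])) {
        type <- if (strand == "+") "AL" else "AF"
        pr <- if (lA[1L] < lB[1L]) c(lA, lB) else c(lB, lA)
        keys <- c(keys, paste0(type, ":", paste(c(jA[nrow(jA), 1L], pr),
                                                collapse = "-")))
      }
    }
  }
  sort(unique(keys))
}

# all exon-chain structures drawn from an n-exon template: every non-empty
# subset, plus variants merging one template-adjacent chosen pair (a
# retained intron)
template_structures <- function(template) {
  n <- nrow(template)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ex <- template[idx, , drop = FALSE]
    out[[length(out) + 1L]] <- ex
    adj <- which(diff(idx) == 1L)
    for (a in adj) {
      m <- ex
      m[a, 2L] <- m[a + 1L, 2L]
      out[[length(out) + 1L]] <- m[-(a + 1L), , drop = FALSE]
    }
  }
  out
}

# exhaustive hypergeometric upper tail by enumerating every draw (small N)
oracle_hyper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
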