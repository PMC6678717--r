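test_that("gene grouping partitions transcripts and flags event-free genes", {
  txs <- c(lapply(1:3, function(i)
             mk_tx(paste0("A", i), list(c(100, 200)), gene = "G1")),
           lapply(1:2, function(i)
             mk_tx(paste0("B", i), list(c(100, 200)), gene = "G2")),
           list(mk_tx("C1", list(c(100, 200)), gene = "G3")))
  g <- group_by_gene(txs)
  expect_identical(lengths(lapply(g, `[[`, "transcripts")),
                   c(G1 = 3L, G2 = 2L, G3 = 1L))
  expect_false(g$G1$event_free)
  expect_true(g$G3$event_free)

  bad <- list(mk_tx("X1", list(c(1, 10)), gene = "G", chrom = "chr1"),
              mk_tx("X2", list(c(1, 10)), gene = "G", chrom = "chr2"))
  expect_error(group_by_gene(bad), "G")
})

test_that("forced SE and RI configurations are classified with exact coordinates", {
  t1 <- mk_tx("T1", list(c(100, 200), c(300, 400), c(500, 600)))
  t2 <- mk_tx("T2", list(c(100, 200), c(500, 600)))
  ev <- detect_events(list(t1, t2))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$type, "SE")
  expect_identical(ev[[1]]$coordinates, c(200L, 300L, 400L, 500L))
  expect_identical(ev[[1]]$inclusion, "T1")
  expect_identical(ev[[1]]$exclusion, "T2")

  r1 <- mk_tx("T1", list(c(100, 400)))
  r2 <- mk_tx("T2", list(c(100, 200), c(300, 400)))
  evr <- detect_events(list(r1, r2))
  expect_length(evr, 1L)
  expect_identical(evr[[1]]$type, "RI")
  expect_identical(evr[[1]]$coordinates, c(100L, 200L, 300L, 400L))
})

test_that("alternative splice-site and terminal-exon labels follow strand", {
  a <- list(c(100, 200), c(300, 400))
  b <- list(c(100, 180), c(300, 400))   # donor (left) boundary varies
  ev_p <- detect_events(list(mk_tx("T1", a, "+"), mk_tx("T2", b, "+")))
  ev_m <- detect_events(list(mk_tx("T1", a, "-"), mk_tx("T2", b, "-")))
  expect_identical(vapply(ev_p, `[[`, character(1), "type"), "A5")
  expect_identical(vapply(ev_m, `[[`, character(1), "type"), "A3")
  expect_identical(ev_p[[1]]$coordinates, c(180L, 200L, 300L))

  f1 <- list(c(100, 150), c(500, 600))
  f2 <- list(c(300, 380), c(500, 600))  # different non-overlapping first exon
  af_p <- detect_events(list(mk_tx("T1", f1, "+"), mk_tx("T2", f2, "+")))
  af_m <- detect_events(list(mk_tx("T1", f1, "-"), mk_tx("T2", f2, "-")))
  expect_identical(vapply(af_p, `[[`, character(1), "type"), "AF")
  expect_identical(vapply(af_m, `[[`, character(1), "type"), "AL")
})

test_that("mutually exclusive exons require shared flanks and disjoint middles", {
  t1 <- mk_tx("T1", list(c(100, 200), c(300, 400), c(700, 800)))
  t2 <- mk_tx("T2", list(c(100, 200), c(500, 600), c(700, 800)))
  ev <- detect_events(list(t1, t2))
  expect_identical(vapply(ev, `[[`, character(1), "type"), "MX")
  expect_identical(ev[[1]]$coordinates, c(200L, 300L, 400L, 500L, 600L, 700L))
  # overlapping middles are not mutually exclusive: the shifted boundaries
  # classify as alternative splice sites instead
  t3 <- mk_tx("T3", list(c(100, 200), c(350, 450), c(700, 800)))
  ev_ov <- detect_events(list(t1, t3))
  expect_setequal(vapply(ev_ov, `[[`, character(1), "type"), c("A3", "A5"))
})

test_that("event detection is order-invariant, idempotent under duplication and strand-consistent", {
  fx <- generate_genes(withr::local_tempdir(), seed = 13)
  groups <- group_by_gene(fx$transcripts)
  for (g in groups) {
    base <- event_key(detect_events(g))
    perm <- g
    perm$transcripts <- rev(g$transcripts)
    expect_identical(event_key(detect_events(perm)), base)
    dup <- g
    dup$transcripts <- c(g$transcripts, g$transcripts[1])
    expect_identical(event_key(detect_events(dup)), base)
  }

  # mirroring coordinates and flipping strand swaps A5<->A3 and AF<->AL and
  # fixes SE/RI/MX
  mirror <- function(t, M = 1e6) {
    ex <- cbind(start = M - rev(t$exons[, "end"]),
                end = M - rev(t$exons[, "start"]))
    transcript_model(t$transcript_id, t$gene_id, t$chrom,
                     if (t$strand == "+") "-" else "+", ex, t$read_support)
  }
  swap <- c(SE = "SE", RI = "RI", MX = "MX", A5 = "A3", A3 = "A5",
            AF = "AL", AL = "AF")
  for (g in groups) {
    types <- sort(vapply(detect_events(g), `[[`, character(1), "type"))
    m_types <- sort(unname(swap[vapply(detect_events(lapply(g$transcripts,
                                                            mirror)),
                                       `[[`, character(1), "type")]))
    expect_identical(sort(unname(swap[types])), m_types)
  }
})

test_that("event detection matches the brute-force enumerator on template genes", {
  template <- cbind(start = c(0, 300, 600, 900) + 1000L,
                    end = c(150, 450, 750, 1050) + 1000L)
  structs <- template_structures(template)
  n_checked <- 0L
  for (i in seq_along(structs)) for (j in seq_along(structs)) {
    if (i >= j) next
    for (strand in c("+", "-")) {
      txs <- list(mk_tx("T1", structs[[i]], strand),
                  mk_tx("T2", structs[[j]], strand))
      expect_identical(event_key(detect_events(txs)), oracle_events(txs))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("event counting tabulates distinct events per type and sample", {
  fx <- generate_genes(withr::local_tempdir(), seed = 17,
                       event_plan = c("SE", "SE", "SE", "RI", "RI"))
  s1 <- sample_transcriptome("S1", fx$transcripts)
  flat <- lapply(fx$transcripts, function(t) {
    t$read_support <- 1L
    t
  })
  only_first <- Filter(function(t) grepl("T1$", t$transcript_id), flat)
  s2 <- sample_transcriptome("S2", only_first)   # single-isoform genes
  tab <- count_events(list(s1, s2))
  expect_identical(unname(tab$counts["S1", c("SE", "RI")]), c(3L, 2L))
  expect_identical(sum(tab$counts["S1", ]), 5L)
  expect_identical(sum(tab$counts["S2", ]), 0L)
  pr <- as_proportions(tab)
  expect_equal(sum(pr["S1", ]), 1)
})

test_that("profile comparison reproduces the Pearson chi-squared statistic", {
  same <- matrix(rep(10L, 14), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), as_event_types()))
  r0 <- compare_as_profiles(same)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  r <- compare_as_profiles(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-12)
  expect_identical(r$dof, 1L)

  # independent recomputation from the margins on a random table
  set.seed(5)
  m <- matrix(rpois(21, 30), nrow = 3)
  rr <- compare_as_profiles(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(rr$chi2, sum((m - E)^2 / E), tolerance = 1e-12)
  expect_identical(rr$dof, 2L * 6L)

  # all-zero columns are dropped, not divided by
  mz <- cbind(m, 0)
  expect_equal(compare_as_profiles(mz)$chi2, rr$chi2)

  expect_error(compare_as_profiles(matrix(1:7, nrow = 1)), "degenerate")
  expect_error(compare_as_profiles(matrix(0, 2, 7)), "degenerate")
  expect_error(compare_as_profiles(matrix(c(5, 0, 7, 0), 2)), "degenerate")
})

test_that("a skewed sample yields a significant profile difference", {
  tab <- rbind(c(30, 30, 30, 30, 30, 30, 30),
               c(28, 32, 30, 29, 31, 30, 30),
               c(80, 10, 10, 30, 30, 30, 30))
  r <- compare_as_profiles(tab)
  expect_lt(r$p, 0.05)
})

test_that("diversity scores are isoform-usage entropies with the expected bounds", {
  two_even <- list(mk_tx("T1", list(c(0, 10)), support = 5),
                   mk_tx("T2", list(c(20, 30)), support = 5))
  expect_equal(diversity_score(two_even)$score, 1.0)
  skew <- list(mk_tx("T1", list(c(0, 10)), support = 3),
               mk_tx("T2", list(c(20, 30)), support = 1))
  expect_equal(diversity_score(skew)$score,
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-12)
  expect_equal(diversity_score(skew)$score, 0.8113, tolerance = 1e-4)
  one <- list(mk_tx("T1", list(c(0, 10)), support = 99))
  expect_identical(diversity_score(one)$score, 0)
  zero <- list(mk_tx("T1", list(c(0, 10)), support = 0))
  expect_error(diversity_score(zero), "no expressed isoform")

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    txs <- lapply(seq_len(n), function(i)
      mk_tx(paste0("T", i), list(c(i * 100, i * 100 + 50)),
            support = sample(0:20, 1)))
    sup <- vapply(txs, function(t) t$read_support, integer(1))
    if (sum(sup) == 0) next
    d <- diversity_score(txs)
    expect_gte(d$score, 0)
    expect_lte(d$score, log2(max(d$n_isoforms, 1)) + 1e-12)
    expect_identical(d$score == 0, sum(sup > 0) <= 1L)
  }
})

test_that("diversity-score differences rank genes and respect pseudometric properties", {
  mk_sample <- function(sid, plan) {
    txs <- unlist(lapply(names(plan), function(g)
      lapply(seq_along(plan[[g]]), function(i)
        mk_tx(paste0(sid, ".", g, ".T", i), list(c(i * 100, i * 100 + 50)),
              gene = g, support = plan[[g]][i]))), recursive = FALSE)
    sample_transcriptome(sid, txs)
  }
  a <- mk_sample("A", list(G1 = c(1, 1, 1), G2 = c(5, 5), G3 = c(10)))
  b <- mk_sample("B", list(G1 = c(9), G2 = c(5, 5), G4 = c(3, 1)))
  sd_ab <- score_d(diversity_scores(a), diversity_scores(b))
  expect_equal(sd_ab$D[sd_ab$gene_id == "G1"], log2(3), tolerance = 1e-12)
  expect_identical(sd_ab$D[sd_ab$gene_id == "G2"], 0)
  expect_true(sd_ab$one_sample_only[sd_ab$gene_id == "G4"])
  expect_false(sd_ab$one_sample_only[sd_ab$gene_id == "G1"])
  expect_identical(sd_ab$gene_id[1], "G1")   # largest D first
  expect_false(is.unsorted(rev(sd_ab$D)))

  sd_ba <- score_d(diversity_scores(b), diversity_scores(a))
  expect_identical(sd_ab$D, sd_ba$D)          # symmetry
  sd_aa <- score_d(diversity_scores(a), diversity_scores(a))
  expect_true(all(sd_aa$D == 0))

  expect_identical(top_spliced_genes(sd_ab, k = 2), sd_ab$gene_id[1:2])
  expect_identical(top_spliced_genes(sd_ab, min_d = max(sd_ab$D)), "G1")
  expect_setequal(top_spliced_genes(sd_ab, min_d = 0), sd_ab$gene_id)
  expect_error(top_spliced_genes(sd_ab, k = 0), "positive")
  expect_error(top_spliced_genes(sd_ab, min_d = -1), "non-negative")
  expect_error(top_spliced_genes(sd_ab), "exactly one")
})
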