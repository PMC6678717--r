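test_that("TSS extraction is strand-aware", {
  plus <- mk_tx("T1", list(c(100, 200), c(300, 400)), "+")
  minus <- mk_tx("T2", list(c(100, 200), c(300, 400)), "-")
  single <- mk_tx("T3", list(c(500, 600)), "+")
  expect_identical(tss_of(plus), 100L)
  expect_identical(tss_of(minus), 399L)
  expect_identical(tss_of(single), 500L)
})

test_that("nearest-feature distance handles containment, gaps, sign and empties", {
  tr <- mk_track("CAGE", cbind(990, 1010))
  expect_identical(nearest_feature_distance(1000, "chr1", "+", tr)$distance, 0L)

  tr2 <- mk_track("CAGE", cbind(1100, 1200))
  expect_identical(nearest_feature_distance(1000, "chr1", "+", tr2)$distance,
                   100L)
  # same geometry on the minus strand: feature is upstream in transcription
  expect_identical(nearest_feature_distance(1000, "chr1", "-", tr2)$distance,
                   -100L)

  empty <- feature_track("CAGE", NULL)
  r <- nearest_feature_distance(1000, "chr1", "+", empty)
  expect_true(is.na(r$distance))
  expect_null(r$feature)
  # features only on another chromosome count as absent
  r2 <- nearest_feature_distance(1000, "chr9", "+", tr2)
  expect_true(is.na(r2$distance))

  # equidistant up/downstream: the downstream feature is reported
  tie <- mk_track("CAGE", rbind(c(800, 901), c(1100, 1200)))
  rt <- nearest_feature_distance(1000, "chr1", "+", tie)
  expect_identical(rt$distance, 100L)
  expect_identical(rt$feature$start, 1100L)
  rt_m <- nearest_feature_distance(1000, "chr1", "-", tie)
  expect_identical(rt_m$distance, 100L)
  expect_identical(rt_m$feature$start, 800L)
})

test_that("nearest-feature distance equals an exhaustive linear scan", {
  set.seed(101)
  for (rep in 1:5) {
    iv <- cbind(sample.int(50000, 300), 0)
    iv[, 2] <- iv[, 1] + sample.int(400, 300, replace = TRUE)
    tr <- mk_track("X", iv)
    tss <- sample.int(52000, 60)
    strand <- sample(c("+", "-"), 60, TRUE)
    for (i in seq_along(tss)) {
      got <- nearest_feature_distance(tss[i], "chr1", strand[i], tr)$distance
      expect_identical(got, oracle_nearest(tss[i], "chr1", strand[i], tr))
    }
  }
})

test_that("flipping strand negates nonzero signed distances", {
  set.seed(77)
  iv <- cbind(sample.int(20000, 100), 0)
  iv[, 2] <- iv[, 1] + sample.int(200, 100, replace = TRUE)
  tr <- mk_track("X", iv)
  for (tss in sample.int(21000, 40)) {
    dp <- nearest_feature_distance(tss, "chr1", "+", tr)$distance
    dm <- nearest_feature_distance(tss, "chr1", "-", tr)$distance
    expect_identical(abs(dp), abs(dm))
    if (dp != 0L) expect_identical(dm, -dp)
  }
})

test_that("distance summaries bin absolute distances per track", {
  t1 <- mk_tx("T1", list(c(1000, 1200)), "+")
  s <- sample_transcriptome("S", list(t1))
  tr <- mk_track("CAGE", cbind(990, 1010))
  ds <- distance_summary(s, list(tr))
  expect_identical(nrow(ds$records), 1L)
  expect_identical(ds$records$distance, 0L)
  expect_identical(unname(ds$histogram[1, 1]), 1L)

  # ten transcripts all placed 50 bp from a feature: one bin carries all
  txs <- lapply(1:10, function(i)
    mk_tx(paste0("T", i), list(c(i * 5000, i * 5000 + 300)), "+"))
  feats <- cbind(sapply(1:10, function(i) i * 5000 + 50), 0)
  feats[, 2] <- feats[, 1] + 20
  s10 <- sample_transcriptome("S", txs)
  ds10 <- distance_summary(s10, list(mk_track("CAGE", feats)))
  expect_true(all(abs(ds10$records$distance) == 50L))
  expect_identical(unname(ds10$histogram[1, "[0,100)"]), 10L)

  dse <- distance_summary(s, list(feature_track("CAGE", NULL)))
  expect_true(all(is.na(dse$records$distance)))
  expect_true(all(dse$histogram == 0L))
})

test_that("distance filtering keeps within-cutoff transcripts, inclusively", {
  t_in <- mk_tx("Tin", list(c(1000, 1200)), "+")    # feature at distance 0
  t_edge <- mk_tx("Tedge", list(c(5000, 5200)), "+")  # nearest at 1001
  s <- sample_transcriptome("S", list(t_in, t_edge))
  tr <- mk_track("CAGE", rbind(c(990, 1010), c(6001, 6050)))
  fr <- filter_by_distance(s, list(tr), cutoff_bp = 1000)
  expect_identical(fr$kept, "Tin")
  expect_identical(fr$discarded, "Tedge")
  fr2 <- filter_by_distance(s, list(tr), cutoff_bp = 1001)
  expect_setequal(fr2$kept, c("Tin", "Tedge"))

  expect_error(filter_by_distance(s, list(), 1000), "at least one")
  expect_error(filter_by_distance(s, list(tr), 0), "positive")
})

test_that("filter reports partition the input and are monotone in the cutoff", {
  fx <- generate_genes(withr::local_tempdir(), seed = 21,
                       event_plan = rep(NA_character_, 30))
  trk <- generate_tracks(fx$transcripts, withr::local_tempdir(), seed = 21)
  s <- sample_transcriptome("S", fx$transcripts)
  ids <- vapply(fx$transcripts, function(t) t$transcript_id, character(1))
  prev_kept <- character(0)
  for (cut in c(100, 500, 1000, 5000, 10000)) {
    for (mode in c("any", "all")) {
      fr <- filter_by_distance(s, trk$tracks, cut, mode = mode)
      expect_setequal(c(fr$kept, fr$discarded), ids)
      expect_length(intersect(fr$kept, fr$discarded), 0L)
    }
    fr_any <- filter_by_distance(s, trk$tracks, cut)
    expect_true(all(prev_kept %in% fr_any$kept))
    prev_kept <- fr_any$kept
  }
  # "all" mode is at least as strict as "any"
  fa <- filter_by_distance(s, trk$tracks, 1000, mode = "all")
  expect_true(all(fa$kept %in% prev_kept))
})
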