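mk_pred <- function(tool, noncoding, coding = character(0)) {
  calls <- c(stats::setNames(rep("noncoding", length(noncoding)), noncoding),
             stats::setNames(rep("coding", length(coding)), coding))
  structure(list(tool_name = tool, calls = calls, score = NULL),
            class = "prediction_set")
}

test_that("classifier combination yields the four standard call sets", {
  a <- mk_pred("plek", c("t1", "t2"), coding = "t4")
  b <- mk_pred("cnci", c("t2", "t3"))
  cs <- combine_predictions(a, b)
  expect_identical(cs$tool_a$transcript_ids, c("t1", "t2"))
  expect_identical(cs$intersection$transcript_ids, "t2")
  expect_identical(cs$union$transcript_ids, c("t1", "t2", "t3"))
  expect_true(all(cs$intersection$transcript_ids %in%
                    cs$tool_a$transcript_ids))
  expect_true(all(cs$tool_b$transcript_ids %in% cs$union$transcript_ids))

  disj <- combine_predictions(mk_pred("a", "x"), mk_pred("b", "y"))
  expect_length(disj$intersection$transcript_ids, 0L)
})

test_that("set identities hold on randomized prediction sets", {
  set.seed(202)
  for (rep in 1:10) {
    universe <- sprintf("t%03d", 1:200)
    a_ids <- sample(universe, 120)
    b_ids <- sample(universe, 90)
    cs <- combine_predictions(mk_pred("a", a_ids), mk_pred("b", b_ids))
    # brute-force membership scan
    inter <- universe[universe %in% a_ids & universe %in% b_ids]
    uni <- universe[universe %in% a_ids | universe %in% b_ids]
    expect_setequal(cs$intersection$transcript_ids, inter)
    expect_setequal(cs$union$transcript_ids, uni)
    expect_identical(length(cs$union$transcript_ids),
                     length(a_ids) + length(b_ids) -
                       length(cs$intersection$transcript_ids))
  }
})

test_that("intron-chain matching calls clones known and fresh chains novel", {
  entry <- catalog_entry(mk_tx("C1", list(c(100, 200), c(300, 400)), "+"),
                         tissues = "liver")
  clone <- mk_tx("cand1", list(c(80, 200), c(300, 450)), "+")  # ragged ends
  fresh <- mk_tx("cand2", list(c(100, 180), c(300, 400)), "+") # new donor
  off_chrom <- mk_tx("cand3", list(c(100, 200), c(300, 400)), "+",
                     chrom = "chrX")
  v <- match_to_catalog(list(clone, fresh, off_chrom), list(entry))
  expect_identical(v$verdict, c("known", "novel", "novel"))
  expect_identical(v$matched_entries[1], "C1")

  # reflexivity: the catalog matched against itself finds every entry
  fx <- generate_lnc_inputs(withr::local_tempdir(), seed = 3)
  self <- match_to_catalog(lapply(fx$catalog, function(e) e$transcript),
                           fx$catalog)
  expect_true(all(self$verdict == "known"))
  expect_true(all(mapply(function(id, m) id %in% strsplit(m, ";")[[1]],
                         self$transcript_id, self$matched_entries)))

  # verdicts do not depend on candidate order
  v1 <- match_to_catalog(fx$candidates, fx$catalog)
  v2 <- match_to_catalog(rev(fx$candidates), fx$catalog)
  expect_identical(v1[order(v1$transcript_id), ],
                   v2[order(v2$transcript_id), ], ignore_attr = TRUE)
})

test_that("exon-overlap mode applies a reciprocal threshold", {
  entry <- catalog_entry(mk_tx("C1", list(c(0, 1000)), "+"))
  half <- mk_tx("cand1", list(c(500, 1000)), "+")   # 50% of entry, 100% of cand
  v <- match_to_catalog(list(half), list(entry), mode = "exon_overlap",
                        min_overlap = 0.5)
  expect_identical(v$verdict, "known")
  v2 <- match_to_catalog(list(half), list(entry), mode = "exon_overlap",
                         min_overlap = 0.6)
  expect_identical(v2$verdict, "novel")
  # single-exon candidates fall back to overlap in intron-chain mode
  v3 <- match_to_catalog(list(half), list(entry), mode = "intron_chain")
  expect_identical(v3$verdict, "known")
  expect_error(match_to_catalog(list(half), list(entry), min_overlap = 0),
               "min_overlap")
})

test_that("tissue specificity requires exactly one tissue across matches", {
  liver <- catalog_entry(mk_tx("C1", list(c(100, 200), c(300, 400)), "+"),
                         "liver")
  brain <- catalog_entry(mk_tx("C2", list(c(80, 200), c(300, 500)), "+"),
                         "brain")
  bare <- catalog_entry(mk_tx("C3", list(c(1000, 1100), c(1300, 1400)), "+"))
  catalog <- list(liver, brain, bare)
  # cand1 shares the intron chain of both C1 and C2 (two tissues)
  cand1 <- mk_tx("cand1", list(c(90, 200), c(300, 420)), "+")
  cand2 <- mk_tx("cand2", list(c(1000, 1100), c(1300, 1450)), "+")
  v <- match_to_catalog(list(cand1, cand2), catalog)
  ts <- tissue_specific(v, catalog)
  expect_identical(ts$not_specific, "cand1")
  expect_identical(ts$unassigned, "cand2")

  v1 <- match_to_catalog(list(mk_tx("cand3", list(c(90, 200), c(300, 420)),
                                    "+")),
                         list(liver))
  ts1 <- tissue_specific(v1, list(liver))
  expect_identical(ts1$by_tissue$liver, "cand3")
})

test_that("the synthetic lncRNA fixture pipeline reproduces its truth table", {
  fx <- generate_lnc_inputs(withr::local_tempdir(), seed = 12)
  v <- match_to_catalog(fx$candidates, fx$catalog)
  expect_identical(v$verdict[match(fx$truth$transcript_id, v$transcript_id)],
                   fx$truth$verdict)
  ts <- tissue_specific(v, fx$catalog)
  truth_known <- fx$truth[fx$truth$verdict == "known", ]
  for (tissue in unique(truth_known$specific)) {
    ids <- sort(truth_known$transcript_id[truth_known$specific == tissue])
    got <- switch(tissue,
                  multi = ts$not_specific,
                  unassigned = ts$unassigned,
                  ts$by_tissue[[tissue]])
    expect_identical(got, ids)
  }
})
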