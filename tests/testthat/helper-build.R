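# shorthand constructors used across test files

mk_tx <- function(id, exons, strand = "+", gene = "G", chrom = "chr1",
                  support = 1L) {
  if (is.list(exons)) exons <- do.call(rbind, exons)
  transcript_model(id, gene, chrom, strand,
                   cbind(start = exons[, 1], end = exons[, 2]),
                   read_support = support)
}

mk_track <- function(name, iv, chrom = "chr1") {
  feature_track(name, data.frame(chrom = chrom, start = iv[, 1],
                                 end = iv[, 2]))
}

event_key <- function(events) {
  sort(vapply(events, function(e)
    paste0(e$type, ":", paste(e$coordinates, collapse = "-")), character(1)))
}
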