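# Shared fixtures for the suite. The anchor/gap specs below describe the
# five curated motifs in generator form (anchor classes and the non-gap run
# ranges between them).

curated_toy_specs <- list(
  GC   = list(anchors = c("KS", "CGS", "KR"),
              gaps = list(c(1, 1), c(10, 10))),
  AC   = list(anchors = c("RKS", "DE", "KR"),
              gaps = list(c(1, 1), c(10, 10))),
  PDE  = list(anchors = c("YFW", "H", "YFW", "R", "HRK", "DE"),
              gaps = list(c(0, 0), c(1, 1), c(0, 0), c(20, 40), c(0, 0))),
  HNOX = list(anchors = c("H", "P", "Y", "S", "R"),
              gaps = list(c(12, 12), c(14, 16), c(1, 1), c(1, 1))),
  ABA  = list(anchors = c("DE", "R", "DE", "Y", "H"),
              gaps = list(c(7, 8), c(3, 4), c(5, 5), c(6, 6)))
)

quiet_scan <- function(...) suppressMessages(scan_proteome(...))
quiet_load <- function(...) suppressMessages(load_proteome(...))

span_key <- function(df) paste(df$start, df$end, sep = "-")

random_test_sequence <- function(max_len = 40, with_ambiguity = TRUE) {
  alphabet <- if (with_ambiguity)
    c(rep(centerscan:::AA_STANDARD, 2), "X", "B", "Z")
  else centerscan:::AA_STANDARD
  paste(sample(alphabet, sample(seq_len(max_len), 1), replace = TRUE),
        collapse = "")
}
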