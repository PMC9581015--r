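test_that("curated and simple patterns parse into the expected elements", {
  p <- parse_pattern("[KS]x[CGS]x(10)[KR]", "GC")
  expect_length(p$elements, 5)
  kinds <- vapply(p$elements, `[[`, character(1), "kind")
  expect_equal(kinds, c("class", "wildcard", "class", "wildcard", "class"))
  expect_setequal(p$elements[[1]]$residues, c("K", "S"))
  expect_setequal(p$elements[[3]]$residues, c("C", "G", "S"))
  expect_equal(p$elements[[4]]$repeat_min, 10L)
  expect_equal(p$elements[[4]]$repeat_max, 10L)

  p1 <- parse_pattern("A")
  expect_length(p1$elements, 1)
  expect_equal(p1$elements[[1]],
               list(kind = "fixed", residues = "A",
                    repeat_min = 1L, repeat_max = 1L))

  hnox <- parse_pattern("Hx(12)Px(14,16)YxSxR")
  expect_length(hnox$elements, 9)
  expect_equal(hnox$elements[[2]][c("repeat_min", "repeat_max")],
               list(repeat_min = 12L, repeat_max = 12L))
  expect_equal(hnox$elements[[4]][c("repeat_min", "repeat_max")],
               list(repeat_min = 14L, repeat_max = 16L))
})

test_that("malformed patterns fail with informative errors", {
  expect_error(parse_pattern("x(5,"), "unterminated|number")
  expect_error(parse_pattern("[KS"), "unbalanced")
  expect_error(parse_pattern("x(7,3)"), "minimum 7 exceeds maximum 3")
  expect_error(parse_pattern("[K1]"), "standard amino-acid")
  expect_error(parse_pattern("[]A"), "empty")
  expect_error(parse_pattern("x(3)"), "non-wildcard")
  expect_error(parse_pattern(""), "empty pattern")
  expect_error(parse_pattern("A<B"), "anchor")
})

test_that("render canonicalizes and round-trips", {
  expect_equal(render_pattern(parse_pattern("[KS]x[CGS]x(10)[KR]")),
               "[KS]x[CGS]x(10)[KR]")
  expect_equal(render_pattern(parse_pattern("H-x(12)-P")), "Hx(12)P")
  expect_equal(render_pattern(parse_pattern("x(3,3)A")), "x(3)A")
  expect_equal(render_pattern(parse_pattern("<A(2){PG}x>")), "<A(2){PG}x>")

  set.seed(101)
  for (i in 1:50) {
    p <- random_pattern(6)
    expect_true(patterns_equal(p, parse_pattern(render_pattern(p))))
  }
})

test_that("length ranges reproduce the curated center sizes", {
  expect_equal(length_range(parse_pattern("[KS]x[CGS]x(10)[KR]")), c(14L, 14L))
  expect_equal(length_range(parse_pattern("[RKS]x[DE]x(10)[KR]")), c(14L, 14L))
  expect_equal(length_range(parse_pattern("[YFW]Hx[YFW]Rx(20,40)[HRK][DE]")),
               c(27L, 47L))
  expect_equal(length_range(parse_pattern("Hx(12)Px(14,16)YxSxR")),
               c(33L, 35L))
  expect_equal(length_range(parse_pattern("[DE]x(7,8)Rx(3,4)[DE]x(5)Yx(6)H")),
               c(26L, 28L))
  expect_equal(length_range(parse_pattern("x(2,3)A")), c(3L, 4L))
})

test_that("find_matches enumerates all overlapping spans in order", {
  m <- find_matches(parse_pattern("A"), "AAA")
  expect_equal(m$start, 1:3)
  expect_equal(m$end, 1:3)

  m <- find_matches(parse_pattern("Hx(1,2)Y"), "HAYHAAY")
  expect_equal(m[, c("start", "end")],
               data.frame(start = c(1L, 4L), end = c(3L, 7L)))

  m <- find_matches(parse_pattern("[KS]x[CGS]x(10)[KR]", "GC"),
                    "KACAAAAAAAAAAK")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 14L))
  expect_equal(m$matched_text, "KACAAAAAAAAAAK")

  # ranged wildcard yields several ends per start; shortest_per_start compacts
  m <- find_matches(parse_pattern("Hx(0,2)Y"), "HYYY")
  expect_equal(m[, c("start", "end")],
               data.frame(start = c(1L, 1L, 1L), end = 2:4))
  ms <- find_matches(parse_pattern("Hx(0,2)Y"), "HYYY",
                     mode = "shortest_per_start")
  expect_equal(ms$end, 2L)

  expect_equal(nrow(find_matches(parse_pattern("A"), "")), 0L)
})

test_that("every match length lies within the pattern length range", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_pattern(6)
    s <- random_test_sequence(40)
    m <- find_matches(p, s)
    if (nrow(m) == 0) next
    rng <- length_range(p)
    len <- m$end - m$start + 1L
    expect_true(all(len >= rng[1] & len <= rng[2]))
    expect_equal(nchar(m$matched_text), len)
  }
})

test_that("sequence ambiguity codes match wildcards only", {
  expect_equal(nrow(find_matches(parse_pattern("A"), "XBX")), 0L)
  expect_equal(nrow(find_matches(parse_pattern("[AG]"), "XBZ")), 0L)
  expect_equal(nrow(find_matches(parse_pattern("{A}"), "X")), 0L)
  expect_error(parse_pattern("[AX]"), "standard amino-acid")  # X is not a class member
  m <- find_matches(parse_pattern("Kx(1)K"), "KXK")
  expect_equal(nrow(m), 1L)
  expect_warning(find_matches(parse_pattern("A"), "KA*AA"), "terminator")
})

test_that("terminal anchors restrict matches to sequence ends", {
  expect_equal(find_matches(parse_pattern("<A"), "AAA")$start, 1L)
  expect_equal(find_matches(parse_pattern("A>"), "AAA")$start, 3L)
  expect_equal(nrow(find_matches(parse_pattern("<K>"), "AKA")), 0L)
})

test_that("fast matcher agrees exactly with the brute-force oracle", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_pattern(6)
    s <- random_test_sequence(40)
    a <- find_matches(p, s)
    b <- brute_force_matches(p, s)
    expect_identical(a[, c("start", "end")], b[, c("start", "end")],
                     label = sprintf("pattern %s on %s", render_pattern(p), s))
  }
  # trivial oracle anchors
  expect_equal(brute_force_matches(parse_pattern("xQ"), "AQ")$start, 1L)
  hnox <- parse_pattern("Hx(12)Px(14,16)YxSxR")
  set.seed(1)
  expect_equal(nrow(brute_force_matches(hnox, random_test_sequence(30, FALSE))),
               0L)
})

test_that("expand_class enlarges conserved positions without narrowing", {
  p <- parse_pattern("[IL]A")
  p2 <- expand_class(p, 1, "V")
  expect_setequal(p2$elements[[1]]$residues, c("V", "I", "L"))
  expect_equal(render_pattern(p2), "[VIL]A")
  expect_setequal(p$elements[[1]]$residues, c("I", "L"))  # original untouched

  expect_true(patterns_equal(expand_class(p, 1, character()), p))
  p3 <- expand_class(parse_pattern("PA"), 1, "A")
  expect_equal(p3$elements[[1]]$kind, "class")
  expect_setequal(p3$elements[[1]]$residues, c("P", "A"))

  expect_error(expand_class(p, 5, "V"), "out of range")
  expect_error(expand_class(parse_pattern("Ax(2)C"), 2, "V"), "wildcard")
})

test_that("widen_gap widens only and preserves old matches", {
  p <- parse_pattern("Hx(14,16)Y")
  p2 <- widen_gap(p, 2, 13, 18)
  expect_equal(p2$elements[[2]][c("repeat_min", "repeat_max")],
               list(repeat_min = 13L, repeat_max = 18L))
  expect_error(widen_gap(p, 2, 15, 16), "widens")
  expect_error(widen_gap(p, 1, 0, 2), "not a wildcard")
  expect_true(patterns_equal(widen_gap(parse_pattern("Ax(10)C"), 2, 10, 10),
                             parse_pattern("Ax(10)C")))
})

test_that("relaxation never removes a match span (monotonicity)", {
  set.seed(11)
  for (i in 1:120) {
    p <- random_pattern(5)
    s <- random_test_sequence(40, with_ambiguity = FALSE)
    m0 <- find_matches(p, s)
    wi <- which(vapply(p$elements, function(e) e$kind == "wildcard",
                       logical(1)))
    if (length(wi)) {
      el <- p$elements[[wi[1]]]
      m1 <- find_matches(
        widen_gap(p, wi[1], max(0L, el$repeat_min - 2L), el$repeat_max + 2L),
        s)
      expect_true(all(span_key(m0) %in% span_key(m1)))
      expect_gte(nrow(m1), nrow(m0))
    }
    ci <- which(vapply(p$elements, function(e)
      e$kind %in% c("fixed", "class") && e$repeat_min == 1L, logical(1)))
    if (length(ci)) {
      m2 <- find_matches(
        expand_class(p, ci[1], sample(centerscan:::AA_STANDARD, 2)), s)
      expect_true(all(span_key(m0) %in% span_key(m2)))
    }
  }
})

test_that("matching is deterministic", {
  p <- parse_pattern("[RKS]x[DE]x(10)[KR]", "AC")
  s <- random_proteome(1, 200, seed = 5)$sequence
  expect_identical(find_matches(p, s), find_matches(p, s))
})
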