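# PROSITE-dialect motif patterns: parse, render, analyze, relax, match.
#
# A pattern is an ordered list of elements:
#   fixed           one residue, repeat (N,N), N >= 1        e.g. "H", "A(3)"
#   class           residue alternatives in [..]             e.g. "[KS]"
#   excluded_class  PROSITE exclusion in {..}                e.g. "{P}"
#   wildcard        any residue, finite repeat range         e.g. "x", "x(10)", "x(14,16)"
# Optional PROSITE anchors "<" (N-terminus) and ">" (C-terminus) are accepted.
# Both the compact dialect ("Hx(12)P") and hyphen-separated PROSITE
# ("H-x(12)-P") parse; rendering always emits the compact dialect.

new_pattern_element <- function(kind, residues = character(), repeat_min = 1L,
                                repeat_max = repeat_min) {
  stopifnot(kind %in% c("fixed", "class", "excluded_class", "wildcard"))
  el <- list(kind = kind, residues = residues,
             repeat_min = as.integer(repeat_min),
             repeat_max = as.integer(repeat_max))
  validate_element(el)
  el
}

validate_element <- function(el) {
  if (el$repeat_min < 0L || el$repeat_max < el$repeat_min)
    stop("invalid repeat range (", el$repeat_min, ",", el$repeat_max, ")")
  if (el$kind == "fixed") {
    stopifnot(length(el$residues) == 1L, el$repeat_min == el$repeat_max,
              el$repeat_min >= 1L)
  } else if (el$kind %in% c("class", "excluded_class")) {
    if (length(el$residues) == 0L) stop("empty residue class")
    bad <- setdiff(el$residues, AA_STANDARD)
    if (length(bad)) stop("non-amino-acid letter(s) in class: ",
                          paste(bad, collapse = ", "))
  } else if (length(el$residues) != 0L) {
    stop("wildcard elements carry no residues")
  }
  invisible(el)
}

new_motif_pattern <- function(motif_id, elements, source_text,
                              anchor_start = FALSE, anchor_end = FALSE) {
  if (!any(vapply(elements, function(e) e$kind != "wildcard", logical(1))))
    stop("pattern must contain at least one non-wildcard element")
  structure(list(motif_id = motif_id, elements = elements,
                 source_text = source_text,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "motif_pattern")
}

#' Parse a PROSITE-dialect motif pattern
#'
#' Accepts the compact dialect used for functional-center motifs (e.g.
#' `"[KS]x[CGS]x(10)[KR]"`) as well as hyphen-separated PROSITE
#' (`"H-x(12)-P"`). Recognized tokens: single residue letters, optionally with
#' a fixed repeat `A(3)`; `x`, `x(N)`, `x(N,M)` wildcards; `[ABC]` residue
#' classes; `{ABC}` PROSITE exclusions; terminal anchors `<` and `>`.
#' Whitespace is ignored and letters are upper-cased. Ranged gaps are written
#' `x(N,M)` only: curly braces always mean exclusion, never a gap range.
#'
#' @param text pattern string.
#' @param motif_id label attached to the pattern and its matches.
#' @return a `motif_pattern` object.
#' @export
#' @examples
#' p <- parse_pattern("[KS]x[CGS]x(10)[KR]", "GC")
#' length_range(p)  # c(14, 14)
parse_pattern <- function(text, motif_id = "motif") {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty pattern string")
  raw <- strsplit(text, "")[[1]]
  keep <- !(raw %in% c(" ", "\t", "\n", "-", "."))
  chars <- toupper(raw[keep])
  offs <- which(keep)                      # offsets into the original string
  n <- length(chars)
  perr <- function(i, msg) {
    at <- if (i <= n) offs[i] else nchar(text) + 1L
    tok <- if (i <= n) chars[i] else "<end>"
    stop(sprintf("pattern parse error at offset %d near '%s': %s", at, tok, msg),
         call. = FALSE)
  }
  # read "(N)" or "(N,M)" starting at i (which must be "("); returns
  # list(min, max, next_i)
  read_repeat <- function(i, allow_range = TRUE) {
    j <- i + 1L
    num <- function(j0) {
      j1 <- j0
      while (j1 <= n && grepl("[0-9]", chars[j1])) j1 <- j1 + 1L
      if (j1 == j0) perr(j0, "expected a number in repeat specifier")
      list(val = as.integer(paste(chars[j0:(j1 - 1L)], collapse = "")), next_i = j1)
    }
    a <- num(j)
    if (a$next_i <= n && chars[a$next_i] == ",") {
      if (!allow_range) perr(a$next_i, "ranged repeat is only valid after 'x'")
      b <- num(a$next_i + 1L)
      if (b$next_i > n || chars[b$next_i] != ")")
        perr(b$next_i, "unterminated repeat specifier")
      if (a$val > b$val) perr(j, sprintf("repeat minimum %d exceeds maximum %d",
                                         a$val, b$val))
      list(min = a$val, max = b$val, next_i = b$next_i + 1L)
    } else if (a$next_i <= n && chars[a$next_i] == ")") {
      list(min = a$val, max = a$val, next_i = a$next_i + 1L)
    } else {
      perr(a$next_i, "unterminated repeat specifier")
    }
  }
  elements <- list()
  anchor_start <- FALSE
  anchor_end <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "<") {
      if (i != 1L) perr(i, "'<' anchor is only valid at the pattern start")
      anchor_start <- TRUE
      i <- i + 1L
    } else if (ch == ">") {
      if (i != n) perr(i, "'>' anchor is only valid at the pattern end")
      anchor_end <- TRUE
      i <- i + 1L
    } else if (ch %in% c("[", "{")) {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      res <- character()
      while (j <= n && chars[j] != close) {
        if (!chars[j] %in% AA_STANDARD)
          perr(j, "only standard amino-acid letters are allowed in a class")
        res <- c(res, chars[j])
        j <- j + 1L
      }
      if (j > n) perr(i, sprintf("unbalanced '%s'", ch))
      if (length(res) == 0L) perr(i, "empty residue class")
      elements[[length(elements) + 1L]] <- new_pattern_element(
        if (ch == "[") "class" else "excluded_class", unique(res))
      i <- j + 1L
    } else if (ch == "X") {
      rng <- list(min = 1L, max = 1L, next_i = i + 1L)
      if (i + 1L <= n && chars[i + 1L] == "(") rng <- read_repeat(i + 1L)
      elements[[length(elements) + 1L]] <- new_pattern_element(
        "wildcard", character(), rng$min, rng$max)
      i <- rng$next_i
    } else if (ch %in% AA_STANDARD) {
      rng <- list(min = 1L, max = 1L, next_i = i + 1L)
      if (i + 1L <= n && chars[i + 1L] == "(")
        rng <- read_repeat(i + 1L, allow_range = FALSE)
      if (rng$min < 1L) perr(i, "fixed-residue repeat must be at least 1")
      elements[[length(elements) + 1L]] <- new_pattern_element(
        "fixed", ch, rng$min, rng$max)
      i <- rng$next_i
    } else if (ch %in% c("]", "}")) {
      perr(i, sprintf("unbalanced '%s'", ch))
    } else {
      perr(i, "unrecognized token")
    }
  }
  if (length(elements) == 0L) stop("pattern contains no elements")
  new_motif_pattern(motif_id, elements, text, anchor_start, anchor_end)
}

#' Render a motif pattern as a canonical compact string
#'
#' The inverse of [parse_pattern()]: hyphens are dropped, degenerate ranges
#' collapse (`x(3,3)` renders `x(3)`, `x(1,1)` renders `x`) and class residues
#' appear in their stored order. `parse_pattern(render_pattern(p))` always
#' reproduces `p` element-for-element.
#'
#' @param p a `motif_pattern`.
#' @return single pattern string.
#' @export
render_pattern <- function(p) {
  stopifnot(inherits(p, "motif_pattern"))
  rep_txt <- function(lo, hi) {
    if (lo == 1L && hi == 1L) ""
    else if (lo == hi) sprintf("(%d)", lo)
    else sprintf("(%d,%d)", lo, hi)
  }
  parts <- vapply(p$elements, function(e) {
    switch(e$kind,
      fixed = paste0(e$residues, rep_txt(e$repeat_min, e$repeat_max)),
      class = paste0("[", paste(e$residues, collapse = ""), "]"),
      excluded_class = paste0("{", paste(e$residues, collapse = ""), "}"),
      wildcard = paste0("x", rep_txt(e$repeat_min, e$repeat_max)))
  }, character(1))
  paste0(if (isTRUE(p$anchor_start)) "<" else "", paste(parts, collapse = ""),
         if (isTRUE(p$anchor_end)) ">" else "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  rng <- length_range(x)
  cat(sprintf("<motif_pattern> %s: %s  [%d element(s), match length %d-%d]\n",
              x$motif_id, render_pattern(x), length(x$elements), rng[1], rng[2]))
  invisible(x)
}

#' @export
format.motif_pattern <- function(x, ...) render_pattern(x)

#' Compare two motif patterns element-wise
#'
#' Elements are equal when kind and repeat range agree and residue sets agree
#' as sets (order-insensitive).
#'
#' @param a,b `motif_pattern` objects.
#' @return TRUE or FALSE.
#' @export
patterns_equal <- function(a, b) {
  if (length(a$elements) != length(b$elements)) return(FALSE)
  if (!identical(isTRUE(a$anchor_start), isTRUE(b$anchor_start)) ||
      !identical(isTRUE(a$anchor_end), isTRUE(b$anchor_end))) return(FALSE)
  all(mapply(function(x, y) {
    x$kind == y$kind && x$repeat_min == y$repeat_min &&
      x$repeat_max == y$repeat_max && setequal(x$residues, y$residues)
  }, a$elements, b$elements))
}

#' Minimum and maximum match length of a pattern
#'
#' Sums element repeat ranges; a good consensus motif spans roughly 12-50
#' residues (shorter risks false positives, longer misses candidates).
#'
#' @param p a `motif_pattern`.
#' @return integer vector `c(min_len, max_len)`.
#' @export
#' @examples
#' length_range(parse_pattern("[YFW]Hx[YFW]Rx(20,40)[HRK][DE]"))  # c(27, 47)
length_range <- function(p) {
  stopifnot(inherits(p, "motif_pattern"))
  c(sum(vapply(p$elements, `[[`, integer(1), "repeat_min")),
    sum(vapply(p$elements, `[[`, integer(1), "repeat_max")))
}

# character-level indicator: which positions of `chars` can one unit of
# element `el` consume?
element_char_ok <- function(el, chars) {
  switch(el$kind,
    wildcard = rep(TRUE, length(chars)),
    fixed = chars == el$residues,
    class = chars %in% el$residues,
    # ambiguity codes never satisfy an exclusion: only definite residues do
    excluded_class = chars %in% setdiff(AA_STANDARD, el$residues))
}

#' Find all matches of a motif pattern in a protein sequence
#'
#' Enumerates every distinct `(start, end)` span where the pattern matches,
#' including multiple end positions per start when ranged wildcards allow
#' different gap lengths, and overlapping spans. Uses a vectorized
#' position-set sweep over the elements (polynomial in sequence length even
#' for wide gap ranges). Sequence ambiguity codes (X, B, Z, J, U, O) match
#' wildcard elements only.
#'
#' @param p a `motif_pattern`.
#' @param seq protein sequence string (sanitized on entry).
#' @param mode `"all_spans"` (default) or `"shortest_per_start"`, which keeps
#'   only the shortest span at each start for compact reports.
#' @param seq_id identifier recorded in the result.
#' @return data.frame with columns `seq_id`, `start`, `end`, `matched_text`,
#'   `motif_id`; 1-based inclusive coordinates, sorted by `(start, end)`.
#' @export
#' @examples
#' find_matches(parse_pattern("Hx(1,2)Y"), "HAYHAAY")[, c("start", "end")]
find_matches <- function(p, seq, mode = c("all_spans", "shortest_per_start"),
                         seq_id = "seq") {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "motif_pattern"))
  s <- sanitize_sequence(seq, seq_id)
  n <- nchar(s)
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      matched_text = character(), motif_id = character(),
                      stringsAsFactors = FALSE)
  rng <- length_range(p)
  if (n == 0L || rng[1] > n) return(empty)
  chars <- strsplit(s, "")[[1]]
  starts <- seq_len(n - rng[1] + 1L)
  if (isTRUE(p$anchor_start)) starts <- 1L
  # cheap pruning on the first element
  e1 <- p$elements[[1]]
  ok1 <- element_char_ok(e1, chars)
  if (e1$repeat_min >= 1L) starts <- starts[ok1[starts]]
  if (length(starts) == 0L) return(empty)
  # state matrix: row = candidate start, column j = "next position to consume
  # is j" (j in 1..n+1)
  M <- matrix(FALSE, nrow = length(starts), ncol = n + 1L)
  M[cbind(seq_along(starts), starts)] <- TRUE
  for (el in p$elements) {
    ok <- element_char_ok(el, chars)
    cs <- c(0L, cumsum(ok))
    newM <- matrix(FALSE, nrow = nrow(M), ncol = n + 1L)
    for (L in el$repeat_min:el$repeat_max) {
      if (L == 0L) { newM <- newM | M; next }
      if (L > n) break
      js <- seq_len(n + 1L - L)                 # start positions of the run
      run_ok <- (cs[js + L] - cs[js]) == L
      active <- js[run_ok]
      if (length(active) == 0L) next
      newM[, active + L] <- newM[, active + L, drop = FALSE] |
        M[, active, drop = FALSE]
    }
    M <- newM
    if (!any(M)) return(empty)
  }
  hit <- which(M, arr.ind = TRUE)
  start <- starts[hit[, 1L]]
  end <- hit[, 2L] - 1L
  keep <- end >= start
  if (isTRUE(p$anchor_end)) keep <- keep & (end == n)
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) return(empty)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (mode == "shortest_per_start") {
    first <- !duplicated(start)
    start <- start[first]; end <- end[first]
  }
  out <- data.frame(seq_id = seq_id, start = as.integer(start),
                    end = as.integer(end),
                    matched_text = substring(s, start, end),
                    motif_id = p$motif_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exhaustive reference matcher (brute force)
#'
#' Plain recursive enumeration of every element-to-span assignment, written
#' independently of [find_matches()] so the two can be compared as an
#' equivalence check. Intended for short sequences (tens of residues).
#'
#' @inheritParams find_matches
#' @return data.frame in the same shape as [find_matches()].
#' @export
brute_force_matches <- function(p, seq, seq_id = "seq") {
  stopifnot(inherits(p, "motif_pattern"))
  s <- sanitize_sequence(seq, seq_id)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  els <- p$elements
  spans <- list()
  unit_ok <- function(el, pos) {
    ch <- chars[pos]
    if (el$kind == "wildcard") return(TRUE)
    if (el$kind == "fixed") return(ch == el$residues)
    if (el$kind == "class") return(ch %in% el$residues)
    (ch %in% AA_STANDARD) && !(ch %in% el$residues)
  }
  recurse <- function(ei, pos, start) {
    if (ei > length(els)) {
      end <- pos - 1L
      if (end >= start && (!isTRUE(p$anchor_end) || end == n))
        spans[[length(spans) + 1L]] <<- c(start, end)
      return(invisible())
    }
    el <- els[[ei]]
    for (L in el$repeat_min:el$repeat_max) {
      if (pos + L - 1L > n) break
      ok <- TRUE
      if (L > 0L) for (q in pos:(pos + L - 1L)) {
        if (!unit_ok(el, q)) { ok <- FALSE; break }
      }
      if (ok) recurse(ei + 1L, pos + L, start)
    }
  }
  start_set <- if (isTRUE(p$anchor_start)) 1L else seq_len(max(n, 0L))
  for (st in start_set) if (st <= n) recurse(1L, st, st)
  if (length(spans) == 0L)
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      matched_text = character(), motif_id = character(),
                      stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, spans))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- data.frame(seq_id = seq_id, start = as.integer(m[, 1L]),
                    end = as.integer(m[, 2L]),
                    matched_text = substring(s, m[, 1L], m[, 2L]),
                    motif_id = p$motif_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relax a pattern by enlarging a residue class
#'
#' Adds chemically similar residues to a conserved position (e.g. expanding
#' `[IL]` to `[VIL]`) to loosen motif stringency when a search retrieves too
#' few candidates. A fixed residue is promoted to a class. The match set of
#' the relaxed pattern is always a superset of the original's.
#'
#' @param p a `motif_pattern`.
#' @param element_index 1-based index of a fixed or class element.
#' @param extra_residues character vector of residues to add (may be empty).
#' @return a new `motif_pattern`; `p` is unchanged.
#' @export
expand_class <- function(p, element_index, extra_residues) {
  stopifnot(inherits(p, "motif_pattern"))
  if (element_index < 1L || element_index > length(p$elements))
    stop("element index ", element_index, " out of range")
  el <- p$elements[[element_index]]
  if (el$kind %in% c("wildcard", "excluded_class"))
    stop("cannot expand a ", el$kind, " element; pick a fixed or class position")
  extra_residues <- toupper(as.character(extra_residues))
  bad <- setdiff(extra_residues, AA_STANDARD)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  if (el$kind == "fixed" && el$repeat_min > 1L &&
      length(setdiff(extra_residues, el$residues)) > 0L)
    stop("cannot expand a repeated fixed element; rewrite the repeat first")
  # stored order keeps new members first, as in [IL] + V -> [VIL]
  res <- c(setdiff(unique(extra_residues), el$residues), el$residues)
  new_el <- if (length(res) == 1L)
    new_pattern_element("fixed", res, el$repeat_min, el$repeat_max)
  else new_pattern_element("class", res, el$repeat_min, el$repeat_max)
  els <- p$elements
  els[[element_index]] <- new_el
  out <- new_motif_pattern(p$motif_id, els, source_text = NA_character_,
                           p$anchor_start, p$anchor_end)
  out$source_text <- render_pattern(out)
  out
}

#' Relax a pattern by widening a wildcard gap
#'
#' Loosens stringency by allowing the gap between conserved residues to vary
#' more. Only widening is permitted (`new_min <= repeat_min`,
#' `new_max >= repeat_max`), so every span matched before remains matched.
#'
#' @param p a `motif_pattern`.
#' @param element_index 1-based index of a wildcard element.
#' @param new_min,new_max widened repeat bounds.
#' @return a new `motif_pattern`; `p` is unchanged.
#' @export
widen_gap <- function(p, element_index, new_min, new_max) {
  stopifnot(inherits(p, "motif_pattern"))
  if (element_index < 1L || element_index > length(p$elements))
    stop("element index ", element_index, " out of range")
  el <- p$elements[[element_index]]
  if (el$kind != "wildcard")
    stop("element ", element_index, " is not a wildcard gap")
  new_min <- as.integer(new_min); new_max <- as.integer(new_max)
  if (new_min < 0L) stop("gap minimum must be non-negative")
  if (new_min > el$repeat_min || new_max < el$repeat_max)
    stop("widen_gap only widens: re-parse the pattern to tighten a gap")
  els <- p$elements
  els[[element_index]] <- new_pattern_element("wildcard", character(),
                                              new_min, new_max)
  out <- new_motif_pattern(p$motif_id, els, source_text = NA_character_,
                           p$anchor_start, p$anchor_end)
  out$source_text <- render_pattern(out)
  out
}
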