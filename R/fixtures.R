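# Deterministic synthetic data: random proteomes, planted motif instances
# with ground truth, toy center alignments, and scan evaluation. Everything
# is reproducible from an integer seed and leaves the caller's RNG state
# untouched.

#' Generate a random synthetic proteome
#'
#' Residues are drawn i.i.d. from the given composition; sequence lengths are
#' fixed (`len_sd = 0`) or normal with the given mean/sd (rounded, floored at
#' 1). Identical seeds give byte-identical output.
#'
#' @param n_seqs number of sequences (>= 0).
#' @param len_mean mean sequence length (default 300).
#' @param len_sd length standard deviation (default 0 = fixed length).
#' @param composition `"uniform"` (1/20 per residue, the analytic null),
#'   `"swissprot"` (an empirical residue-frequency preset), or a named
#'   numeric vector of frequencies over the 20 standard residues summing
#'   to 1.
#' @param seed integer seed.
#' @return data.frame with `seq_id` (`synth_0001`, ...) and `sequence`.
#' @export
random_proteome <- function(n_seqs, len_mean = 300L, len_sd = 0,
                            composition = "uniform", seed = 1L) {
  stopifnot(n_seqs >= 0L, len_mean >= 1)
  prob <- composition_vector(composition)
  with_seed(seed, {
    lens <- if (len_sd > 0)
      pmax(1L, as.integer(round(stats::rnorm(n_seqs, len_mean, len_sd))))
    else rep(as.integer(len_mean), n_seqs)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = prob),
            collapse = ""), character(1))
    data.frame(seq_id = sprintf("synth_%04d", seq_len(n_seqs)),
               sequence = if (n_seqs) seqs else character(0),
               stringsAsFactors = FALSE)
  })
}

composition_vector <- function(composition) {
  if (is.character(composition) && length(composition) == 1L) {
    if (composition == "uniform") return(rep(1 / 20, 20))
    if (composition == "swissprot") {
      # UniProtKB/Swiss-Prot release-level residue frequencies (percent)
      f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, E = 6.72,
             Q = 3.93, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
             M = 2.41, F = 3.86, P = 4.74, S = 6.64, T = 5.36, W = 1.10,
             Y = 2.92, V = 6.86)
      return(unname(f[AA_STANDARD] / sum(f)))
    }
    stop("unknown composition preset: ", composition)
  }
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  bad <- setdiff(names(composition), AA_STANDARD)
  if (length(bad)) stop("invalid residue(s) in composition: ",
                        paste(bad, collapse = ", "))
  full <- stats::setNames(rep(0, 20), AA_STANDARD)
  full[names(composition)] <- composition
  if (abs(sum(full) - 1) > 1e-8) stop("composition must sum to 1")
  unname(full)
}

#' Sample one instance from a motif's language
#'
#' Draws a concrete string matched by the pattern: a uniform class member at
#' each class position, a uniform non-member for exclusions, and for each
#' wildcard a uniform gap length within its range filled with uniform
#' residues. Uses the current RNG state.
#'
#' @param p a `motif_pattern`.
#' @return a single string; guaranteed to match `p`.
#' @export
sample_motif_instance <- function(p) {
  stopifnot(inherits(p, "motif_pattern"))
  parts <- vapply(p$elements, function(e) {
    L <- if (e$repeat_min == e$repeat_max) e$repeat_min
         else sample(e$repeat_min:e$repeat_max, 1L)
    if (L == 0L) return("")
    pool <- switch(e$kind,
      fixed = e$residues, class = e$residues,
      excluded_class = setdiff(AA_STANDARD, e$residues),
      wildcard = AA_STANDARD)
    if (e$kind == "fixed") paste(rep(e$residues, L), collapse = "")
    else paste(sample(pool, L, replace = TRUE), collapse = "")
  }, character(1))
  paste(parts, collapse = "")
}

#' Plant motif instances into a proteome with ground truth
#'
#' Overwrites `k` non-overlapping regions of the proteome with strings
#' sampled from the motif's language, recording exact coordinates as ground
#' truth. Placement uses rejection sampling with a retry cap (1000 attempts
#' per instance). Every planted string is asserted to match its motif at
#' generation time.
#'
#' @param proteome data.frame with `seq_id`, `sequence`.
#' @param motif a `motif_record` (or `motif_pattern`).
#' @param k number of instances to plant.
#' @param seed integer seed.
#' @param with_downstream_DE if TRUE, a D or E is additionally written at a
#'   random offset 1-3 past each instance (the cation-binding variant).
#' @return list with `proteome` (modified) and `truth`, a data.frame of
#'   `seq_id`, `start`, `end`, `motif_id`, `planted_text`,
#'   `de_offset` (NA when `with_downstream_DE` is FALSE).
#' @export
plant_instances <- function(proteome, motif, k, seed = 1L,
                            with_downstream_DE = FALSE) {
  p <- if (inherits(motif, "motif_record")) motif$pattern else motif
  stopifnot(inherits(p, "motif_pattern"), k >= 0L)
  truth <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif_id = character(),
                      planted_text = character(), de_offset = integer(),
                      stringsAsFactors = FALSE)
  if (k == 0L) return(list(proteome = proteome, truth = truth))
  occupied <- lapply(seq_len(nrow(proteome)), function(i) integer(0))
  with_seed(seed, {
    for (inst in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        txt <- sample_motif_instance(p)
        L <- nchar(txt)
        reserve <- L + if (with_downstream_DE) 3L else 0L
        i <- sample.int(nrow(proteome), 1L)
        slen <- nchar(proteome$sequence[i])
        if (slen < reserve) next
        st <- sample.int(slen - reserve + 1L, 1L)
        span <- st:(st + reserve - 1L)
        if (length(intersect(span, occupied[[i]]))) next
        s <- proteome$sequence[i]
        substr(s, st, st + L - 1L) <- txt
        de_off <- NA_integer_
        if (with_downstream_DE) {
          de_off <- sample(1:3, 1L)
          pos <- st + L - 1L + de_off
          substr(s, pos, pos) <- sample(c("D", "E"), 1L)
        }
        proteome$sequence[i] <- s
        occupied[[i]] <- c(occupied[[i]], span)
        m <- find_matches(p, txt)
        if (!any(m$start == 1L & m$end == L))
          stop("internal error: planted text does not match its motif")
        truth <- rbind(truth, data.frame(
          seq_id = proteome$seq_id[i], start = st, end = st + L - 1L,
          motif_id = p$motif_id, planted_text = txt, de_offset = de_off,
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place instance ", inst,
             " without overlap after 1000 attempts; proteome too crowded")
    }
    truth <- truth[order(match(truth$seq_id, proteome$seq_id), truth$start), ]
    rownames(truth) <- NULL
    list(proteome = proteome, truth = truth)
  })
}

#' Generate a toy center alignment with known anchor/gap structure
#'
#' Builds an alignment in which specified anchor positions carry conserved
#' residues (cycling through class members so every member is observed) and
#' the runs between anchors carry random filler residues whose per-row counts
#' are drawn from the given ranges (the first two rows take the range minimum
#' and maximum so both bounds are always realized; shorter runs are padded
#' with `-`). Filler columns are resampled (seeded, bounded retries) if they
#' accidentally reach the conservation threshold, so that [build_motif()] on
#' the output — forcing the anchor columns — regenerates exactly the pattern
#' `anchors`/`gaps` describe. This mirrors how the H-NOX consensus
#' `Hx(12)Px(14,16)YxSxR` arises from an 11-species alignment of heme-binding
#' centers.
#'
#' @param anchors character vector; each entry the residue(s) conserved at an
#'   anchor (e.g. `c("H", "P", "Y", "S", "R")` or `c("KS", "CGS", "KR")`).
#' @param gaps list (length `length(anchors) - 1`) of `c(min, max)` non-gap
#'   run lengths between consecutive anchors; `c(0, 0)` for adjacent anchors.
#' @param n_rows number of rows (>= longest anchor class, >= 2).
#' @param seed integer seed.
#' @return a `center_alignment` with attributes `anchor_columns` (positions
#'   of the anchor columns) and `target_pattern` (the pattern text the
#'   builder regenerates).
#' @export
toy_center_alignment <- function(anchors, gaps, n_rows = 11L, seed = 1L) {
  anchors <- toupper(as.character(anchors))
  stopifnot(length(anchors) >= 1L, length(gaps) == length(anchors) - 1L)
  classes <- strsplit(anchors, "")
  if (n_rows < max(lengths(classes)) || n_rows < 2L)
    stop("n_rows must be >= 2 and >= the largest anchor class size")
  gaps <- lapply(gaps, function(g) {
    g <- as.integer(g)
    if (length(g) == 1L) g <- c(g, g)
    stopifnot(length(g) == 2L, g[1] >= 0L, g[2] >= g[1])
    g
  })
  # target pattern text for the round-trip contract
  target <- paste(vapply(seq_along(anchors), function(i) {
    cls <- classes[[i]]
    a <- if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
    if (i == length(anchors)) return(a)
    g <- gaps[[i]]
    gtxt <- if (g[2] == 0L) ""
            else if (g[1] == g[2] && g[1] == 1L) "x"
            else if (g[1] == g[2]) sprintf("x(%d)", g[1])
            else sprintf("x(%d,%d)", g[1], g[2])
    paste0(a, gtxt)
  }, character(1)), collapse = "")
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      rows <- list()
      for (r in seq_len(n_rows)) {
        parts <- character()
        for (i in seq_along(anchors)) {
          cls <- classes[[i]]
          parts <- c(parts, cls[((r - 1L) %% length(cls)) + 1L])
          if (i < length(anchors)) {
            g <- gaps[[i]]
            L <- if (r == 1L) g[1] else if (r == 2L) g[2]
                 else if (g[1] == g[2]) g[1] else sample(g[1]:g[2], 1L)
            width <- g[2]
            fill <- if (L > 0L)
              paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
            else ""
            parts <- c(parts, paste0(fill,
                                     paste(rep("-", width - L), collapse = "")))
          }
        }
        rows[[r]] <- paste(parts, collapse = "")
      }
      aln <- center_alignment(stats::setNames(
        unlist(rows), sprintf("row%02d", seq_len(n_rows))))
      widths <- c(0L, cumsum(vapply(seq_along(anchors)[-length(anchors)],
                                    function(i) 1L + gaps[[i]][2], integer(1))))
      anchor_cols <- widths + 1L
      built <- try(suppressWarnings(build_motif(aln, build_params(
        force_positions = anchor_cols), motif_id = "toy")), silent = TRUE)
      if (!inherits(built, "try-error") &&
          render_pattern(built) == target) {
        attr(aln, "anchor_columns") <- anchor_cols
        attr(aln, "target_pattern") <- target
        return(aln)
      }
    }
  })
  stop("could not realize an alignment regenerating '", target,
       "' within 100 attempts; widen n_rows or simplify the spec")
}

#' Evaluate scan hits against planted ground truth
#'
#' @param hits hit data.frame from [scan_proteome()].
#' @param truth truth data.frame from [plant_instances()].
#' @return list: `recall` (fraction of truth recovered at exact
#'   `(seq_id, start, end, motif_id)` coordinates), `precision` (fraction of
#'   hits that are planted; 0 when there are hits but no truth, NA when there
#'   are no hits), `coordinate_exactness` (among truth rows overlapped by a
#'   same-motif hit, the fraction recovered at exact coordinates), and the
#'   counts `n_truth`, `n_hits`, `n_exact`.
#' @export
evaluate_scan <- function(hits, truth) {
  key <- function(d) paste(d$seq_id, d$start, d$end, d$motif_id, sep = "|")
  tk <- key(truth); hk <- key(hits)
  exact <- tk %in% hk
  overlapped <- vapply(seq_len(nrow(truth)), function(i) {
    any(hits$seq_id == truth$seq_id[i] & hits$motif_id == truth$motif_id[i] &
          hits$start <= truth$end[i] & hits$end >= truth$start[i])
  }, logical(1))
  list(recall = if (nrow(truth)) mean(exact) else NA_real_,
       precision = if (nrow(hits)) mean(hk %in% tk) else NA_real_,
       coordinate_exactness = if (any(overlapped))
         sum(exact) / sum(overlapped) else NA_real_,
       n_truth = nrow(truth), n_hits = nrow(hits), n_exact = sum(exact))
}

#' Write a proteome and truth table to disk
#'
#' @param proteome data.frame with `seq_id`, `sequence`.
#' @param fasta_path output FASTA path (written via Biostrings).
#' @param truth optional truth data.frame; written as TSV when
#'   `truth_path` is given.
#' @param truth_path optional output TSV path for the truth table.
#' @return invisibly, `fasta_path`.
#' @export
write_proteome <- function(proteome, fasta_path, truth = NULL,
                           truth_path = NULL) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- proteome$seq_id
  Biostrings::writeXStringSet(aa, fasta_path)
  if (!is.null(truth) && !is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta_path)
}

#' Random small motif patterns for property testing
#'
#' Draws a random pattern of up to `max_elements` elements mixing fixed
#' residues, classes, exclusions and (bounded) ranged wildcards; always
#' includes at least one non-wildcard element. Uses the current RNG state.
#'
#' @param max_elements maximum element count (default 6).
#' @return a `motif_pattern`.
#' @export
random_pattern <- function(max_elements = 6L) {
  n <- sample.int(max_elements, 1L)
  els <- vector("list", n)
  kinds <- sample(c("fixed", "class", "excluded_class", "wildcard"), n,
                  replace = TRUE)
  kinds[sample.int(n, 1L)] <- sample(c("fixed", "class"), 1L)
  for (i in seq_len(n)) {
    els[[i]] <- switch(kinds[i],
      fixed = new_pattern_element("fixed", sample(AA_STANDARD, 1L)),
      class = new_pattern_element("class",
        sample(AA_STANDARD, sample(2:4, 1L))),
      excluded_class = new_pattern_element("excluded_class",
        sample(AA_STANDARD, sample(1:15, 1L))),
      wildcard = {
        lo <- sample(0:3, 1L)
        new_pattern_element("wildcard", character(), lo,
                            lo + sample(0:3, 1L))
      })
  }
  p <- new_motif_pattern("rand", els, source_text = NA_character_)
  p$source_text <- render_pattern(p)
  p
}
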