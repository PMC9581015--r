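# Proteome scanning with curated or user motifs, downstream-acidic annotation
# of cyclase hits, and TSV/GFF3/FASTA export.

#' Load a proteome from FASTA
#'
#' Reads protein sequences with Biostrings, takes the first whitespace token
#' of each header as the sequence identifier, rejects duplicate identifiers
#' and sanitizes residues (upper-case; `*` terminators stripped with a
#' warning; ambiguity codes kept).
#'
#' @param path FASTA file.
#' @return data.frame with columns `seq_id`, `sequence`, in file order.
#' @export
load_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty identifier)")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  seqs <- vapply(seq_along(aa), function(i)
    sanitize_sequence(as.character(aa[[i]]), ids[i]), character(1))
  message(length(aa), " sequence(s) loaded from ", path)
  data.frame(seq_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Curated functional-center motif registry
#'
#' The five bundled search motifs: guanylate cyclase (GC) and adenylate
#' cyclase (AC) 14-residue catalytic centers, the 27-47 residue cyclic
#' nucleotide phosphodiesterase (PDE) center, the 33-35 residue H-NOX
#' heme/gas-sensing center whose H residue is the distal NO ligand and whose
#' YxSxR signature stabilizes the porphyrin ring, and the 26-28 residue
#' abscisic-acid (ABA) interacting center from PYR/PYL receptor binding
#' residues.
#'
#' @param registry_path optional path to a custom registry TSV with columns
#'   `motif_id`, `center_class`, `pattern`, `expected_min_len`,
#'   `expected_max_len`, `notes`; defaults to the bundled registry.
#' @return list of `motif_record` objects, each with fields `motif_id`,
#'   `center_class`, `pattern` (a `motif_pattern`), `expected_length_range`,
#'   `note`.
#' @export
#' @examples
#' length(builtin_motifs())  # 5
builtin_motifs <- function(registry_path = NULL) {
  if (is.null(registry_path))
    registry_path <- system.file("extdata", "motifs", "curated_motifs.tsv",
                                 package = "centerscan", mustWork = TRUE)
  reg <- utils::read.delim(registry_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(reg)), function(i) {
    rec <- structure(list(
      motif_id = reg$motif_id[i],
      center_class = reg$center_class[i],
      pattern = parse_pattern(reg$pattern[i], reg$motif_id[i]),
      expected_length_range = c(reg$expected_min_len[i], reg$expected_max_len[i]),
      note = reg$notes[i]), class = "motif_record")
    rng <- length_range(rec$pattern)
    if (!identical(as.integer(rng), as.integer(rec$expected_length_range)))
      stop("registry length mismatch for ", rec$motif_id, ": pattern spans ",
           rng[1], "-", rng[2], " but registry expects ",
           rec$expected_length_range[1], "-", rec$expected_length_range[2])
    rec
  })
}

#' Wrap a custom pattern as a motif record
#'
#' @param pattern pattern string or `motif_pattern`.
#' @param motif_id label.
#' @param center_class one of GC, AC, PDE, HNOX, ABA or "custom".
#' @param note free-text provenance note.
#' @return a `motif_record`.
#' @export
motif_record <- function(pattern, motif_id = "custom",
                         center_class = "custom", note = "") {
  if (is.character(pattern)) pattern <- parse_pattern(pattern, motif_id)
  stopifnot(inherits(pattern, "motif_pattern"))
  pattern$motif_id <- motif_id
  structure(list(motif_id = motif_id, center_class = center_class,
                 pattern = pattern,
                 expected_length_range = length_range(pattern), note = note),
            class = "motif_record")
}

#' @export
print.motif_record <- function(x, ...) {
  cat(sprintf("<motif_record> %s (%s): %s  [expected length %d-%d]\n",
              x$motif_id, x$center_class, render_pattern(x$pattern),
              x$expected_length_range[1], x$expected_length_range[2]))
  invisible(x)
}

#' Scan a proteome with a set of motifs
#'
#' Runs [find_matches()] for every sequence x motif combination, streaming
#' one sequence at a time. Hits are never deduplicated across motifs: a span
#' matching both the GC and AC motifs yields two rows, because the center
#' classes carry distinct biology.
#'
#' @param proteome data.frame from [load_proteome()] (or with columns
#'   `seq_id`, `sequence`).
#' @param motifs list of `motif_record`s (default: all curated motifs).
#' @param mode match mode passed to [find_matches()].
#' @param flank number of context residues captured each side of a hit
#'   (default 5).
#' @return data.frame of hits: `seq_id`, `motif_id`, `center_class`, `start`,
#'   `end`, `length`, `matched_text`, `flank_before`, `flank_after`;
#'   1-based inclusive coordinates, ordered by proteome sequence order, then
#'   start, end and motif_id.
#' @export
scan_proteome <- function(proteome, motifs = builtin_motifs(),
                          mode = c("all_spans", "shortest_per_start"),
                          flank = 5L) {
  mode <- match.arg(mode)
  if (inherits(motifs, "motif_record")) motifs <- list(motifs)
  if (length(motifs) == 0L) stop("no motifs supplied")
  stopifnot(all(c("seq_id", "sequence") %in% names(proteome)))
  out <- list()
  for (i in seq_len(nrow(proteome))) {
    s <- proteome$sequence[i]
    sid <- proteome$seq_id[i]
    for (m in motifs) {
      h <- find_matches(m$pattern, s, mode = mode, seq_id = sid)
      if (nrow(h) == 0L) next
      h$center_class <- m$center_class
      h$length <- h$end - h$start + 1L
      h$flank_before <- substring(s, pmax(1L, h$start - flank), h$start - 1L)
      h$flank_after <- substring(s, h$end + 1L,
                                 pmin(nchar(s), h$end + flank))
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), motif_id = character(),
                      center_class = character(), start = integer(),
                      end = integer(), length = integer(),
                      matched_text = character(), flank_before = character(),
                      flank_after = character(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  ord <- order(match(hits$seq_id, proteome$seq_id), hits$start, hits$end,
               hits$motif_id)
  hits <- hits[ord, c("seq_id", "motif_id", "center_class", "start", "end",
                      "length", "matched_text", "flank_before", "flank_after")]
  rownames(hits) <- NULL
  counts <- table(hits$motif_id)
  message(paste(sprintf("%s: %d hit(s)", names(counts), as.integer(counts)),
                collapse = "; "))
  hits
}

#' Flag the downstream-acidic cation-binding variant of cyclase hits
#'
#' GC and AC centers followed by an acidic residue (D or E) 1-3 positions
#' downstream show higher catalytic activity. For each GC/AC hit the smallest
#' offset in the window with residue `D` or `E` at `end + offset` is recorded
#' in `downstream_acidic_offset` (NA when absent). Hits of other center
#' classes pass through unchanged; sequence-end overruns are handled silently.
#'
#' @param hits hit data.frame from [scan_proteome()].
#' @param proteome the proteome the hits were found in.
#' @param window integer `c(lo, hi)` offsets to inspect; default `c(1, 3)`
#'   (a `c(0, 3)` window is selectable, offset 0 being the motif's final
#'   position itself).
#' @param classes center classes the rule applies to; default GC and AC.
#' @return `hits` with a `downstream_acidic_offset` integer column.
#' @export
annotate_downstream_acidic <- function(hits, proteome, window = c(1L, 3L),
                                       classes = c("GC", "AC")) {
  stopifnot(length(window) == 2L, window[1] >= 0L, window[2] >= window[1])
  seqs <- stats::setNames(proteome$sequence, proteome$seq_id)
  off <- rep(NA_integer_, nrow(hits))
  idx <- which(hits$center_class %in% classes)
  for (i in idx) {
    s <- seqs[[hits$seq_id[i]]]
    for (o in window[1]:window[2]) {
      pos <- hits$end[i] + o
      if (pos < 1L || pos > nchar(s)) next
      if (substr(s, pos, pos) %in% c("D", "E")) { off[i] <- o; break }
    }
  }
  hits$downstream_acidic_offset <- off
  hits
}

#' Export hits as TSV and/or GFF3
#'
#' TSV output carries a commented header recording the tool version, the
#' motif registry checksum, the options used and the coordinate convention
#' (1-based, inclusive ends). GFF3 output (via rtracklayer) uses feature type
#' `protein_match` with motif and score attributes.
#'
#' @param hits hit data.frame (optionally scored/annotated).
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @param motifs motif records used for the scan (for the registry checksum).
#' @param options_note free-text note recorded in the header.
#' @return invisibly, `path`.
#' @export
export_hits <- function(hits, path, format = c("tsv", "gff3"),
                        motifs = NULL, options_note = "") {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# centerscan %s hit table",
              as.character(utils::packageVersion("centerscan"))),
      "# coordinates: 1-based, inclusive ends",
      sprintf("# motif_registry_md5: %s", registry_checksum(motifs)),
      sprintf("# options: %s", options_note)), con)
    utils::write.table(hits, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    if (nrow(hits) == 0L) {
      writeLines("##gff-version 3", path)
      return(invisible(path))
    }
    mc <- S4Vectors::DataFrame(
      source = "centerscan", type = "protein_match",
      score = if ("overall_score" %in% names(hits))
        hits$overall_score else NA_real_,
      ID = sprintf("%s.%s.%d", hits$seq_id, hits$motif_id, hits$start),
      motif_id = hits$motif_id, center_class = hits$center_class,
      matched_text = hits$matched_text)
    gr <- GenomicRanges::GRanges(
      seqnames = hits$seq_id,
      ranges = IRanges::IRanges(start = hits$start, end = hits$end))
    S4Vectors::mcols(gr) <- mc
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

registry_checksum <- function(motifs) {
  if (is.null(motifs)) return("none")
  txt <- vapply(motifs, function(m)
    paste(m$motif_id, m$center_class, render_pattern(m$pattern), sep = "\t"),
    character(1))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Read a hit table written by [export_hits()]
#'
#' @param path TSV path.
#' @return hit data.frame (header comments dropped).
#' @export
read_hits <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export top candidate regions as FASTA for structural assessment
#'
#' Takes the top-ranked hits (the 5-10 best candidates are the usual handoff
#' to homology modeling and docking), pads each hit by `pad` residues on both
#' sides (clipped to the sequence bounds) and writes the regions as FASTA.
#' Headers embed `seq_id|start-end|motif_id|score`.
#'
#' @param hits ranked hit data.frame (best first; see [rank_hits()]).
#' @param proteome the source proteome.
#' @param path output FASTA.
#' @param top_n number of candidates to export (default 10).
#' @param pad flank padding in residues (default 20).
#' @return invisibly, the exported region data.frame.
#' @export
export_candidates <- function(hits, proteome, path, top_n = 10L, pad = 20L) {
  stopifnot(top_n >= 0L, pad >= 0L)
  sel <- utils::head(hits, top_n)
  seqs <- stats::setNames(proteome$sequence, proteome$seq_id)
  if (nrow(sel) == 0L) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(), path)
    return(invisible(sel))
  }
  from <- pmax(1L, sel$start - pad)
  to <- pmin(nchar(seqs[sel$seq_id]), sel$end + pad)
  regions <- substring(seqs[sel$seq_id], from, to)
  score <- if ("overall_score" %in% names(sel))
    sprintf("%.4f", sel$overall_score) else "NA"
  hdr <- sprintf("%s|%d-%d|%s|score=%s", sel$seq_id, from, to, sel$motif_id,
                 score)
  out <- Biostrings::AAStringSet(regions)
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(data.frame(seq_id = sel$seq_id, start = from, end = to,
                       motif_id = sel$motif_id, region = regions,
                       stringsAsFactors = FALSE))
}
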