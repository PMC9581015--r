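# Consensus motif construction from alignments of annotated functional
# centers: highly conserved columns become fixed/class anchors, runs of
# non-conserved columns collapse into ranged wildcard gaps whose bounds are
# the per-row counts of non-gap residues spanned by the run.

#' Default residue grouping scheme for conservation
#'
#' Residues with similar chemistry are pooled when assessing column
#' conservation and (optionally) completing anchor classes: basic `[KR]`,
#' acidic `[DE]`, aliphatic `[ILVM]`, aromatic `[FYW]`, hydroxyl `[ST]`;
#' every other residue is its own group.
#'
#' @return named character vector mapping residue to group label.
#' @export
default_grouping <- function() {
  groups <- list(basic = c("K", "R"), acidic = c("D", "E"),
                 aliphatic = c("I", "L", "V", "M"),
                 aromatic = c("F", "Y", "W"), hydroxyl = c("S", "T"))
  map <- stats::setNames(AA_STANDARD, AA_STANDARD)
  for (g in names(groups)) map[groups[[g]]] <- g
  map
}

#' Construct a center alignment
#'
#' @param rows named character vector (or list) of equal-length aligned
#'   sequences; `-` marks gaps. Names are row identifiers (accession/species).
#' @return a `center_alignment` object.
#' @export
center_alignment <- function(rows) {
  rows <- unlist(rows)
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    names(rows) <- sprintf("row%02d", seq_along(rows))
  rows[] <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]),
                 c(AA_STANDARD, "-"))
  if (length(bad))
    stop("invalid alignment character(s): ", paste(bad, collapse = ", "))
  structure(list(rows = rows, column_count = widths[[1]]),
            class = "center_alignment")
}

#' Read an aligned FASTA of functional centers
#'
#' @param path aligned FASTA file; `-` gaps; rows must share one length.
#' @return a `center_alignment`.
#' @export
read_center_alignment <- function(path) {
  aln <- Biostrings::readAAMultipleAlignment(path, format = "fasta")
  center_alignment(as.character(Biostrings::unmasked(aln)))
}

#' @export
print.center_alignment <- function(x, ...) {
  cat(sprintf("<center_alignment> %d row(s) x %d column(s)\n",
              length(x$rows), x$column_count))
  invisible(x)
}

#' Build parameters for consensus construction
#'
#' @param conservation_threshold fraction of non-gap rows the most frequent
#'   residue (group) must reach for a column to become an anchor; default 0.9.
#' @param grouping named residue-to-group map (see [default_grouping()]), or
#'   NULL to require single-residue conservation.
#' @param force_positions columns always kept as anchors regardless of
#'   conservation (e.g. residues with experimentally proven function).
#' @param length_bounds advisory consensus length bounds; default `c(12, 50)`.
#' @param max_gap_fraction maximum fraction of gap rows an anchor column may
#'   carry; default 0.2.
#' @param group_complete if TRUE, anchor classes are completed with unobserved
#'   members of the winning residue group (e.g. observed `[RK]` stays `[RK]`,
#'   observed `[I]` under the aliphatic group becomes `[ILVM]`); default FALSE,
#'   keeping only observed residues.
#' @param forced_only if TRUE, only `force_positions` become anchors and
#'   conservation is ignored — useful when the key residues are known from
#'   experiment and everything else should collapse into gaps; default FALSE.
#' @return a `build_params` list.
#' @export
build_params <- function(conservation_threshold = 0.9,
                         grouping = default_grouping(),
                         force_positions = integer(),
                         length_bounds = c(12L, 50L),
                         max_gap_fraction = 0.2,
                         group_complete = FALSE,
                         forced_only = FALSE) {
  stopifnot(conservation_threshold > 0, conservation_threshold <= 1,
            length(length_bounds) == 2L, length_bounds[1] >= 1L,
            length_bounds[2] >= length_bounds[1],
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  structure(list(conservation_threshold = conservation_threshold,
                 grouping = grouping,
                 force_positions = as.integer(force_positions),
                 length_bounds = as.integer(length_bounds),
                 max_gap_fraction = max_gap_fraction,
                 group_complete = isTRUE(group_complete),
                 forced_only = isTRUE(forced_only)),
            class = "build_params")
}

#' Per-column residue profile of a center alignment
#'
#' @param a a `center_alignment`.
#' @param grouping residue-to-group map for group conservation (NULL for
#'   single-residue only).
#' @return data.frame with one row per column: `column`, `n_nongap`,
#'   `gap_fraction`, `top_residue`, `residue_conservation` (frequency of the
#'   most common residue among non-gap rows), `top_group`,
#'   `group_conservation`, and `observed` (distinct residues, in order of
#'   first appearance down the column).
#' @export
column_profile <- function(a, grouping = default_grouping()) {
  stopifnot(inherits(a, "center_alignment"))
  mat <- do.call(rbind, strsplit(unname(a$rows), ""))
  nr <- nrow(mat)
  out <- lapply(seq_len(a$column_count), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    n <- length(res)
    if (n == 0L)
      return(data.frame(column = j, n_nongap = 0L, gap_fraction = 1,
                        top_residue = NA_character_, residue_conservation = 0,
                        top_group = NA_character_, group_conservation = 0,
                        observed = "", stringsAsFactors = FALSE))
    tab <- sort(table(res), decreasing = TRUE)
    if (is.null(grouping)) {
      gtab <- tab
    } else {
      gtab <- sort(table(grouping[res]), decreasing = TRUE)
    }
    data.frame(column = j, n_nongap = n, gap_fraction = 1 - n / nr,
               top_residue = names(tab)[1], residue_conservation = tab[[1]] / n,
               top_group = names(gtab)[1], group_conservation = gtab[[1]] / n,
               observed = paste(unique(res), collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build a consensus search motif from a center alignment
#'
#' Columns where the most frequent residue (or residue group) reaches the
#' conservation threshold among non-gap rows — and gaps are rare — become
#' anchors, emitted as a fixed residue or a bracketed class of the residues
#' observed there. Maximal runs of non-anchor columns collapse into one
#' wildcard whose `(min,max)` are the smallest and largest number of non-gap
#' residues any row carries across that run. Leading and trailing non-anchor
#' runs are trimmed. By construction every ungapped input row matches the
#' resulting motif.
#'
#' @param a a `center_alignment` with at least 2 rows (a single row passes
#'   through as a literal pattern).
#' @param params a [build_params()] list.
#' @param motif_id label for the resulting pattern.
#' @return a `motif_pattern`; the per-column decision table is attached as
#'   attribute `"build_report"`. Warns (never errors) when the consensus
#'   length falls outside `params$length_bounds`.
#' @export
#' @examples
#' a <- center_alignment(c(r1 = "HAAY", r2 = "HGCY", r3 = "HQWY"))
#' render_pattern(build_motif(a))  # "Hx(2)Y"
build_motif <- function(a, params = build_params(), motif_id = "consensus") {
  stopifnot(inherits(a, "center_alignment"), inherits(params, "build_params"))
  prof <- column_profile(a, params$grouping)
  conserved <- prof$group_conservation >= params$conservation_threshold &
    prof$gap_fraction <= params$max_gap_fraction & prof$n_nongap > 0L
  anchor <- if (params$forced_only) prof$column %in% params$force_positions
            else conserved | (prof$column %in% params$force_positions)
  if (!any(anchor))
    stop("no anchor column reached conservation threshold ",
         params$conservation_threshold,
         "; lower the threshold or force known key positions")
  prof$anchor <- anchor
  mat <- do.call(rbind, strsplit(unname(a$rows), ""))
  first_a <- min(which(anchor)); last_a <- max(which(anchor))
  elements <- list()
  j <- first_a
  while (j <= last_a) {
    if (anchor[j]) {
      res <- unique(mat[, j][mat[, j] != "-"])
      if (params$group_complete && !is.null(params$grouping)) {
        grp <- params$grouping[res]
        members <- names(params$grouping)[params$grouping %in% grp]
        res <- unique(c(res, members))
      }
      elements[[length(elements) + 1L]] <-
        if (length(res) == 1L) new_pattern_element("fixed", res)
        else new_pattern_element("class", res)
      j <- j + 1L
    } else {
      k <- j
      while (k <= last_a && !anchor[k]) k <- k + 1L
      run <- mat[, j:(k - 1L), drop = FALSE]
      counts <- rowSums(run != "-")
      if (max(counts) > 0L)
        elements[[length(elements) + 1L]] <-
          new_pattern_element("wildcard", character(),
                              min(counts), max(counts))
      j <- k
    }
  }
  p <- new_motif_pattern(motif_id, elements, source_text = NA_character_)
  p$source_text <- render_pattern(p)
  for (w in validate_motif(p, params$length_bounds)) warning(w)
  attr(p, "build_report") <- prof
  p
}

#' Advisory length check for a consensus motif
#'
#' Functional centers typically span 12-50 residues: an overly long consensus
#' reduces the chance of finding candidates, while a short one inflates the
#' false-positive rate. Returns warnings as strings and never blocks.
#'
#' @param p a `motif_pattern`.
#' @param bounds `c(lower, upper)` advisory bounds; default `c(12, 50)`.
#' @return character vector of warning messages (length 0 when within bounds).
#' @export
validate_motif <- function(p, bounds = c(12L, 50L)) {
  rng <- length_range(p)
  out <- character()
  if (rng[1] < bounds[1])
    out <- c(out, sprintf(
      "consensus minimum length %d is below %d: too short; false-positive risk",
      rng[1], bounds[1]))
  if (rng[2] > bounds[2])
    out <- c(out, sprintf(
      "consensus maximum length %d exceeds %d: too long; may miss candidates",
      rng[2], bounds[2]))
  out
}

#' Write a build report as TSV
#'
#' @param p motif from [build_motif()] (carries the `"build_report"`
#'   attribute).
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
write_build_report <- function(p, path) {
  rep <- attr(p, "build_report")
  if (is.null(rep)) stop("pattern carries no build report")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# centerscan build report; pattern: %s",
                     render_pattern(p)), con)
  utils::write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
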