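# Physicochemical screening of candidate centers against experimentally
# validated references: per-feature 0-1 scores (1 = at the reference mean),
# green/amber/red classification and the selection rule "green overall mean,
# at least two green features, no red scores".

cs_tables <- new.env(parent = emptyenv())

load_table <- function(name) {
  if (!is.null(cs_tables[[name]])) return(cs_tables[[name]])
  path <- system.file("extdata", "tables", paste0(name, ".tsv"),
                      package = "centerscan", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cs_tables[[name]] <- tab
  tab
}

#' Physicochemical data tables
#'
#' Returns the shipped residue tables: average residue masses (Da),
#' Kyte-Doolittle hydropathy values and the EMBOSS pKa set used for net
#' charge and isoelectric point.
#'
#' @param which one of `"masses"`, `"hydrophobicity"`, `"pka"`.
#' @return data.frame.
#' @export
physicochemical_table <- function(which = c("masses", "hydrophobicity", "pka")) {
  which <- match.arg(which)
  load_table(switch(which, masses = "residue_masses",
                    hydrophobicity = "hydrophobicity_kd", pka = "pka_emboss"))
}

WATER_MASS <- 18.01528

#' Net charge of a fragment at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and ionizable
#' side chains (K, R, H positive; D, E, C, Y negative) using the shipped
#' EMBOSS pKa table.
#'
#' @param subseq fragment (standard residues; ambiguity codes contribute no
#'   charge).
#' @param pH numeric pH (vectorized).
#' @return net charge in elementary units.
#' @export
net_charge <- function(subseq, pH) {
  pka <- load_table("pka_emboss")
  chars <- strsplit(toupper(subseq), "")[[1]]
  counts <- table(factor(chars, levels = AA_STANDARD))
  vapply(pH, function(ph) {
    z <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      n <- if (g == "Nterm" || g == "Cterm") 1L else as.integer(counts[[g]])
      if (n == 0L) next
      z <- z + if (pka$charge[i] > 0)
        n / (1 + 10^(ph - pka$pka[i]))
      else
        -n / (1 + 10^(pka$pka[i] - ph))
    }
    z
  }, numeric(1))
}

#' Compute the physicochemical feature vector of a fragment
#'
#' Molecular weight (sum of average residue masses plus one water),
#' isoelectric point (bisection root of [net_charge()] on pH 0-14, converged
#' to 1e-6), mean Kyte-Doolittle hydrophobicity (GRAVY) and, as an auxiliary
#' value, the net charge at pH 7. Ambiguity codes are excluded from all
#' averages with a warning; a fragment with no standard residue is an error.
#'
#' @param subseq protein fragment (length >= 1).
#' @return named list: `molecular_weight`, `isoelectric_point`,
#'   `mean_hydrophobicity`, `net_charge_pH7`.
#' @export
#' @examples
#' compute_features("G")$molecular_weight  # free glycine, 75.07 Da
compute_features <- function(subseq) {
  stopifnot(is.character(subseq), length(subseq) == 1L, nchar(subseq) >= 1L)
  chars <- strsplit(toupper(subseq), "")[[1]]
  amb <- chars %in% AA_AMBIGUOUS
  if (any(amb)) {
    warning(sum(amb), " ambiguity code(s) excluded from feature averages")
    chars <- chars[!amb]
  }
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  if (length(chars) == 0L) stop("fragment contains no standard residues")
  frag <- paste(chars, collapse = "")
  masses <- load_table("residue_masses")
  kd <- load_table("hydrophobicity_kd")
  mw <- sum(masses$mass[match(chars, masses$residue)]) + WATER_MASS
  gravy <- mean(kd$hydropathy[match(chars, kd$residue)])
  # bisection: net charge is strictly decreasing in pH
  lo <- 0; hi <- 14
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (net_charge(frag, mid) > 0) lo <- mid else hi <- mid
  }
  list(molecular_weight = mw, isoelectric_point = (lo + hi) / 2,
       mean_hydrophobicity = gravy, net_charge_pH7 = net_charge(frag, 7))
}

SCORED_FEATURES <- c("molecular_weight", "isoelectric_point",
                     "mean_hydrophobicity")

features_matrix <- function(seqs) {
  t(vapply(seqs, function(s) {
    f <- compute_features(s)
    c(molecular_weight = f$molecular_weight,
      isoelectric_point = f$isoelectric_point,
      mean_hydrophobicity = f$mean_hydrophobicity,
      net_charge_pH7 = f$net_charge_pH7)
  }, numeric(4)))
}

#' Reference statistics from validated-center fragments
#'
#' Per-feature mean and standard deviation over the feature vectors of an
#' experimentally validated pool of center sequences; the scoring baseline.
#' The standard deviation is floored at `1e-6 * |mean| + 1e-9` so a single
#' or degenerate reference set still yields finite scores.
#'
#' @param ref_seqs character vector of validated-center fragments (>= 1).
#' @param provenance optional labels of the reference sequences.
#' @return a `reference_stats` list: `mean`, `sd` (named over features),
#'   `n_reference`, `provenance`.
#' @export
reference_stats <- function(ref_seqs, provenance = names(ref_seqs)) {
  ref_seqs <- as.character(ref_seqs)
  if (length(ref_seqs) < 1L) stop("empty reference set")
  fm <- features_matrix(ref_seqs)[, SCORED_FEATURES, drop = FALSE]
  mu <- colMeans(fm)
  sd <- if (nrow(fm) > 1L) apply(fm, 2, stats::sd) else rep(0, ncol(fm))
  floor_eps <- 1e-6 * abs(mu) + 1e-9
  sd <- pmax(sd, floor_eps)
  structure(list(mean = mu, sd = stats::setNames(sd, SCORED_FEATURES),
                 n_reference = length(ref_seqs),
                 provenance = provenance),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> n = %d\n", x$n_reference))
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Score one feature vector against a reference
#'
#' Each feature receives `max(0, 1 - |x - mu| / (c * sigma))`: 1 exactly at
#' the reference mean, falling linearly to 0 at `c` standard deviations.
#' Features classify green (score >= `green`), red (score < `red`) or amber,
#' and a candidate is selected when the overall mean score is green, at least
#' two features are green, and no feature is red.
#'
#' @param f feature list from [compute_features()] (or a named numeric
#'   vector covering the scored features).
#' @param ref a [reference_stats()] object.
#' @param c spread multiplier (> 0, default 3).
#' @param green,red class thresholds (defaults 0.6 and 0.3).
#' @return a `score_card` list: `scores`, `classes`, `overall`,
#'   `overall_class`, `n_green`, `n_red`, `selected`.
#' @export
score_hit <- function(f, ref, c = 3, green = 0.6, red = 0.3) {
  stopifnot(inherits(ref, "reference_stats"), c > 0, red <= green)
  x <- unlist(f)[SCORED_FEATURES]
  sc <- pmax(1 - abs(x - ref$mean) / (c * ref$sd), 0)
  cls <- ifelse(sc >= green, "green", ifelse(sc < red, "red", "amber"))
  overall <- mean(sc)
  overall_class <- if (overall >= green) "green"
                   else if (overall < red) "red" else "amber"
  structure(list(scores = sc, classes = stats::setNames(cls, names(sc)),
                 overall = overall, overall_class = overall_class,
                 n_green = sum(cls == "green"), n_red = sum(cls == "red"),
                 selected = overall_class == "green" &&
                   sum(cls == "green") >= 2L && !any(cls == "red")),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> overall %.3f (%s); %s\n", x$overall,
              x$overall_class, if (x$selected) "SELECTED" else "not selected"))
  print(data.frame(score = round(x$scores, 3), class = x$classes))
  invisible(x)
}

#' Score a hit table against a reference set
#'
#' Computes the feature vector of each matched subsequence and attaches score
#' columns: `score_mw`, `score_pi`, `score_gravy`, `overall_score`,
#' `n_green`, `n_red`, `classification` (class of the overall score),
#' `selected`, plus the raw feature values and `net_charge_pH7`. The
#' downstream-acidic flag, when present, is surfaced as the logical
#' `cation_binding` bonus column; it does not enter the numeric score.
#'
#' @param hits hit data.frame from [scan_proteome()].
#' @param ref a [reference_stats()] object.
#' @inheritParams score_hit
#' @return `hits` with scoring columns appended.
#' @export
score_hits <- function(hits, ref, c = 3, green = 0.6, red = 0.3) {
  if (nrow(hits) == 0L) {
    for (col in c("mw", "pi", "gravy", "net_charge_pH7", "score_mw",
                  "score_pi", "score_gravy", "overall_score"))
      hits[[col]] <- numeric(0)
    hits$n_green <- integer(0); hits$n_red <- integer(0)
    hits$classification <- character(0); hits$selected <- logical(0)
    return(hits)
  }
  cards <- lapply(hits$matched_text, function(s)
    score_hit(compute_features(s), ref, c = c, green = green, red = red))
  fm <- features_matrix(hits$matched_text)
  hits$mw <- fm[, "molecular_weight"]
  hits$pi <- fm[, "isoelectric_point"]
  hits$gravy <- fm[, "mean_hydrophobicity"]
  hits$net_charge_pH7 <- fm[, "net_charge_pH7"]
  hits$score_mw <- vapply(cards, function(x) x$scores[["molecular_weight"]],
                          numeric(1))
  hits$score_pi <- vapply(cards, function(x) x$scores[["isoelectric_point"]],
                          numeric(1))
  hits$score_gravy <- vapply(cards,
                             function(x) x$scores[["mean_hydrophobicity"]],
                             numeric(1))
  hits$overall_score <- vapply(cards, `[[`, numeric(1), "overall")
  hits$n_green <- vapply(cards, `[[`, integer(1), "n_green")
  hits$n_red <- vapply(cards, `[[`, integer(1), "n_red")
  hits$classification <- vapply(cards, `[[`, character(1), "overall_class")
  hits$selected <- vapply(cards, `[[`, logical(1), "selected")
  if ("downstream_acidic_offset" %in% names(hits))
    hits$cation_binding <- !is.na(hits$downstream_acidic_offset)
  hits
}

#' Rank scored hits from high to low confidence
#'
#' Orders by: selected first, then overall score (descending), number of
#' green features (descending), and finally `seq_id` and `start` ascending
#' as a deterministic tie-break.
#'
#' @param hits scored hit data.frame from [score_hits()].
#' @return the reordered data.frame.
#' @export
rank_hits <- function(hits) {
  stopifnot(all(c("overall_score", "n_green", "selected") %in% names(hits)))
  ord <- order(-as.integer(hits$selected), -hits$overall_score,
               -hits$n_green, hits$seq_id, hits$start)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
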