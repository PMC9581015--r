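AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity / non-standard codes kept in sequences; they match wildcards only.
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O")

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so
#' deterministic generators do not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sanitize a protein sequence for matching
#'
#' Upper-cases, truncates at the first `*` stop/terminator and drops alignment
#' gaps `-` (both with a warning). Ambiguity codes (X, B, Z, J, U, O) are kept;
#' they match only wildcard pattern elements. Any other character is an error.
#'
#' @param seq single character string.
#' @param id sequence label used in messages.
#' @return sanitized string.
#' @export
#' @examples
#' sanitize_sequence("mkv")       # "MKV"
#' suppressWarnings(sanitize_sequence("MKV*"))  # "MKV"
sanitize_sequence <- function(seq, id = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  star <- regexpr("*", s, fixed = TRUE)
  if (star > 0L) {
    warning(sprintf("%s: '*' terminator at position %d; sequence truncated", id, star))
    s <- substr(s, 1L, star - 1L)
  }
  if (grepl("-", s, fixed = TRUE)) {
    warning(sprintf("%s: gap characters '-' removed", id))
    s <- gsub("-", "", s, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c(AA_STANDARD, AA_AMBIGUOUS))
  if (length(bad))
    stop(sprintf("%s: invalid residue character(s): %s", id, paste(bad, collapse = ", ")))
  s
}
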