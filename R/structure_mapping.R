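# Projection of per-residue recognition scores onto protein structures via
# the PDB temperature-factor column.

#' Per-residue summed recognition scores for one toxin
#'
#' Residues covered by a recognised core motif receive that peptide series'
#' sum of running-median scores; residues in no core are 0; where cores
#' overlap, a residue carries the maximum of the competing sums. Negative
#' series sums are floored at 0, as only recognised (positive-signal) series
#' are painted.
#'
#' @param epitopes List of epitopes, each a list with elements `core`
#'   (a `core_motif`) and `similar` (the [collect_similar()] table).
#' @param accession Toxin to map.
#' @param length Sequence length of the toxin.
#' @return Numeric vector of length `length` (class `residue_score_map`,
#'   attribute `accession`).
#' @export
residue_scores <- function(epitopes, accession, length) {
  scores <- numeric(length)
  for (ep in epitopes) {
    sim <- ep$similar
    row <- sim[sim$accession == accession & sim$matched, , drop = FALSE]
    if (!nrow(row) || is.na(row$sum[1])) next
    s <- max(row$sum[1], 0)
    span <- row$win_start[1]:row$win_end[1]
    span <- span[span >= 1 & span <= length]
    scores[span] <- pmax(scores[span], s)
  }
  structure(scores, class = "residue_score_map", accession = accession)
}

#' Write residue scores into a PDB temperature-factor column
#'
#' Rewrites the B-factor field (columns 61-66, two decimals) of every ATOM
#' record of the selected chain with the residue's score, linearly rescaled
#' so the maximum score maps to 99.99; every other byte of the file is
#' preserved. Structure residue numbering is related to toxin positions by
#' `toxin_position = pdb_resseq + offset`.
#'
#' @param pdb_in Path to the input PDB file.
#' @param score_map Numeric vector of per-residue scores
#'   (from [residue_scores()]), indexed by toxin position.
#' @param pdb_out Output path.
#' @param chain Chain identifier to paint (default `"A"`); other chains are
#'   left untouched.
#' @param offset Integer added to PDB residue numbers to obtain toxin
#'   positions (default 0).
#' @return Invisibly, the rescaled scores actually written (named by PDB
#'   residue number).
#' @export
write_scored_structure <- function(pdb_in, score_map, pdb_out, chain = "A",
                                   offset = 0L) {
  lines <- readLines(pdb_in)
  is_atom <- startsWith(lines, "ATOM  ")
  if (!any(is_atom)) stop("no ATOM records in ", pdb_in, call. = FALSE)
  if (any(nchar(lines[is_atom]) < 66L)) {
    stop("malformed ATOM record (shorter than 66 columns)", call. = FALSE)
  }
  max_score <- max(score_map, 0)
  scale <- if (max_score > 0) 99.99 / max_score else 0
  written <- numeric(0)
  unmapped <- integer(0)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (substr(ln, 22L, 22L) != chain) next
    resseq <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
    if (is.na(resseq)) stop("malformed residue number in ATOM record", call. = FALSE)
    pos <- resseq + as.integer(offset)
    if (pos < 1L || pos > length(score_map)) {
      unmapped <- c(unmapped, resseq)
      b <- 0
    } else {
      b <- score_map[pos] * scale
    }
    substr(ln, 61L, 66L) <- sprintf("%6.2f", b)
    lines[i] <- ln
    written[as.character(resseq)] <- b
  }
  if (length(unique(unmapped))) {
    warning("residues outside the score map left at 0: ",
            paste(sort(unique(unmapped)), collapse = ", "))
  }
  writeLines(lines, pdb_out)
  invisible(written)
}
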