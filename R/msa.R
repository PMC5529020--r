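# Multiple-sequence-alignment input and profile-to-alignment anchoring.
# Alignments are consumed, not computed; gap character is "-".

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Clustal formats; format is guessed from the file
#' content when not given.
#'
#' @param path File path.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @return Named character vector of equal-length aligned sequences, upper
#'   case, with `-` as the gap character.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    aln <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(aln))
    names(seqs) <- sub("\\s.*$", "", names(aln))
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal", oldclustal = TRUE)
    seqs <- toupper(unlist(aln$seq))
    names(seqs) <- aln$nam
  }
  seqs <- gsub("[.]", "-", seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  seqs
}

ungap <- function(aligned) gsub("-", "", aligned, fixed = TRUE)

# Alignment column of each residue (ungapped position) of one aligned row.
residue_columns <- function(aligned_row) {
  which(strsplit(aligned_row, "")[[1]] != "-")
}

#' Anchor running-median profiles to a multiple sequence alignment
#'
#' Places the score of the 15-mer starting at ungapped position i at the
#' alignment column of residue i; gap columns carry no value, and the last
#' k - 1 residues of every toxin carry no score (no 15-mer starts there).
#'
#' @param profiles Named list of `signal_profile` objects; every accession
#'   must appear in the alignment. Alignment rows without a profile are kept
#'   (all-NA score rows) so that similarity scans can still see their
#'   sequences.
#' @param msa Named character vector from [read_msa()] (or built in code).
#' @param toxins Optional toxin set; when given, each alignment row is checked
#'   to ungap to the toxin's sequence.
#' @param k Peptide length (default 15).
#' @return Object of class `aligned_profile`: list with `msa` (rows restricted
#'   to profiled + unprofiled accessions, original order), `scores` (matrix,
#'   rows = accessions, columns = alignment columns, NA where no value) and
#'   `k`.
#' @export
map_profiles_to_msa <- function(profiles, msa, toxins = NULL, k = 15L) {
  accs <- names(msa)
  missing <- setdiff(names(profiles), accs)
  if (length(missing)) {
    stop("profile accession not in alignment: ", missing[1], call. = FALSE)
  }
  ncol_aln <- nchar(msa[[1]])
  scores <- matrix(NA_real_, nrow = length(accs), ncol = ncol_aln,
                   dimnames = list(accs, NULL))
  for (acc in accs) {
    bare <- ungap(msa[[acc]])
    if (!is.null(toxins)) {
      ref <- toxins$sequence[match(acc, toxins$accession)]
      if (!is.na(ref) && !identical(bare, ref)) {
        stop("alignment row does not ungap to sequence of ", acc, call. = FALSE)
      }
    }
    p <- profiles[[acc]]
    if (is.null(p)) next
    n_win <- nchar(bare) - k + 1L
    if (length(p$score) != n_win) {
      stop("profile length mismatch for ", acc, call. = FALSE)
    }
    cols <- residue_columns(msa[[acc]])
    if (n_win > 0L) scores[acc, cols[seq_len(n_win)]] <- p$score
  }
  structure(list(msa = msa, scores = scores, k = as.integer(k)),
            class = "aligned_profile")
}

#' Export an aligned profile as long-format plot data
#'
#' One row per (accession, alignment column) with a residue; used to
#' reproduce aligned signal-profile panels.
#'
#' @param aligned An `aligned_profile`.
#' @return data.frame with accession, column, position (ungapped), residue,
#'   score (NA where no 15-mer starts).
#' @export
aligned_profile_table <- function(aligned) {
  rows <- lapply(names(aligned$msa), function(acc) {
    cols <- residue_columns(aligned$msa[[acc]])
    chars <- strsplit(aligned$msa[[acc]], "")[[1]]
    data.frame(accession = acc, column = cols,
               position = seq_along(cols), residue = chars[cols],
               score = aligned$scores[acc, cols],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
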