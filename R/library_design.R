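# Peptide library design: sequence sanitisation, overlapping-window tiling,
# deduplication, and randomised replicate array layout with corner controls.

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AMBIGUOUS_AA <- c("X", "B", "Z", "J", "U", "O")

#' Corner-control peptide sequence
#'
#' A lysine/arginine-rich 15-mer highly prone to unspecific antibody binding,
#' replicated across the array; its empirical signal distributions in the two
#' recordings define the null model for significance calling.
#' @export
CORNER_PEPTIDE <- "KKKRKKKRKKKRKKK"

#' Replace ambiguous residues with glycine
#'
#' Unspecified or ambiguous residue codes (X, B, Z, J, U, O) are replaced by
#' glycine so that every peptide in the library is synthesisable over the 20
#' standard amino acids. Standard residues are unchanged and length is
#' preserved.
#'
#' @param raw Upper-case amino-acid string, possibly containing ambiguity
#'   codes.
#' @return Sanitised amino-acid string over the 20 standard letters.
#' @examples
#' sanitize_sequence("ACDX") # "ACDG"
#' @export
sanitize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("`raw` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(raw, "")[[1]]
  bad <- which(!chars %in% c(LETTERS))
  if (length(bad)) {
    stop(sprintf("non-letter character '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  chars[chars %in% AMBIGUOUS_AA] <- "G"
  nonstd <- which(!chars %in% STANDARD_AA)
  if (length(nonstd)) {
    # remaining letters that are neither standard nor recognised ambiguity codes
    stop(sprintf("unrecognised residue '%s' at position %d", chars[nonstd[1]], nonstd[1]),
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a toxin record set
#'
#' Bundles protein sequences with identity metadata into the data.frame the
#' rest of the pipeline consumes. Sequences are sanitised
#' (see [sanitize_sequence()]) and accessions must be unique.
#'
#' @param accession Character vector of unique sequence identifiers.
#' @param sequence Amino-acid sequences (upper case).
#' @param species,family,subgroup Optional metadata vectors (recycled scalars
#'   allowed).
#' @param is_partial Logical; whether each record covers only part of the
#'   mature protein.
#' @return A `data.frame` with columns accession, species, family, subgroup,
#'   is_partial, sequence.
#' @export
toxin_set <- function(accession, sequence, species = NA_character_,
                      family = NA_character_, subgroup = NA_character_,
                      is_partial = FALSE) {
  if (anyDuplicated(accession)) {
    stop("duplicate accession: ", accession[duplicated(accession)][1], call. = FALSE)
  }
  sequence <- vapply(as.character(sequence), sanitize_sequence, character(1),
                     USE.NAMES = FALSE)
  data.frame(
    accession = as.character(accession),
    species = rep_len(as.character(species), length(accession)),
    family = rep_len(as.character(family), length(accession)),
    subgroup = rep_len(as.character(subgroup), length(accession)),
    is_partial = rep_len(as.logical(is_partial), length(accession)),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
}

#' Tile a sequence into overlapping peptides
#'
#' Slides a window of length `k` along the sequence with single-residue
#' displacement (overlap `k - 1`), so a sequence of length L yields
#' max(L - k + 1, 0) peptides in N-to-C order; the peptide starting at
#' position i (1-based, N-terminal residue) is tile i.
#'
#' @param sequence Sanitised amino-acid string.
#' @param k Window length (default 15).
#' @return Character vector of tiles; empty for sequences shorter than `k`.
#' @export
tile_sequence <- function(sequence, k = 15L) {
  L <- nchar(sequence)
  n <- max(L - k + 1L, 0L)
  if (n == 0L) return(character(0))
  starts <- seq_len(n)
  substring(sequence, starts, starts + k - 1L)
}

#' Build a deduplicated peptide library
#'
#' Tiles every toxin into overlapping `k`-mers and curates the set for
#' redundant (non-unique) peptide sequences: each distinct peptide string is
#' kept once, with the union of all (accession, start) origins that produce
#' it.
#'
#' @param toxins Toxin set from [toxin_set()].
#' @param k Peptide length (default 15).
#' @return An object of class `peptide_library`: list with `peptides` (unique
#'   peptide strings, in order of first occurrence), `origins` (data.frame
#'   peptide/accession/start), `k` and `overlap`.
#' @export
build_library <- function(toxins, k = 15L) {
  stopifnot(is.data.frame(toxins), all(c("accession", "sequence") %in% names(toxins)))
  if (anyDuplicated(toxins$accession)) {
    stop("duplicate accession: ",
         toxins$accession[duplicated(toxins$accession)][1], call. = FALSE)
  }
  per <- lapply(seq_len(nrow(toxins)), function(i) {
    tiles <- tile_sequence(toxins$sequence[i], k = k)
    if (!length(tiles)) return(NULL)
    data.frame(peptide = tiles, accession = toxins$accession[i],
               start = seq_along(tiles), stringsAsFactors = FALSE)
  })
  origins <- do.call(rbind, per)
  if (is.null(origins)) {
    origins <- data.frame(peptide = character(0), accession = character(0),
                          start = integer(0))
  }
  structure(
    list(peptides = unique(origins$peptide), origins = origins,
         k = as.integer(k), overlap = as.integer(k) - 1L),
    class = "peptide_library"
  )
}

#' @export
print.peptide_library <- function(x, ...) {
  cat(sprintf("peptide_library: %d unique %d-mers from %d window positions (%d toxins)\n",
              length(x$peptides), x$k, nrow(x$origins),
              length(unique(x$origins$accession))))
  invisible(x)
}

#' Assign peptides to randomised array fields
#'
#' Every unique library peptide is placed in `replicates` fields and the
#' corner-control peptide in `corner_field_count` fields; field order is a
#' seeded random permutation of all placements, emulating random positioning
#' to minimise local intensity biases. Grid geometry is abstracted to a flat
#' field list; corner-ness is a flag.
#'
#' @param library A `peptide_library`.
#' @param replicates Fields per unique peptide (default 5).
#' @param corner_field_count Fields carrying the corner peptide (default 852).
#' @param seed Integer seed recorded in the layout.
#' @param corner_peptide Control peptide string (default [CORNER_PEPTIDE]).
#' @return An object of class `array_layout`: data.frame with columns
#'   field_id, peptide, is_corner_control, plus attributes `replicates`,
#'   `corner_peptide`, `corner_field_count`, `seed`.
#' @export
assign_layout <- function(library, replicates = 5L, corner_field_count = 852L,
                          seed = 1L, corner_peptide = CORNER_PEPTIDE) {
  stopifnot(inherits(library, "peptide_library"), replicates >= 1L,
            corner_field_count >= 0L)
  peptide <- c(rep(library$peptides, each = replicates),
               rep(corner_peptide, corner_field_count))
  corner <- c(rep(FALSE, length(library$peptides) * replicates),
              rep(TRUE, corner_field_count))
  perm <- with_seed(seed, sample.int(length(peptide)))
  layout <- data.frame(
    field_id = seq_along(peptide),
    peptide = peptide[perm],
    is_corner_control = corner[perm],
    stringsAsFactors = FALSE
  )
  attr(layout, "replicates") <- as.integer(replicates)
  attr(layout, "corner_peptide") <- corner_peptide
  attr(layout, "corner_field_count") <- as.integer(corner_field_count)
  attr(layout, "seed") <- as.integer(seed)
  class(layout) <- c("array_layout", "data.frame")
  layout
}
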