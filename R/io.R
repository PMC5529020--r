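# Readers and writers for the pipeline's external formats: FASTA + metadata
# sidecar, tab-separated library/layout/intensity/result tables.

#' Read toxin sequences with a metadata sidecar
#'
#' @param fasta Path to a FASTA file of amino-acid sequences; record ids up
#'   to the first whitespace are the accessions.
#' @param meta Optional path to a tab-separated sidecar with columns
#'   accession, species, family, subgroup, is_partial.
#' @return Toxin set data.frame (see [toxin_set()]); sequences are sanitised.
#' @export
read_toxins <- function(fasta, meta = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  acc <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  tox <- toxin_set(acc, seqs)
  if (!is.null(meta)) {
    md <- read.delim(meta, stringsAsFactors = FALSE)
    i <- match(tox$accession, md$accession)
    for (col in c("species", "family", "subgroup")) {
      if (col %in% names(md)) tox[[col]] <- as.character(md[[col]])[i]
    }
    if ("is_partial" %in% names(md)) tox$is_partial <- as.logical(md$is_partial)[i]
  }
  tox
}

#' Write a toxin set as FASTA plus metadata sidecar
#'
#' @param toxins Toxin set data.frame.
#' @param fasta,meta Output paths.
#' @return Invisibly, `fasta`.
#' @export
write_toxins <- function(toxins, fasta, meta = NULL) {
  con <- file(fasta, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(toxins))) {
    writeLines(c(paste0(">", toxins$accession[i]), toxins$sequence[i]), con)
  }
  if (!is.null(meta)) {
    write_tsv(toxins[, c("accession", "species", "family", "subgroup",
                         "is_partial")], meta)
  }
  invisible(fasta)
}

#' Write a tab-separated table with header
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated intensity table
#' @param path Path to a TSV with columns field_id, peptide, intensity.
#' @return data.frame.
#' @export
read_intensities <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("field_id", "peptide", "intensity")
  if (!all(need %in% names(tab))) {
    stop("intensity table must have columns field_id, peptide, intensity",
         call. = FALSE)
  }
  tab
}

#' Write a peptide library as TSV
#'
#' One row per unique peptide with its origins serialised as
#' `accession:start` pairs separated by `;`.
#' @param library A `peptide_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(library, path) {
  org <- split(paste0(library$origins$accession, ":", library$origins$start),
               library$origins$peptide)
  df <- data.frame(
    peptide = library$peptides,
    origins = vapply(org[library$peptides], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write an array layout as TSV
#' @param layout An `array_layout`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  write_tsv(as.data.frame(layout)[, c("field_id", "peptide", "is_corner_control")],
            path)
}

#' Read an array layout TSV
#' @param path Path written by [write_layout()].
#' @param replicates,corner_field_count,seed Layout attributes to restore.
#' @return An `array_layout`.
#' @export
read_layout <- function(path, replicates = 5L, corner_field_count = NULL,
                        seed = NA_integer_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_corner_control <- as.logical(df$is_corner_control)
  attr(df, "replicates") <- as.integer(replicates)
  attr(df, "corner_peptide") <- if (any(df$is_corner_control))
    df$peptide[df$is_corner_control][1] else CORNER_PEPTIDE
  attr(df, "corner_field_count") <-
    as.integer(corner_field_count %||% sum(df$is_corner_control))
  attr(df, "seed") <- as.integer(seed)
  class(df) <- c("array_layout", "data.frame")
  df
}
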