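# Signal processing: replicate medians, re-incubation estimation and removal,
# running-median score profiles per toxin.

#' Collapse replicate fields to per-peptide channel medians
#'
#' The median signal of the replicate fields of each peptide is determined in
#' both recordings, which suppresses single-field outliers. Corner-control
#' fields are excluded from peptide medians and returned separately as the two
#' empirical control distributions used for re-incubation estimation and
#' bootstrap calibration.
#'
#' @param background,antivenom Intensity tables (data.frames with columns
#'   field_id, peptide, intensity), one row per field.
#' @param layout The `array_layout` the tables were recorded on.
#' @return List with `signal` (data.frame peptide/background_median/
#'   antivenom_median), `corner_background` and `corner_antivenom` (numeric
#'   vectors of corner-field intensities).
#' @export
replicate_median <- function(background, antivenom, layout) {
  stopifnot(inherits(layout, "array_layout"))
  for (tab in list(background, antivenom)) {
    stopifnot(all(c("field_id", "peptide", "intensity") %in% names(tab)))
  }
  corner_ids <- layout$field_id[layout$is_corner_control]
  peptides <- unique(layout$peptide[!layout$is_corner_control])

  channel_medians <- function(tab) {
    tab <- tab[!tab$field_id %in% corner_ids, , drop = FALSE]
    missing <- setdiff(peptides, tab$peptide)
    if (length(missing)) {
      stop("peptide missing from intensity table: ", missing[1], call. = FALSE)
    }
    med <- vapply(split(tab$intensity, tab$peptide), median, numeric(1))
    med[peptides]
  }
  corner_values <- function(tab) tab$intensity[tab$field_id %in% corner_ids]

  list(
    signal = data.frame(
      peptide = peptides,
      background_median = unname(channel_medians(background)),
      antivenom_median = unname(channel_medians(antivenom)),
      stringsAsFactors = FALSE
    ),
    corner_background = corner_values(background),
    corner_antivenom = corner_values(antivenom)
  )
}

#' Estimate the re-incubation factor from corner-control signals
#'
#' The second (antivenom) incubation inflates signals of peptides prone to
#' unspecific binding; the inflation is estimated as the ratio of the median
#' corner-control signal in the antivenom recording to that in the background
#' recording, and is applied multiplicatively when correcting signals.
#'
#' @param corner_background,corner_antivenom Numeric vectors of corner-field
#'   intensities from the two recordings.
#' @return Dimensionless factor (> 0).
#' @export
estimate_reincubation <- function(corner_background, corner_antivenom) {
  if (!length(corner_background) || !length(corner_antivenom)) {
    stop("corner-control distributions must be non-empty", call. = FALSE)
  }
  mb <- median(corner_background)
  if (mb <= 0) stop("median corner background signal must be positive", call. = FALSE)
  median(corner_antivenom) / mb
}

#' Background-correct antivenom medians
#'
#' Corrected score = antivenom median minus the background median multiplied
#' by the re-incubation factor. Scores may be negative; no clamping is applied
#' so the null distribution keeps its full shape.
#'
#' @param antivenom_median,background_median Numeric vectors (recycled).
#' @param factor Re-incubation factor (> 0).
#' @return Corrected scores in the same fluorescence units.
#' @export
correct_signal <- function(antivenom_median, background_median, factor) {
  stopifnot(factor > 0)
  antivenom_median - factor * background_median
}

#' Three-point running median of a score profile
#'
#' Each interior position is replaced by the median of itself and its nearest
#' preceding and subsequent overlapping peptide; terminal positions use the
#' median of the two available values (their mean), preserving profile
#' length.
#'
#' @param x Numeric vector of corrected scores indexed by 15-mer N-terminal
#'   position.
#' @return Numeric vector of the same length.
#' @export
running_median <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  if (n == 2L) return(c(mean(x), mean(x)))
  mid <- median3(x[1:(n - 2L)], x[2:(n - 1L)], x[3:n])
  c((x[1L] + x[2L]) / 2, mid, (x[n - 1L] + x[n]) / 2)
}

#' Map corrected peptide scores onto toxins as running-median profiles
#'
#' Each toxin's profile holds, at index i (the N-terminal position of the
#' 15-mer starting at residue i), the corrected score of that peptide; a
#' peptide shared by several toxins contributes its single score at every
#' origin. Profiles are then smoothed with [running_median()].
#'
#' @param signal Per-peptide signal data.frame from [replicate_median()]
#'   with an added `corrected` column, or any data.frame with columns
#'   `peptide` and `corrected`.
#' @param toxins Toxin set covering the peptides.
#' @param k Peptide length (default 15).
#' @return Named list (by accession) of `signal_profile` objects: lists with
#'   `accession`, `raw` (corrected scores) and `score` (running medians),
#'   both of length L - k + 1.
#' @export
map_to_toxins <- function(signal, toxins, k = 15L) {
  stopifnot(all(c("peptide", "corrected") %in% names(signal)))
  score_of <- setNames(signal$corrected, signal$peptide)
  profiles <- lapply(seq_len(nrow(toxins)), function(i) {
    tiles <- tile_sequence(toxins$sequence[i], k = k)
    if (!length(tiles)) return(NULL)
    raw <- unname(score_of[tiles])
    if (anyNA(raw)) {
      stop("no signal for peptide ", tiles[which(is.na(raw))[1]],
           " of ", toxins$accession[i], call. = FALSE)
    }
    structure(list(accession = toxins$accession[i], raw = raw,
                   score = running_median(raw)),
              class = "signal_profile")
  })
  names(profiles) <- toxins$accession
  profiles[!vapply(profiles, is.null, logical(1))]
}
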