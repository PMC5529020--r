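# Epitope-segment detection, core-motif extraction and mismatch-tolerant
# per-toxin score aggregation on alignment-anchored profiles.

#' Find alignment segments recognised across many toxins
#'
#' A column qualifies when at least `min_share` toxins have a score at or
#' above the significance threshold there; segments are the maximal runs of
#' qualifying columns (intervals separated by zero qualifying columns are
#' distinct segments). For each segment the member toxins (those with at
#' least one above-threshold score inside it) and their peak scores are
#' recorded.
#'
#' @param aligned An `aligned_profile` from [map_profiles_to_msa()].
#' @param threshold Significance score threshold (finite).
#' @param min_share Minimum number of sharing toxins per column (default 10).
#' @return List of `epitope_segment` objects: lists with `start`, `end`
#'   (alignment columns, inclusive), `members` (accessions) and `peaks`
#'   (named per-member maximum score in the segment); ordered by column.
#' @export
find_shared_segments <- function(aligned, threshold, min_share = 10L) {
  stopifnot(inherits(aligned, "aligned_profile"), is.finite(threshold))
  above <- !is.na(aligned$scores) & aligned$scores >= threshold
  qualifying <- colSums(above) >= min_share
  runs <- true_runs(qualifying)
  lapply(seq_len(nrow(runs)), function(i) {
    cols <- runs$start[i]:runs$end[i]
    block <- above[, cols, drop = FALSE]
    members <- rownames(block)[rowSums(block) > 0L]
    peaks <- vapply(members, function(acc) {
      max(aligned$scores[acc, cols], na.rm = TRUE)
    }, numeric(1))
    structure(list(start = runs$start[i], end = runs$end[i],
                   members = members, peaks = peaks),
              class = "epitope_segment")
  })
}

#' Extract the core motif of an epitope segment
#'
#' The member toxin with the highest peak (ties broken by accession order)
#' anchors the motif: its maximal run of consecutive significant 15-mers
#' overlapping the segment is collected, and the core is the residue window
#' shared by all 15-mers of the run — the intersection window, of length
#' 15 - (run length - 1). When the toxin has several such runs, the one
#' containing its peak is used.
#'
#' @param segment An `epitope_segment`.
#' @param aligned The `aligned_profile` the segment was found in.
#' @param profiles The profile list used to build `aligned`.
#' @param threshold Significance score threshold.
#' @return Object of class `core_motif`: list with `core` (residue string),
#'   `accession` (anchor toxin), `start`, `end` (ungapped positions of the
#'   core in the anchor), `columns` (alignment columns of the core residues),
#'   `run` (start/end profile positions of the peptide run) and `run_length`.
#' @export
extract_core_motif <- function(segment, aligned, profiles, threshold) {
  stopifnot(inherits(segment, "epitope_segment"), length(segment$members) > 0L)
  k <- aligned$k
  ord <- order(-segment$peaks, segment$members)
  top <- segment$members[ord[1L]]
  prof <- profiles[[top]]
  row <- aligned$msa[[top]]
  cols <- residue_columns(row)
  seqc <- ungap(row)
  n_win <- length(prof$score)
  # windows overlapping the segment: any residue column within [start, end]
  overlaps <- vapply(seq_len(n_win), function(i) {
    wc <- cols[i:(i + k - 1L)]
    any(wc >= segment$start & wc <= segment$end)
  }, logical(1))
  sig <- prof$score >= threshold & overlaps
  runs <- true_runs(sig)
  if (!nrow(runs)) stop("anchor toxin has no significant run in segment", call. = FALSE)
  peak_pos <- which(sig)[which.max(prof$score[sig])]
  hit <- which(runs$start <= peak_pos & runs$end >= peak_pos)[1L]
  p1 <- runs$start[hit]; p2 <- runs$end[hit]
  core_start <- p2
  core_end <- p1 + k - 1L
  structure(
    list(core = substr(seqc, core_start, core_end), accession = top,
         start = core_start, end = core_end,
         columns = cols[core_start:core_end],
         run = c(start = p1, end = p2), run_length = p2 - p1 + 1L),
    class = "core_motif"
  )
}

#' @export
print.core_motif <- function(x, ...) {
  cat(sprintf("core_motif '%s' (anchor %s, residues %d-%d, run of %d peptides)\n",
              x$core, x$accession, x$start, x$end, x$run_length))
  invisible(x)
}

# Hamming distance between equal-length strings; any differing symbol
# (including a gap) counts one mismatch.
hamming_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("unequal lengths", call. = FALSE)
  sum(ca != cb)
}

#' Sum scores of 15-mers carrying a similar core across toxins
#'
#' For every alignment row, the residues at the core's alignment columns are
#' compared with the core; a toxin matches when no more than `max_mismatch`
#' residues differ (gaps count as mismatches). For matching toxins the
#' running-median scores of all 15-mers containing the matched window are
#' summed. Comparison is anchored at the core's alignment columns, not by
#' free sliding.
#'
#' @param core A `core_motif`.
#' @param aligned The `aligned_profile`.
#' @param profiles Profile list (by accession).
#' @param max_mismatch Maximum residue differences (default 3).
#' @return data.frame with one row per alignment row: accession, core_seq
#'   (residues at the core columns, `-` for gaps), distance, matched,
#'   win_start, win_end (ungapped window in the toxin; NA if unmatched),
#'   n_peptides and sum (NA if unmatched).
#' @export
collect_similar <- function(core, aligned, profiles, max_mismatch = 3L) {
  stopifnot(inherits(core, "core_motif"), max_mismatch >= 0L)
  k <- aligned$k
  rows <- lapply(names(aligned$msa), function(acc) {
    chars <- strsplit(aligned$msa[[acc]], "")[[1]]
    sub <- chars[core$columns]
    core_seq <- paste(sub, collapse = "")
    dist <- sum(sub != strsplit(core$core, "")[[1]])
    matched <- dist <= max_mismatch && any(sub != "-")
    win_start <- win_end <- NA_integer_
    n_pep <- 0L
    s <- NA_real_
    prof <- profiles[[acc]]
    if (matched && !is.null(prof)) {
      pos_map <- cumsum(chars != "-")
      res_pos <- pos_map[core$columns][sub != "-"]
      win_start <- min(res_pos); win_end <- max(res_pos)
      L <- sum(chars != "-")
      starts <- max(1L, win_end - k + 1L):min(win_start, L - k + 1L)
      starts <- starts[starts >= 1L & starts <= L - k + 1L &
                         starts <= win_start & starts + k - 1L >= win_end]
      n_pep <- length(starts)
      s <- if (n_pep) sum(prof$score[starts]) else NA_real_
    }
    data.frame(accession = acc, core_seq = core_seq, distance = dist,
               matched = matched, win_start = win_start, win_end = win_end,
               n_peptides = n_pep, sum = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
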