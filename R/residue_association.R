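# Sequence-logo matrices (Shannon information) and rank-based
# residue-association Z-scores linking residue presence at alignment
# positions to per-toxin binding-score sums.

LOGO_MAX_BITS <- log2(20)

#' Shannon sequence-logo matrix
#'
#' Per-position residue frequencies (gaps excluded) and information content
#' in bits, information = log2(20) - Shannon entropy of the frequencies.
#' Letter heights are frequency times position information, the standard
#' Shannon-logo scaling.
#'
#' @param sequences Character vector of equal-length (aligned) sequences;
#'   `-` is the gap symbol.
#' @return Object of class `logo_matrix`: list with `freq` (positions x 20
#'   residues), `info` (bits per position), `height` (freq * info) and `n`.
#' @export
logo_matrix <- function(sequences) {
  if (!length(sequences)) stop("no sequences", call. = FALSE)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must have equal length", call. = FALSE)
  L <- lens
  chars <- do.call(rbind, strsplit(sequences, ""))
  freq <- matrix(0, nrow = L, ncol = length(STANDARD_AA),
                 dimnames = list(NULL, STANDARD_AA))
  info <- numeric(L)
  for (p in seq_len(L)) {
    col <- chars[, p]
    col <- col[col != "-"]
    if (!length(col)) next
    tab <- table(factor(col, levels = STANDARD_AA))
    f <- as.numeric(tab) / length(col)
    freq[p, ] <- f
    nz <- f[f > 0]
    info[p] <- LOGO_MAX_BITS + sum(nz * log2(nz))
  }
  structure(list(freq = freq, info = info, height = freq * info,
                 n = length(sequences)),
            class = "logo_matrix")
}

#' Rank-based residue-association Z-scores
#'
#' Sequences are ranked by their binding-score sums (average ranks on ties,
#' ranks ascending with score). For residue r at position p, present in n_r
#' of N sequences, the Wilcoxon rank-sum Z-score
#' \deqn{Z = (W - n_r (N+1)/2) / \sqrt{n_r (N - n_r)(N+1)/12}}
#' with W the rank-sum of the carriers, so a positive Z associates the
#' residue with high binding. Fully conserved or absent residues get no Z
#' (a conserved residue sits both at the top and the bottom of the ranking
#' and cannot associate either way). Gaps are a 21st category: a gap at a
#' position can itself associate with low binding.
#'
#' @param sequences Equal-length (aligned) sequence windows, one per toxin.
#' @param sums Numeric binding-score sums, one per sequence.
#' @return Object of class `residue_association`: list with `z` (positions x
#'   21 symbols, NA where undefined), `n_carriers` (same shape), `N`.
#' @export
residue_zscores <- function(sequences, sums) {
  N <- length(sequences)
  if (N < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (length(sums) != N) stop("one sum per sequence required", call. = FALSE)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must have equal length", call. = FALSE)
  symbols <- c(STANDARD_AA, "-")
  L <- lens
  chars <- do.call(rbind, strsplit(sequences, ""))
  z <- n_carriers <- matrix(NA_real_, nrow = L, ncol = length(symbols),
                            dimnames = list(NULL, symbols))
  degenerate <- length(unique(sums)) == 1L
  if (degenerate) {
    warning("constant score sums: all association Z-scores undefined")
  }
  ranks <- rank(sums)
  for (p in seq_len(L)) {
    for (r in unique(chars[, p])) {
      carriers <- chars[, p] == r
      n_r <- sum(carriers)
      n_carriers[p, r] <- n_r
      if (degenerate || n_r == 0L || n_r == N) next
      W <- sum(ranks[carriers])
      z[p, r] <- (W - n_r * (N + 1) / 2) /
        sqrt(n_r * (N - n_r) * (N + 1) / 12)
    }
  }
  structure(list(z = z, n_carriers = n_carriers, N = N),
            class = "residue_association")
}

#' Significance mask for a residue-association matrix
#'
#' Two-sided normal p-values of the defined Z-scores, Benjamini-Hochberg
#' corrected across all defined (position, residue) pairs; masked entries
#' pass the corrected level `alpha`.
#'
#' @param assoc A `residue_association` from [residue_zscores()].
#' @param alpha Significance level after correction (default 0.05).
#' @return Logical matrix of the same shape as `assoc$z` (FALSE where Z is
#'   undefined).
#' @export
significance_mask <- function(assoc, alpha = 0.05) {
  stopifnot(inherits(assoc, "residue_association"))
  z <- assoc$z
  defined <- which(!is.na(z))
  mask <- matrix(FALSE, nrow = nrow(z), ncol = ncol(z),
                 dimnames = dimnames(z))
  if (!length(defined)) return(mask)
  p <- 2 * pnorm(-abs(z[defined]))
  mask[defined] <- p.adjust(p, method = "BH") <= alpha
  mask
}

#' Long-format association table
#'
#' @param assoc A `residue_association`.
#' @param alpha Level passed to [significance_mask()].
#' @return data.frame position, residue, z, n_carriers, significant.
#' @export
association_table <- function(assoc, alpha = 0.05) {
  mask <- significance_mask(assoc, alpha)
  idx <- which(!is.na(assoc$z), arr.ind = TRUE)
  data.frame(
    position = idx[, 1],
    residue = colnames(assoc$z)[idx[, 2]],
    z = assoc$z[idx],
    n_carriers = assoc$n_carriers[idx],
    significant = mask[idx],
    stringsAsFactors = FALSE
  )
}
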