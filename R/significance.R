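# Significance calling: bootstrap null calibration from corner-control
# distributions, one-sided Z-tests, Benjamini-Hochberg FDR, and the
# two-successive-peptide recognition rule.

#' Bootstrap standard deviation of the null running-median score
#'
#' Estimates the spread of the background-corrected running-median score of a
#' random (unspecifically binding) peptide by pushing resampled corner-control
#' intensities through the identical pipeline transformations: per repetition,
#' three neighbouring pseudo-peptides each receive `replicates` draws with
#' replacement from both empirical corner distributions; channel medians are
#' formed, corrected with the re-incubation factor, and the three corrected
#' scores are collapsed by the 3-window running median (the centre value).
#' Sigma is the standard deviation over all repetitions. The corner peptide's
#' high unspecific binding makes this a conservative null width.
#'
#' @param corner_background,corner_antivenom Empirical corner-field intensity
#'   distributions.
#' @param factor Re-incubation factor.
#' @param n_boot Bootstrap repetitions (default 50,000).
#' @param replicates Draws per pseudo-peptide per channel (default 5).
#' @param seed Integer seed.
#' @return Sigma, in fluorescence units.
#' @export
bootstrap_sigma <- function(corner_background, corner_antivenom, factor,
                            n_boot = 50000L, replicates = 5L, seed = 1L) {
  if (!length(corner_background) || !length(corner_antivenom)) {
    stop("corner-control distributions must be non-empty", call. = FALSE)
  }
  stopifnot(n_boot >= 2L, replicates >= 1L, factor > 0)
  with_seed(seed, {
    n <- n_boot * 3L
    bg <- matrix(corner_background[sample.int(length(corner_background),
                                              n * replicates, replace = TRUE)],
                 nrow = n, ncol = replicates)
    av <- matrix(corner_antivenom[sample.int(length(corner_antivenom),
                                             n * replicates, replace = TRUE)],
                 nrow = n, ncol = replicates)
    corrected <- row_medians(av) - factor * row_medians(bg)
    dim(corrected) <- c(3L, n_boot)
    scores <- median3(corrected[1, ], corrected[2, ], corrected[3, ])
    sd(scores)
  })
}

#' One-sided Z-test p-values for running-median scores
#'
#' Assumes the corrected running median of random peptides is normal with
#' mean zero and standard deviation `sigma`; returns the upper-tail
#' probability of each score.
#'
#' @param scores Numeric vector of corrected running-median scores.
#' @param sigma Null standard deviation (> 0), from [bootstrap_sigma()].
#' @return Vector of one-sided p-values.
#' @export
z_pvalues <- function(scores, sigma) {
  stopifnot(sigma > 0)
  pnorm(scores / sigma, lower.tail = FALSE)
}

#' Benjamini-Hochberg significance calls and score threshold
#'
#' Applies the standard step-up rule at level `alpha` and reports, alongside
#' the per-entry significance mask, the smallest score declared significant;
#' because the one-sided p-value is monotone decreasing in the score, every
#' score at or above this threshold is significant.
#'
#' @param pvalues P-values over the analysed set (unique peptide /
#'   running-median pairs).
#' @param scores Matching scores (same length), used to derive the threshold.
#' @param alpha FDR level (default 0.05).
#' @return List with `significant` (logical mask), `score_threshold`
#'   (+Inf when nothing is significant) and `alpha`.
#' @export
bh_call <- function(pvalues, scores = NULL, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), alpha > 0, alpha < 1)
  significant <- p.adjust(pvalues, method = "BH") <= alpha
  threshold <- Inf
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(pvalues))
    if (any(significant)) threshold <- min(scores[significant])
  }
  list(significant = significant, score_threshold = threshold, alpha = alpha)
}

#' Fit the significance model for a processed array
#'
#' Combines the bootstrap null width with BH correction over the unique
#' (peptide, running-median score) pairs of the analysed profiles, yielding
#' the score threshold applied to every profile position.
#'
#' @param profiles Named list of `signal_profile` objects from
#'   [map_to_toxins()].
#' @param toxins Toxin set the profiles were mapped from.
#' @param corner_background,corner_antivenom Corner-control distributions.
#' @param factor Re-incubation factor.
#' @param alpha FDR level (default 0.05).
#' @param n_boot Bootstrap repetitions (default 50,000).
#' @param seed Integer seed for the bootstrap.
#' @param k Peptide length (default 15).
#' @return List of class `significance_model`: sigma, alpha, n_boot,
#'   score_threshold, n_pairs (unique pairs tested), seed.
#' @export
fit_significance <- function(profiles, toxins, corner_background,
                             corner_antivenom, factor, alpha = 0.05,
                             n_boot = 50000L, seed = 1L, k = 15L) {
  sigma <- bootstrap_sigma(corner_background, corner_antivenom, factor,
                           n_boot = n_boot, seed = seed)
  if (sigma <= 0) {
    stop("degenerate null: bootstrap sigma is not positive", call. = FALSE)
  }
  pairs <- unique_score_pairs(profiles, toxins, k = k)
  call <- bh_call(z_pvalues(pairs$score, sigma), pairs$score, alpha = alpha)
  structure(
    list(sigma = sigma, alpha = alpha, n_boot = as.integer(n_boot),
         score_threshold = call$score_threshold, n_pairs = nrow(pairs),
         n_significant = sum(call$significant), seed = as.integer(seed)),
    class = "significance_model"
  )
}

# Unique (peptide, running-median score) pairs across all profiles: the
# multiple-testing family. A peptide can enter several toxins at positions
# with different neighbourhoods, hence several distinct pairs.
unique_score_pairs <- function(profiles, toxins, k = 15L) {
  seq_of <- setNames(toxins$sequence, toxins$accession)
  parts <- lapply(profiles, function(p) {
    tiles <- tile_sequence(seq_of[[p$accession]], k = k)
    data.frame(peptide = tiles, score = p$score, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  all[!duplicated(paste(all$peptide, signif(all$score, 12))), , drop = FALSE]
}

#' @export
print.significance_model <- function(x, ...) {
  cat(sprintf(paste0("significance_model: sigma = %.4g (n_boot = %d), ",
                     "alpha = %.3g, threshold = %.4g (%d of %d pairs significant)\n"),
              x$sigma, x$n_boot, x$alpha, x$score_threshold,
              x$n_significant, x$n_pairs))
  invisible(x)
}

#' Call recognised toxins from profiles and a fitted model
#'
#' A profile position is significant when its running-median score is at or
#' above the model's score threshold; a toxin is recognised when at least two
#' successive 15-mers are significant. All maximal significant runs are
#' returned.
#'
#' @param profiles Named list of `signal_profile` objects.
#' @param model A `significance_model` from [fit_significance()].
#' @return data.frame with one row per toxin: accession, recognized,
#'   n_significant, plus a `runs` list-column of data.frames (start, end,
#'   length) of maximal significant runs.
#' @export
call_recognized <- function(profiles, model) {
  stopifnot(inherits(model, "significance_model"))
  rows <- lapply(profiles, function(p) {
    mask <- p$score >= model$score_threshold
    runs <- true_runs(mask)
    data.frame(accession = p$accession,
               recognized = any(runs$length >= 2L),
               n_significant = sum(mask),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$runs <- lapply(profiles, function(p) true_runs(p$score >= model$score_threshold))
  out
}
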