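# Synthetic-array generator: toxin sets with planted epitope motifs and
# two-recording field-intensity tables with the noise structure the analysis
# assumes (log-normal unspecific binding, heavier-tailed corner controls, a
# multiplicative re-incubation effect between recordings).

#' Noise model for synthetic array intensities
#'
#' Per-field unspecific binding is log-normal (non-negative fluorescence with
#' a heavy right tail); corner-control fields draw from a heavier-tailed
#' log-normal; the second (antivenom) recording is inflated by a
#' multiplicative re-incubation factor.
#'
#' @param background_log_mean,background_log_sd Log-scale parameters of the
#'   per-field unspecific-binding distribution (arbitrary fluorescence units).
#' @param reincubation_factor Multiplicative second-incubation inflation
#'   (dimensionless; the observed experimental value is around 4.3).
#' @param corner_log_mean,corner_log_sd Log-scale parameters of the
#'   corner-control distribution; defaults are heavier-tailed than the
#'   background.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(background_log_mean = log(50), background_log_sd = 0.4,
                        reincubation_factor = 4.3,
                        corner_log_mean = log(100), corner_log_sd = 0.5) {
  stopifnot(background_log_sd >= 0, corner_log_sd >= 0, reincubation_factor > 0)
  structure(
    list(background_log_mean = background_log_mean,
         background_log_sd = background_log_sd,
         reincubation_factor = reincubation_factor,
         corner_log_mean = corner_log_mean,
         corner_log_sd = corner_log_sd),
    class = "noise_model"
  )
}

#' Simulate a toxin set with planted epitope motifs
#'
#' Generates random amino-acid sequences and overwrites, in each carrier of a
#' planted epitope, the window at the motif's position with the motif string.
#' Because linear epitope elements of homologous toxins occupy homologous
#' sequence positions, each motif is planted at one shared position across
#' all of its carriers, so an alignment of the carriers places the motif in a
#' common column range.
#'
#' @param n_toxins Number of sequences (>= 1).
#' @param length_range Integer vector of length 2: min/max sequence length
#'   (min >= 15).
#' @param n_epitopes Number of motifs to plant (0 for a null set).
#' @param n_carriers Carriers per motif (default: half the toxins).
#' @param motif_length_range Motif lengths, drawn uniformly; linear epitope
#'   elements are typically 4-12 residues (default c(6, 10)).
#' @param effect_size Mean antivenom-signal elevation (arbitrary fluorescence
#'   units) for every 15-mer containing a planted motif.
#' @param family Family label(s) for the generated records.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return List with `toxins` (a [toxin_set()] data.frame) and `truth`
#'   (data.frame motif/accession/position/effect_size; zero rows for a null
#'   set).
#' @export
simulate_toxin_set <- function(n_toxins, length_range = c(60L, 90L),
                               n_epitopes = 0L, n_carriers = NULL,
                               motif_length_range = c(6L, 10L),
                               effect_size = 1000, family = "SYN",
                               seed = 1L) {
  stopifnot(n_toxins >= 1L, length_range[1] >= 15L,
            motif_length_range[1] >= 4L, motif_length_range[2] <= 12L)
  n_carriers <- n_carriers %||% max(1L, n_toxins %/% 2L)
  with_seed(seed, {
    len_vals <- seq.int(length_range[1], length_range[2])
    lens <- len_vals[sample.int(length(len_vals), n_toxins, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(STANDARD_AA, L, replace = TRUE), collapse = "")
    }, character(1))
    acc <- sprintf("SYN%04d", seq_len(n_toxins))
    truth <- NULL
    if (n_epitopes > 0L) {
      if (max(motif_length_range) > min(lens)) {
        stop("motif longer than shortest sequence", call. = FALSE)
      }
      for (e in seq_len(n_epitopes)) {
        mlen_vals <- seq.int(motif_length_range[1], motif_length_range[2])
        mlen <- mlen_vals[sample.int(length(mlen_vals), 1L)]
        motif <- paste(sample(STANDARD_AA, mlen, replace = TRUE), collapse = "")
        carriers <- sample.int(n_toxins, min(n_carriers, n_toxins))
        # one shared insertion position, valid for every carrier
        pos <- sample.int(min(lens[carriers]) - mlen + 1L, 1L)
        for (i in carriers) {
          substr(seqs[i], pos, pos + mlen - 1L) <- motif
        }
        truth <- rbind(truth, data.frame(
          motif = motif, accession = acc[carriers], position = pos,
          effect_size = effect_size, stringsAsFactors = FALSE))
      }
    }
    if (is.null(truth)) {
      truth <- data.frame(motif = character(0), accession = character(0),
                          position = integer(0), effect_size = numeric(0))
    }
    list(
      toxins = toxin_set(acc, seqs, species = "Synthetica exempli",
                         family = rep_len(family, n_toxins)),
      truth = truth
    )
  })
}

#' Simulate two-recording field intensities for a layout
#'
#' Background (naive-IgG) channel: independent log-normal draw per field.
#' Antivenom channel: an independent unspecific draw scaled by the
#' re-incubation factor, plus the planted effect size for every non-corner
#' field whose peptide contains a planted motif as a substring. Corner-control
#' fields draw from the heavier-tailed corner distribution in both channels,
#' with the antivenom corner draw also inflated by the re-incubation factor.
#'
#' @param layout An `array_layout` from [assign_layout()].
#' @param truth Planted-epitope truth table from [simulate_toxin_set()]
#'   (zero rows for a null array).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return List with two data.frames, `background` and `antivenom`, each with
#'   columns field_id, peptide, intensity (every field exactly once).
#' @export
simulate_intensities <- function(layout, truth, noise = noise_model(),
                                 seed = 1L) {
  stopifnot(inherits(layout, "array_layout"), inherits(noise, "noise_model"))
  n <- nrow(layout)
  corner <- layout$is_corner_control
  motifs <- unique(truth$motif)
  elevated <- rep(FALSE, n)
  for (m in motifs) {
    elevated <- elevated | grepl(m, layout$peptide, fixed = TRUE)
  }
  elevated <- elevated & !corner
  effect <- numeric(n)
  if (length(motifs)) {
    eff_by_motif <- vapply(motifs, function(m) {
      truth$effect_size[match(m, truth$motif)]
    }, numeric(1))
    for (j in seq_along(motifs)) {
      hit <- grepl(motifs[j], layout$peptide, fixed = TRUE) & !corner
      effect[hit] <- effect[hit] + eff_by_motif[j]
    }
  }
  with_seed(seed, {
    draw <- function(k, meanlog, sdlog) {
      if (sdlog == 0) rep(exp(meanlog), k) else rlnorm(k, meanlog, sdlog)
    }
    bg <- numeric(n)
    av <- numeric(n)
    nc <- sum(!corner)
    bg[!corner] <- draw(nc, noise$background_log_mean, noise$background_log_sd)
    av[!corner] <- noise$reincubation_factor *
      draw(nc, noise$background_log_mean, noise$background_log_sd) +
      effect[!corner]
    if (any(corner)) {
      kc <- sum(corner)
      bg[corner] <- draw(kc, noise$corner_log_mean, noise$corner_log_sd)
      av[corner] <- noise$reincubation_factor *
        draw(kc, noise$corner_log_mean, noise$corner_log_sd)
    }
    list(
      background = data.frame(field_id = layout$field_id,
                              peptide = layout$peptide, intensity = bg,
                              stringsAsFactors = FALSE),
      antivenom = data.frame(field_id = layout$field_id,
                             peptide = layout$peptide, intensity = av,
                             stringsAsFactors = FALSE)
    )
  })
}
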