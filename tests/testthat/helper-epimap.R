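# Shared fixtures and independent oracles. Oracles are deliberately written
# with different primitives than the implementation they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Brute-force 3-window running median with the two-value terminal rule.
oracle_running_median <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - 1L):min(n, i + 1L)]
    median(w)
  }, numeric(1))
}

# Brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k*alpha/m.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Direct profile constructor for hand-built score fixtures.
make_profile <- function(accession, score, raw = score) {
  structure(list(accession = accession, raw = raw, score = score),
            class = "signal_profile")
}

# Identity alignment (gap-free) for equal-length sequences.
identity_msa <- function(toxins) setNames(toxins$sequence, toxins$accession)

# Deterministic intensity tables for a layout: per-field values supplied by
# functions of the peptide string, bypassing the stochastic generator.
fixed_intensities <- function(layout, bg_fun, av_fun) {
  list(
    background = data.frame(field_id = layout$field_id,
                            peptide = layout$peptide,
                            intensity = vapply(layout$peptide, bg_fun, numeric(1)),
                            stringsAsFactors = FALSE),
    antivenom = data.frame(field_id = layout$field_id,
                           peptide = layout$peptide,
                           intensity = vapply(layout$peptide, av_fun, numeric(1)),
                           stringsAsFactors = FALSE)
  )
}

# Minimal synthetic PDB text: one CA atom per residue, chain `chain`,
# residues numbered from `first_res`. Fixed-width per the 80-column format.
make_synthetic_pdb <- function(path, n_res, chain = "A", first_res = 1L) {
  lines <- c("HEADER    SYNTHETIC TEST STRUCTURE                01-JAN-26   XXXX")
  for (i in seq_len(n_res)) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, chain, first_res + i - 1L, i * 1.5, 0, 0, 1.00, 25.00))
  }
  lines <- c(lines, sprintf("TER   %5d      ALA %s%4d", n_res + 1L, chain,
                            first_res + n_res - 1L), "END")
  writeLines(lines, path)
  path
}

# Build a full processed array (null or with planted epitopes) in one call.
make_array <- function(n_toxins = 30, len = 40, n_epitopes = 0,
                       n_carriers = 15, effect_size = 1000,
                       corner_fields = 200, seed = 1,
                       noise = noise_model()) {
  sim <- simulate_toxin_set(n_toxins, length_range = c(len, len),
                            n_epitopes = n_epitopes, n_carriers = n_carriers,
                            effect_size = effect_size, seed = seed)
  lib <- build_library(sim$toxins)
  lay <- assign_layout(lib, replicates = 5, corner_field_count = corner_fields,
                       seed = seed + 1000)
  ch <- simulate_intensities(lay, sim$truth, noise, seed = seed + 2000)
  c(sim, list(library = lib, layout = lay, background = ch$background,
              antivenom = ch$antivenom))
}
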