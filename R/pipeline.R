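# End-to-end orchestration: configuration, the in-memory analysis chain, the
# file-based pipeline runner with manifest, and recognition summaries.

#' Pipeline configuration
#'
#' Collects paths and parameters for [run_pipeline()]. Parameter defaults are
#' the pipeline's standard operating point: 15-mer peptides in 5 replicates,
#' 852 corner-control fields, a 50,000-repetition bootstrap, FDR level 0.05,
#' segments shared by at least 10 toxins, and up to 3 residue mismatches for
#' peptide similarity.
#'
#' @param fasta,meta Toxin FASTA and metadata sidecar paths (NULL when
#'   simulating).
#' @param background,antivenom Intensity-table paths (TSV: field_id, peptide,
#'   intensity), or NULL to simulate.
#' @param layout Optional layout TSV path matching the intensity tables.
#' @param msa_dir Optional directory of per-family alignments named
#'   `<family>.fasta` / `<family>.aln`.
#' @param out_dir Output directory for result tables and the manifest.
#' @param k,replicates,corner_field_count,n_boot,alpha,min_share,max_mismatch
#'   Analysis parameters (see Details).
#' @param seed Single integer seed fanned out to stage-specific child seeds
#'   by fixed offsets.
#' @param simulate Optional named list of arguments for
#'   [simulate_toxin_set()] (plus optional `noise`, a [noise_model()]); when
#'   given, inputs are generated instead of read.
#' @return List of class `epimap_config`.
#' @export
epimap_config <- function(fasta = NULL, meta = NULL, background = NULL,
                          antivenom = NULL, layout = NULL, msa_dir = NULL,
                          out_dir = tempfile("epimap_run_"), k = 15L,
                          replicates = 5L, corner_field_count = 852L,
                          n_boot = 50000L, alpha = 0.05, min_share = 10L,
                          max_mismatch = 3L, seed = 1L, simulate = NULL) {
  stopifnot(k >= 2L, replicates >= 1L, alpha > 0, alpha < 1,
            n_boot >= 2L, min_share >= 1L, max_mismatch >= 0L)
  structure(
    list(fasta = fasta, meta = meta, background = background,
         antivenom = antivenom, layout = layout, msa_dir = msa_dir,
         out_dir = out_dir, k = as.integer(k),
         replicates = as.integer(replicates),
         corner_field_count = as.integer(corner_field_count),
         n_boot = as.integer(n_boot), alpha = alpha,
         min_share = as.integer(min_share),
         max_mismatch = as.integer(max_mismatch), seed = as.integer(seed),
         simulate = simulate),
    class = "epimap_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [epimap_config()] arguments.
#' @return An `epimap_config`.
#' @export
epimap_config_from_yaml <- function(path) {
  do.call(epimap_config, yaml::read_yaml(path))
}

#' Run the analysis chain on in-memory objects
#'
#' Replicate medians, re-incubation estimation and correction, running-median
#' profiles, bootstrap-calibrated significance model, and recognition calls;
#' optionally alignment-anchored epitope analysis per provided MSA.
#'
#' @param toxins Toxin set.
#' @param layout `array_layout` the intensities were recorded on.
#' @param background,antivenom Intensity data.frames.
#' @param msas Optional named list of alignments (named character vectors) to
#'   run the epitope stage on.
#' @param alpha,n_boot,min_share,max_mismatch,k Analysis parameters.
#' @param seed Integer seed (bootstrap).
#' @return List with `factor`, `signal` (per-peptide medians + corrected),
#'   `profiles`, `model`, `calls`, and `epitopes` (per MSA: list of
#'   segment/core/similar/logos/association bundles).
#' @export
analyze_array <- function(toxins, layout, background, antivenom, msas = NULL,
                          alpha = 0.05, n_boot = 50000L, min_share = 10L,
                          max_mismatch = 3L, k = 15L, seed = 1L) {
  med <- replicate_median(background, antivenom, layout)
  factor <- estimate_reincubation(med$corner_background, med$corner_antivenom)
  signal <- med$signal
  signal$corrected <- correct_signal(signal$antivenom_median,
                                     signal$background_median, factor)
  profiles <- map_to_toxins(signal, toxins, k = k)
  model <- fit_significance(profiles, toxins, med$corner_background,
                            med$corner_antivenom, factor, alpha = alpha,
                            n_boot = n_boot, seed = seed, k = k)
  calls <- call_recognized(profiles, model)
  epitopes <- NULL
  if (!is.null(msas)) {
    epitopes <- lapply(msas, function(msa) {
      aligned <- map_profiles_to_msa(profiles[intersect(names(profiles),
                                                        names(msa))],
                                     msa, toxins = toxins, k = k)
      analyze_epitopes(aligned, profiles, model$score_threshold,
                       min_share = min_share, max_mismatch = max_mismatch,
                       alpha = alpha)
    })
  }
  list(factor = factor, signal = signal, profiles = profiles, model = model,
       calls = calls, epitopes = epitopes)
}

#' Epitope-segment analysis of one aligned profile
#'
#' Detects shared segments, extracts each segment's core motif, aggregates
#' mismatch-tolerant per-toxin score sums, and builds the logo and
#' residue-association matrices for the core window.
#'
#' @param aligned An `aligned_profile`.
#' @param profiles The profile list behind it.
#' @param threshold Significance score threshold.
#' @param min_share,max_mismatch,alpha Parameters as in [epimap_config()].
#' @return List of bundles, one per segment: `segment`, `core`, `similar`,
#'   `logo_all`, `logo_recognized`, `association` (NULL when fewer than 3
#'   matched toxins or constant sums).
#' @export
analyze_epitopes <- function(aligned, profiles, threshold, min_share = 10L,
                             max_mismatch = 3L, alpha = 0.05) {
  if (!is.finite(threshold)) return(list())  # nothing significant anywhere
  segments <- find_shared_segments(aligned, threshold, min_share = min_share)
  lapply(segments, function(seg) {
    core <- extract_core_motif(seg, aligned, profiles, threshold)
    similar <- collect_similar(core, aligned, profiles,
                               max_mismatch = max_mismatch)
    all_seqs <- similar$core_seq[similar$core_seq != strrep("-", nchar(core$core))]
    rec_seqs <- similar$core_seq[similar$accession %in% seg$members]
    assoc <- NULL
    scored <- similar[similar$matched & !is.na(similar$sum), , drop = FALSE]
    if (nrow(scored) >= 3L && length(unique(scored$sum)) > 1L) {
      assoc <- residue_zscores(scored$core_seq, scored$sum)
    }
    list(segment = seg, core = core, similar = similar,
         logo_all = if (length(all_seqs)) logo_matrix(all_seqs) else NULL,
         logo_recognized = if (length(rec_seqs)) logo_matrix(rec_seqs) else NULL,
         association = if (!is.null(assoc))
           list(matrix = assoc, table = association_table(assoc, alpha)) else NULL)
  })
}

#' Run the full pipeline from a configuration
#'
#' Executes design, (optional) simulation, signal processing, significance
#' calling and the epitope stage, writing tab-separated result tables and a
#' JSON manifest (parameters, seed, per-stage row counts) to the output
#' directory. Re-running with the same configuration and seed reproduces the
#' tables exactly.
#'
#' @param config An [epimap_config()].
#' @return Invisibly, the in-memory result of [analyze_array()] with an added
#'   `manifest` element.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "epimap_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    noise <- sim_args$noise %||% noise_model()
    sim_args$noise <- NULL
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- do.call(simulate_toxin_set, sim_args)
    toxins <- sim$toxins
    truth <- sim$truth
    library <- build_library(toxins, k = config$k)
    layout <- assign_layout(library, replicates = config$replicates,
                            corner_field_count = config$corner_field_count,
                            seed = config$seed + 1000L)
    chan <- simulate_intensities(layout, truth, noise,
                                 seed = config$seed + 2000L)
    background <- chan$background
    antivenom <- chan$antivenom
    write_toxins(toxins, file.path(config$out_dir, "toxins.fasta"),
                 file.path(config$out_dir, "toxins.tsv"))
    write_tsv(truth, file.path(config$out_dir, "truth.tsv"))
    write_tsv(background, file.path(config$out_dir, "background.tsv"))
    write_tsv(antivenom, file.path(config$out_dir, "antivenom.tsv"))
  } else {
    if (is.null(config$fasta) || is.null(config$background) ||
        is.null(config$antivenom)) {
      stop("config must provide fasta + intensity tables, or a simulate block",
           call. = FALSE)
    }
    toxins <- read_toxins(config$fasta, config$meta)
    library <- build_library(toxins, k = config$k)
    background <- read_intensities(config$background)
    antivenom <- read_intensities(config$antivenom)
    layout <- if (!is.null(config$layout)) {
      read_layout(config$layout, replicates = config$replicates)
    } else {
      # reconstruct from the background table: corner fields carry the
      # corner-control peptide
      df <- background[, c("field_id", "peptide")]
      df$is_corner_control <- df$peptide == CORNER_PEPTIDE
      attr(df, "replicates") <- config$replicates
      attr(df, "corner_peptide") <- CORNER_PEPTIDE
      attr(df, "corner_field_count") <- sum(df$is_corner_control)
      attr(df, "seed") <- NA_integer_
      class(df) <- c("array_layout", "data.frame")
      df
    }
  }
  write_library(library, file.path(config$out_dir, "library.tsv"))
  write_layout(layout, file.path(config$out_dir, "layout.tsv"))

  msas <- NULL
  if (!is.null(config$msa_dir)) {
    files <- list.files(config$msa_dir, pattern = "\\.(fasta|fa|aln|clustal)$",
                        full.names = TRUE)
    msas <- lapply(files, read_msa)
    names(msas) <- tools::file_path_sans_ext(basename(files))
    missing <- setdiff(unique(toxins$family), names(msas))
    if (length(missing)) {
      warning("no alignment for family: ", paste(missing, collapse = ", "),
              "; epitope stage skipped for it")
    }
  }

  res <- analyze_array(toxins, layout, background, antivenom, msas = msas,
                       alpha = config$alpha, n_boot = config$n_boot,
                       min_share = config$min_share,
                       max_mismatch = config$max_mismatch, k = config$k,
                       seed = config$seed + 3000L)

  write_tsv(res$signal, file.path(config$out_dir, "peptide_signal.tsv"))
  prof_tab <- do.call(rbind, lapply(res$profiles, function(p) {
    data.frame(accession = p$accession, position = seq_along(p$raw),
               corrected = p$raw, running_median = p$score,
               stringsAsFactors = FALSE)
  }))
  write_tsv(prof_tab, file.path(config$out_dir, "profiles.tsv"))
  write_tsv(res$calls[, c("accession", "recognized", "n_significant")],
            file.path(config$out_dir, "calls.tsv"))
  summary <- summarize_recognition(res$calls, toxins)
  write_tsv(summary, file.path(config$out_dir, "recognition_summary.tsv"))
  model_out <- res$model
  jsonlite::write_json(unclass(model_out),
                       file.path(config$out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$epitopes)) {
    seg_rows <- list()
    for (fam in names(res$epitopes)) {
      for (b in res$epitopes[[fam]]) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          family = fam, col_start = b$segment$start, col_end = b$segment$end,
          n_members = length(b$segment$members), core = b$core$core,
          anchor = b$core$accession, run_length = b$core$run_length,
          stringsAsFactors = FALSE)
      }
    }
    if (length(seg_rows)) {
      write_tsv(do.call(rbind, seg_rows),
                file.path(config$out_dir, "segments.tsv"))
    }
  }
  manifest <- list(
    parameters = config[c("k", "replicates", "corner_field_count", "n_boot",
                          "alpha", "min_share", "max_mismatch", "seed")],
    reincubation_factor = res$factor,
    sigma = res$model$sigma,
    score_threshold = res$model$score_threshold,
    counts = list(
      toxins = nrow(toxins),
      unique_peptides = length(library$peptides),
      fields = nrow(layout),
      corner_fields = sum(layout$is_corner_control),
      pairs_tested = res$model$n_pairs,
      significant_pairs = res$model$n_significant,
      recognized_toxins = sum(res$calls$recognized)
    ),
    package_version = as.character(utils::packageVersion("epimap"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$truth <- truth
  invisible(res)
}

#' Family-by-species recognition summary
#'
#' @param calls Output of [call_recognized()].
#' @param toxins Toxin set with species/family metadata.
#' @return data.frame with one row per observed (species, family) cell:
#'   n_toxins, n_recognized, ratio. Empty cells are absent, not zero.
#' @export
summarize_recognition <- function(calls, toxins) {
  m <- merge(calls[, c("accession", "recognized")],
             toxins[, c("accession", "species", "family")], by = "accession")
  agg <- aggregate(recognized ~ species + family, data = m,
                   FUN = function(x) c(n = length(x), rec = sum(x)))
  out <- data.frame(
    species = agg$species, family = agg$family,
    n_toxins = agg$recognized[, "n"],
    n_recognized = agg$recognized[, "rec"],
    stringsAsFactors = FALSE
  )
  out$ratio <- out$n_recognized / out$n_toxins
  out <- out[order(out$family, out$species), ]
  rownames(out) <- NULL
  out
}
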