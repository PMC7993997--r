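#' Pipeline configuration
#'
#' Bundles paths, thresholds, analysis windows and the seed for a full run.
#' Threshold defaults are the field's standard published values: FDR 0.05,
#' start-site ratio > 4, combined start counts > 14, frame fraction > 0.5,
#' periodicity probability > 0.5, RRO floors 2 (uORF) and 32 (CDS), mRNA
#' read floor 10, queue-call enrichment 1.5.
#'
#' @param output_dir directory for TSV artifacts and the run manifest.
#' @param seed integer seed driving every stochastic step.
#' @param simulate if `TRUE`, inputs are generated by the synthetic-data
#'   module from `sim`; otherwise `paths` must point at annotation, counts,
#'   metadata, FASTA and per-library wiggle tracks.
#' @param sim a [simulation_config()] (its seed is overridden by `seed`).
#' @param paths named list: `annotation`, `fasta`, `counts`, `metadata`,
#'   `tracks` (named character vector, one wiggle per RPF library).
#' @param thresholds named list overriding any of `fdr`, `start_ratio`,
#'   `start_combined`, `frame_fraction`, `periodicity`, `rro_uorf_floor`,
#'   `rro_cds_floor`, `mrna_read_floor`, `queue_threshold`.
#' @param windows named list overriding `metagene` (`c(upstream,
#'   downstream)`), `queue_search`, `queue_background`, `min_cds_counts`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L, simulate = TRUE,
                            sim = simulation_config(),
                            paths = list(), thresholds = list(),
                            windows = list()) {
  th <- list(fdr = 0.05, start_ratio = 4, start_combined = 14,
             frame_fraction = 0.5, periodicity = 0.5,
             rro_uorf_floor = 2, rro_cds_floor = 32,
             mrna_read_floor = 10, queue_threshold = 1.5)
  bad <- setdiff(names(thresholds), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(thresholds)] <- thresholds
  wn <- list(metagene = c(60L, 90L), queue_search = c(-50L, -10L),
             queue_background = c(-60L, -51L), min_cds_counts = 64)
  bad <- setdiff(names(windows), names(wn))
  if (length(bad)) stop("unknown window(s): ", paste(bad, collapse = ", "))
  wn[names(windows)] <- windows
  if (!simulate) {
    need <- c("annotation", "fasta", "counts", "metadata", "tracks")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("missing path field(s): ", paste(miss, collapse = ", "))
    for (f in c("annotation", "fasta", "counts", "metadata")) {
      if (!file.exists(paths[[f]])) stop("path '", f, "' does not exist: ",
                                         paths[[f]])
    }
    if (!all(file.exists(unlist(paths$tracks)))) stop("missing track file(s)")
  }
  sim$seed <- as.integer(seed)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, paths = paths,
                 thresholds = th, windows = wn),
            class = "pipeline_config")
}

#' Sum positional tracks across libraries
#' @param track_list list of `positional_counts` over the same transcripts.
#' @return a single `positional_counts`-like named list of summed vectors.
#' @export
pool_tracks <- function(track_list) {
  stopifnot(length(track_list) >= 1L)
  out <- track_list[[1]]
  for (k in seq_along(track_list)[-1]) {
    stopifnot(identical(names(track_list[[k]]), names(out)))
    for (tx in names(out)) out[[tx]] <- out[[tx]] + track_list[[k]][[tx]]
  }
  out
}

config_hash <- function(config) {
  plain <- config
  plain$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_tsv <- function(tab, dir, name) {
  partial <- file.path(dir, paste0(name, ".partial"))
  readr::write_tsv(tab, partial, progress = FALSE)
  final <- file.path(dir, name)
  file.rename(partial, final)
  final
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> differential TE -> metagene / 3'UTR:ORF ->
#' uORF calling / RRO -> features, writing one TSV per artifact plus a JSON
#' run manifest recording the config hash, seed, versions and per-stage row
#' counts. Reruns with an identical config reproduce byte-identical TSVs.
#' A stage failure aborts with the stage named; outputs of a failed stage
#' keep a `.partial` suffix.
#'
#' @param config a [pipeline_config()].
#' @return named list of output paths, invisibly; the manifest is
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("riboflux")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   stages = list())
  outputs <- character(0)
  th <- config$thresholds
  wn <- config$windows
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  data <- run_stage("input", {
    if (config$simulate) {
      sim <- simulate_transcriptome(config$sim)
      simulate_counts(sim, tracks = TRUE)
    } else {
      models <- read_annotation(config$paths$annotation, "gff3")
      models <- read_transcript_fasta(models, config$paths$fasta)
      mat <- read_count_matrix(config$paths$counts, config$paths$metadata)
      tracks <- lapply(config$paths$tracks, read_positional_counts,
                       models = models, format = "wiggle")
      list(models = models, matrix = mat, tracks = tracks)
    }
  })
  models <- data$models
  rpf_meta <- data$matrix$libraries[data$matrix$libraries$assay == "RPF", ]
  manifest$stages$input <- list(n_genes = nrow(models),
                                n_libraries = nrow(data$matrix$libraries))

  # -- differential TE ------------------------------------------------------
  dte <- run_stage("dte", {
    out <- run_dte(data$matrix, min_rna_reads = th$mrna_read_floor,
                   fdr_threshold = th$fdr)
    outputs["te_results"] <- write_stage_tsv(out$result, config$output_dir,
                                              "te_results.tsv")
    summary <- tibble::tibble(
      n_tested = sum(out$result$converged),
      n_up = sum(out$result$class == "up"),
      n_down = sum(out$result$class == "down"),
      fdr_threshold = th$fdr
    )
    outputs["te_summary"] <- write_stage_tsv(summary, config$output_dir,
                                              "te_summary.tsv")
    manifest$stages$dte <- list(n_tested = summary$n_tested,
                                 n_up = summary$n_up, n_down = summary$n_down)
    out
  })

  # -- metagene and 3'UTR:ORF -----------------------------------------------
  run_stage("metagene", {
    profiles <- list()
    for (cond in c("reference", "perturbed")) {
      libs <- rpf_meta$library_id[rpf_meta$condition == cond]
      pooled <- pool_tracks(data$tracks[libs])
      prof <- metagene_at_stop(pooled, models, window = wn$metagene,
                               min_cds_counts = wn$min_cds_counts)
      prof$condition <- cond
      profiles[[cond]] <- prof
    }
    prof_tab <- do.call(rbind, profiles)
    outputs["metagene"] <- write_stage_tsv(prof_tab, config$output_dir,
                                            "metagene_profiles.tsv")
    peaks <- do.call(rbind, lapply(c("reference", "perturbed"), function(cond) {
      pk <- detect_queue_peak(profiles[[cond]],
                              search_window = wn$queue_search,
                              background_window = wn$queue_background,
                              threshold = th$queue_threshold)
      pk$condition <- cond
      pk
    }))
    outputs["queue_peaks"] <- write_stage_tsv(peaks, config$output_dir,
                                               "queue_peaks.tsv")
    ratios <- do.call(rbind, lapply(c("reference", "perturbed"), function(cond) {
      libs <- rpf_meta$library_id[rpf_meta$condition == cond]
      r <- suppressMessages(utr3_orf_ratio(pool_tracks(data$tracks[libs]), models))
      r$condition <- cond
      r
    }))
    outputs["utr3_ratios"] <- write_stage_tsv(ratios, config$output_dir,
                                               "utr3_orf_ratios.tsv")
    manifest$stages$metagene <- list(n_offsets = nrow(profiles$reference),
                                      n_utr3_genes = nrow(ratios) / 2L)
  })

  # -- uORF calling and RRO -------------------------------------------------
  run_stage("uorf", {
    ref_libs <- rpf_meta$library_id[rpf_meta$condition == "reference"]
    pooled_ref <- pool_tracks(data$tracks[ref_libs])
    report <- call_translated_uorfs(
      models, pooled_ref,
      ratio_threshold = th$start_ratio, combined_threshold = th$start_combined,
      frame_threshold = th$frame_fraction,
      periodicity_threshold = th$periodicity)
    outputs["uorf_filters"] <- write_stage_tsv(report, config$output_dir,
                                                "uorf_filter_report.tsv")
    translated <- report[report$translated, ]
    manifest$stages$uorf <- list(n_candidates = nrow(report),
                                  n_translated = nrow(translated))
    if (nrow(translated) >= 2L) {
      rro <- compute_rro(translated, models, data$tracks[rpf_meta$library_id])
      sf_rpf <- dte$size_factors[rpf_meta$library_id]
      rro_res <- tryCatch(
        diff_rro(rro, rpf_meta, sf = sf_rpf,
                 uorf_floor = th$rro_uorf_floor, cds_floor = th$rro_cds_floor,
                 fdr_threshold = th$fdr),
        error = function(e) NULL
      )
      if (!is.null(rro_res)) {
        outputs["rro_results"] <- write_stage_tsv(rro_res, config$output_dir,
                                                   "rro_results.tsv")
        manifest$stages$uorf$n_rro_tested <- sum(rro_res$converged)
      }
    }
  })

  # -- features -------------------------------------------------------------
  run_stage("features", {
    nt <- naive_te(dte$matrix, dte$size_factors)
    keep <- match(nt$gene_id, models$transcript_id)
    m_kept <- models[keep, ]
    # reference weight matrix from the ~270 best-translated mRNAs with a
    # defined -3..+4 context
    ctx_ok <- m_kept$utr5_len >= 3L & !is.na(m_kept$sequence)
    top <- order(nt$log2TE_reference[ctx_ok], decreasing = TRUE)
    top <- which(ctx_ok)[top[seq_len(min(270L, length(top)))]]
    contexts <- substr(m_kept$sequence[top], m_kept$utr5_len[top] - 2L,
                       m_kept$utr5_len[top] + 4L)
    weights <- build_weight_matrix(contexts)
    ft <- feature_table(m_kept, nt$log2TE_reference, weights = weights)
    outputs["features"] <- write_stage_tsv(ft, config$output_dir,
                                            "feature_table.tsv")
    dtev <- dte$result$log2dTE[match(ft$transcript_id, dte$result$gene_id)]
    corr <- feature_dte_correlations(
      ft[, c("basal_log2te", "cds_len", "utr5_len", "context_score")], dtev)
    outputs["correlations"] <- write_stage_tsv(corr, config$output_dir,
                                                "feature_dte_correlations.tsv")
    pent <- pentile_dte(dtev, ft$cds_len, ft$transcript_id)
    outputs["pentiles"] <- write_stage_tsv(pent, config$output_dir,
                                            "cds_length_pentiles.tsv")
    freq <- start_context_frequencies(m_kept)
    outputs["start_context"] <- write_stage_tsv(freq, config$output_dir,
                                                 "start_context_frequencies.tsv")
    manifest$stages$features <- list(n_genes = nrow(ft))
  })

  manifest_path <- file.path(config$output_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), manifest_path)
  outputs["manifest"] <- manifest_path
  invisible(outputs)
}
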