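#' Configuration for the synthetic ribosome-profiling generator
#'
#' The generator emulates the statistical structure of a two-condition yeast
#' ribosome-profiling experiment probing a 40S recycling defect: NB-distributed
#' RNA and RPF counts over a few thousand genes (2 replicates x 2 conditions x
#' 2 assays), a stop-codon footprint peak, a queuing peak one ribosome
#' footprint (~30 nt) upstream of the stop codon in the perturbed condition,
#' elevated 3'UTR footprints in the perturbed condition, uORFs with 3-nt
#' periodic footprints, and TE reprogramming optionally driven by the
#' initiation-competition model.
#'
#' @param n_genes number of genes/transcripts.
#' @param n_replicates replicates per (condition x assay) cell.
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param rna_mean_log10_range log10 interval for per-gene mRNA abundance
#'   (expected RNA counts at size factor 1).
#' @param te_meanlog,te_sdlog natural-log location/scale of the basal-TE
#'   lognormal.
#' @param te_cds_slope coupling of log TE to standardized log CDS length
#'   (negative: short CDSs are better translated).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha*mu^2);
#'   0 gives Poisson counts.
#' @param frac_uorf_genes fraction of genes carrying 1-2 planted uORFs.
#' @param uorf_inframe_fraction f0, fraction of uORF footprints in frame 0;
#'   must lie in (1/3, 1].
#' @param uorf_rel_density uORF footprint density relative to the CDS.
#' @param uorf_start_boost extra enrichment of the uORF start codon
#'   (initiating-ribosome peak).
#' @param uorf_log2fc uORF-specific log2 density change in the perturbed
#'   condition (planted differential-RRO effect).
#' @param utr5_rate,utr3_rate background footprint rate per UTR nucleotide,
#'   relative to the mean CDS per-nt density; `utr3_rate` is a named pair
#'   `c(reference=, perturbed=)` (elevated in the perturbed condition for a
#'   recycling defect).
#' @param queue_offset queue-peak position, nt upstream of the stop codon's
#'   first nucleotide (default 30, one ribosome footprint).
#' @param queue_enrichment fold enrichment of the queue codon in the
#'   perturbed condition (>= 1; 1 disables the peak).
#' @param stop_peak_enrichment fold enrichment of the stop codon (both
#'   conditions; the terminating-ribosome peak).
#' @param te_effect_model `"none"` (null), `"planted_table"` (fixed log2
#'   effects on a gene subset) or `"competition"` (effects from
#'   [relative_te_change()] with the PIC pool scaled by `pool_fraction`).
#' @param planted_n,planted_log2 number of affected genes and their log2
#'   effect under `"planted_table"`.
#' @param pool_fraction perturbed/reference 43S pool ratio under
#'   `"competition"`.
#' @param size_factor_range log-uniform interval for library size factors.
#' @param cds_meanlog,cds_sdlog lognormal parameters of CDS length
#'   (default median ~1.2 kb).
#' @param utr5_median,utr3_median medians of the geometric-like UTR length
#'   distributions (nt).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L, n_replicates = 2L, seed = 1L,
                              rna_mean_log10_range = c(0.5, 3),
                              te_meanlog = 0, te_sdlog = 0.5,
                              te_cds_slope = -0.4,
                              nb_dispersion = 0.01,
                              frac_uorf_genes = 0.15,
                              uorf_inframe_fraction = 0.7,
                              uorf_rel_density = 0.8,
                              uorf_start_boost = 6,
                              uorf_log2fc = 0,
                              utr5_rate = 0.002,
                              utr3_rate = c(reference = 0.01, perturbed = 0.04),
                              queue_offset = 30L,
                              queue_enrichment = 4,
                              stop_peak_enrichment = 4,
                              te_effect_model = c("none", "planted_table", "competition"),
                              planted_n = 100L, planted_log2 = 1,
                              pool_fraction = 0.5,
                              size_factor_range = c(0.5, 2),
                              cds_meanlog = log(1200), cds_sdlog = 0.55,
                              utr5_median = 60, utr3_median = 120) {
  te_effect_model <- match.arg(te_effect_model)
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    rna_mean_log10_range = rna_mean_log10_range,
    te_meanlog = te_meanlog, te_sdlog = te_sdlog, te_cds_slope = te_cds_slope,
    nb_dispersion = nb_dispersion,
    frac_uorf_genes = frac_uorf_genes,
    uorf_inframe_fraction = uorf_inframe_fraction,
    uorf_rel_density = uorf_rel_density,
    uorf_start_boost = uorf_start_boost,
    uorf_log2fc = uorf_log2fc,
    utr5_rate = utr5_rate, utr3_rate = utr3_rate,
    queue_offset = as.integer(queue_offset),
    queue_enrichment = queue_enrichment,
    stop_peak_enrichment = stop_peak_enrichment,
    te_effect_model = te_effect_model,
    planted_n = as.integer(planted_n), planted_log2 = planted_log2,
    pool_fraction = pool_fraction,
    size_factor_range = size_factor_range,
    cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
    utr5_median = utr5_median, utr3_median = utr3_median
  )
  stopifnot(
    cfg$n_genes >= 1L, cfg$n_replicates >= 1L,
    cfg$nb_dispersion >= 0,
    cfg$frac_uorf_genes >= 0, cfg$frac_uorf_genes <= 1,
    cfg$uorf_inframe_fraction > 1 / 3, cfg$uorf_inframe_fraction <= 1,
    cfg$queue_enrichment >= 1, cfg$stop_peak_enrichment >= 1,
    all(cfg$utr3_rate >= 0), cfg$utr5_rate >= 0,
    all(c("reference", "perturbed") %in% names(cfg$utr3_rate)),
    cfg$pool_fraction > 0,
    all(cfg$size_factor_range > 0)
  )
  structure(cfg, class = "simulation_config")
}

# Fixed-jump RNG sub-streams (L'Ecuyer-CMRG). Stream 1 drives the
# transcriptome; each library owns a later stream at a fixed index, so adding
# libraries never perturbs draws in earlier ones.
rng_stream_seeds <- function(seed, n_streams) {
  old <- globalenv()$.Random.seed
  old_kind <- RNGkind()
  on.exit({
    if (is.null(old)) {
      # no prior state: restore the entry generator kind, then clear
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

with_stream <- function(stream_seed, expr) {
  old <- globalenv()$.Random.seed
  old_kind <- RNGkind()
  assign(".Random.seed", stream_seed, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

MAX_REPLICATE_STREAMS <- 64L

library_stream_index <- function(assay, condition, replicate) {
  ai <- match(assay, c("RNA", "RPF")) - 1L
  ci <- match(condition, c("reference", "perturbed")) - 1L
  1L + ai * 2L * MAX_REPLICATE_STREAMS + ci * MAX_REPLICATE_STREAMS + replicate
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA")
)
STOP_CODONS <- c("TAA", "TAG", "TGA")
NEAR_COGNATE_STARTS <- c("GTG", "TTG", "CTG", "ATA", "ATT", "ATC",
                         "ACG", "AGG", "AAG")

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# geometric-like length with the requested median and a hard minimum
rgeom_median <- function(n, med, minimum) {
  p <- 1 - 2^(-1 / med)
  minimum + stats::rgeom(n, p)
}

#' Simulate a transcriptome with planted translational structure
#'
#' Draws transcript architectures (lognormal CDS lengths, geometric-like UTR
#' lengths), sequences, basal TEs negatively coupled to CDS length, mRNA
#' abundances, planted uORFs wholly inside 5'UTRs (AUG or near-cognate
#' starts), and per-gene planted log2 TE effects according to
#' `te_effect_model`.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `models` (a `transcript_models` table), `te`
#'   (basal TE, linear scale), `abundance`, `effects` (planted log2 dTE),
#'   `uorf_truth` (tibble of planted uORFs), `K1` (competition rate constants
#'   when `te_effect_model == "competition"`, else `NULL`) and `config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  streams <- rng_stream_seeds(config$seed, 1L)
  with_stream(streams[[1]], {
    n <- config$n_genes
    ids <- sprintf("TX%04d", seq_len(n))
    cds_len <- 3L * pmax(50L, as.integer(round(
      stats::rlnorm(n, config$cds_meanlog, config$cds_sdlog) / 3)))
    utr3_len <- as.integer(rgeom_median(n, config$utr3_median, 20L))
    utr5_len <- as.integer(rgeom_median(n, config$utr5_median, 12L))

    n_uorf_genes <- round(config$frac_uorf_genes * n)
    uorf_gene_idx <- if (n_uorf_genes > 0) sort(sample.int(n, n_uorf_genes)) else integer(0)

    # plant uORFs, resampling the 5'UTR when a uORF cannot fit
    uorf_rows <- list()
    utr5_seq <- character(n)
    for (i in seq_len(n)) {
      if (i %in% uorf_gene_idx) {
        n_uorfs <- sample(1:2, 1)
        lens <- sample(3:7, n_uorfs, replace = TRUE)     # codons incl. stop
        need <- sum(3L * lens) + 3L * (n_uorfs + 1L) + 6L  # spacing + edges
        tries <- 0L
        while (utr5_len[i] < need) {
          tries <- tries + 1L
          if (tries > 20L) stop("uORF cannot fit in 5'UTR of ", ids[i],
                                " after 20 UTR resamples")
          utr5_len[i] <- as.integer(rgeom_median(1, config$utr5_median, need))
        }
        # lay uORFs left to right with >= 3 nt gaps, start >= 3,
        # stop + 3 <= utr5_len
        seq_chars <- strsplit(random_nt(utr5_len[i]), "")[[1]]
        cursor <- 3L
        free <- utr5_len[i] - 3L - cursor - sum(3L * lens) - 3L * (n_uorfs - 1L)
        for (k in seq_len(n_uorfs)) {
          gap <- if (free > 0) sample.int(free + 1L, 1) - 1L else 0L
          free <- free - gap
          start <- cursor + gap
          start_codon <- if (stats::runif(1) < 0.4) "ATG" else
            sample(NEAR_COGNATE_STARTS, 1)
          body <- sample(SENSE_CODONS, lens[k] - 2L, replace = TRUE)
          stopc <- sample(STOP_CODONS, 1)
          uorf_seq <- strsplit(paste0(start_codon, paste(body, collapse = ""),
                                      stopc), "")[[1]]
          seq_chars[(start + 1L):(start + 3L * lens[k])] <- uorf_seq
          uorf_rows[[length(uorf_rows) + 1L]] <- tibble::tibble(
            transcript_id = ids[i],
            start = start, start_codon = start_codon,
            n_codons = lens[k], stop = start + 3L * (lens[k] - 1L)
          )
          cursor <- start + 3L * lens[k] + 3L
        }
        utr5_seq[i] <- paste(seq_chars, collapse = "")
      } else {
        utr5_seq[i] <- random_nt(utr5_len[i])
      }
    }

    cds_seq <- vapply(cds_len, function(L) {
      paste0("ATG",
             paste(sample(SENSE_CODONS, L / 3 - 2L, replace = TRUE), collapse = ""),
             sample(STOP_CODONS, 1))
    }, character(1))
    utr3_seq <- vapply(utr3_len, random_nt, character(1))

    models <- transcript_models(
      transcript_id = ids,
      gene_id = sub("^TX", "G", ids),
      utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
      sequence = paste0(utr5_seq, cds_seq, utr3_seq)
    )

    z_cds <- as.numeric(scale(log(cds_len)))
    log_te <- config$te_meanlog + config$te_cds_slope * z_cds +
      stats::rnorm(n, 0, config$te_sdlog)
    te <- exp(log_te)
    abundance <- 10^stats::runif(n, config$rna_mean_log10_range[1],
                                 config$rna_mean_log10_range[2])

    K1 <- NULL
    effects <- numeric(n)
    if (config$te_effect_model == "planted_table") {
      hit <- sample.int(n, min(config$planted_n, n))
      effects[hit] <- config$planted_log2
    } else if (config$te_effect_model == "competition") {
      K1 <- te  # initiation strength is what basal TE measures
      params <- competition_params(K1 = K1, m = abundance / mean(abundance),
                                   Jmax = 10, R_total = 5 * n, L = 1)
      effects <- relative_te_change(params, 5 * n, 5 * n * config$pool_fraction)
    }

    uorf_truth <- if (length(uorf_rows)) do.call(rbind, uorf_rows) else
      tibble::tibble(transcript_id = character(), start = integer(),
                     start_codon = character(), n_codons = integer(),
                     stop = integer())

    list(models = models, te = te, abundance = abundance, effects = effects,
         uorf_truth = uorf_truth, K1 = K1, config = config)
  })
}

nb_draw <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate counts from a synthetic transcriptome
#'
#' Draws the gene x library count matrix and, optionally, per-nucleotide
#' P-site tracks for every RPF library. RNA counts are NB with mean
#' `abundance * sf`; RPF CDS totals are NB with mean
#' `abundance * TE * 2^(effect in perturbed) * sf`. Each RPF total is then
#' spread multinomially over the CDS with a uniform base rate, the stop codon
#' elevated by `stop_peak_enrichment`, and (perturbed condition only) the
#' codon centered `queue_offset` nt upstream of the stop elevated by
#' `queue_enrichment` - so positional CDS sums equal the matrix RPF cells
#' exactly. 3'UTR and 5'UTR positions receive Poisson background at the
#' configured rates relative to the realized CDS density, and planted uORFs
#' receive 3-nt periodic reads (frame-0 fraction `f0`) with an elevated start
#' codon.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param tracks if `TRUE`, generate positional tracks for RPF libraries.
#' @return a list: `matrix` (a `count_matrix`), `tracks` (named list of
#'   `positional_counts`, one per RPF library; empty if `tracks = FALSE`),
#'   `size_factors` (named per-library vector, log-uniform in the configured
#'   range), plus the `sim` truth fields passed through.
#' @export
simulate_counts <- function(sim, tracks = TRUE) {
  config <- sim$config
  models <- sim$models
  n <- config$n_genes
  reps <- seq_len(config$n_replicates)
  libraries <- expand.grid(replicate = reps,
                           condition = c("reference", "perturbed"),
                           assay = c("RNA", "RPF"),
                           stringsAsFactors = FALSE)
  libraries <- tibble::as_tibble(libraries[, c("condition", "assay", "replicate")])
  libraries$library_id <- sprintf("%s_%s_rep%d", tolower(libraries$assay),
                                  libraries$condition, libraries$replicate)
  libraries <- libraries[, c("library_id", "condition", "assay", "replicate")]

  n_streams <- 1L + 4L * MAX_REPLICATE_STREAMS
  streams <- rng_stream_seeds(config$seed, n_streams)

  stop_first <- stop_codon_first(models)
  cds_from <- cds_first(models)
  cds_to <- cds_last(models)
  L_tx <- tx_length(models)

  counts <- matrix(0L, n, nrow(libraries),
                   dimnames = list(models$transcript_id, libraries$library_id))
  track_list <- list()
  size_factors <- numeric(nrow(libraries))
  names(size_factors) <- libraries$library_id

  uorf_by_tx <- split(sim$uorf_truth, sim$uorf_truth$transcript_id)
  f0 <- config$uorf_inframe_fraction
  frame_w <- 3 * c(f0, (1 - f0) / 2, (1 - f0) / 2)

  for (j in seq_len(nrow(libraries))) {
    lib <- libraries[j, ]
    idx <- library_stream_index(lib$assay, lib$condition, lib$replicate)
    res <- with_stream(streams[[idx]], {
      sf <- exp(stats::runif(1, log(config$size_factor_range[1]),
                             log(config$size_factor_range[2])))
      perturbed <- lib$condition == "perturbed"
      if (lib$assay == "RNA") {
        list(sf = sf,
             counts = as.integer(nb_draw(n, sim$abundance * sf,
                                         config$nb_dispersion)),
             track = NULL)
      } else {
        mu <- sim$abundance * sim$te * 2^(sim$effects * perturbed) * sf
        totals <- as.integer(nb_draw(n, mu, config$nb_dispersion))
        track <- NULL
        if (tracks) {
          track <- vector("list", n)
          names(track) <- models$transcript_id
          utr3_r <- config$utr3_rate[[lib$condition]]
          uorf_gain <- if (perturbed) 2^config$uorf_log2fc else 1
          for (i in seq_len(n)) {
            v <- integer(L_tx[i])
            cds_pos <- cds_from[i]:cds_to[i]            # 0-based
            w <- rep(1, length(cds_pos))
            stop_rel <- (stop_first[i] - cds_from[i]) + 1:3
            w[stop_rel] <- config$stop_peak_enrichment
            if (perturbed && config$queue_enrichment > 1) {
              # queue codon centered -queue_offset from the stop codon start;
              # weight is center-heavy (the stalled 80S has one P-site), so
              # the planted peak is sharp at the center nucleotide
              queue_rel <- stop_rel - config$queue_offset - 1L
              queue_w <- config$queue_enrichment * c(0.5, 2, 0.5)
              keep <- queue_rel >= 1
              w[queue_rel[keep]] <- queue_w[keep]
            }
            if (totals[i] > 0) {
              v[cds_pos + 1L] <- as.integer(
                stats::rmultinom(1, totals[i], w / sum(w)))
            }
            # extra-CDS reads follow the EXPECTED density, with one
            # independent gamma multiplier of variance alpha per region and
            # library: each region is marginally NB at the study dispersion,
            # with no cross-region noise coupling
            d <- mu[i] / models$cds_len[i]
            region_g <- function() {
              if (config$nb_dispersion <= 0) 1 else
                stats::rgamma(1, shape = 1 / config$nb_dispersion,
                              rate = 1 / config$nb_dispersion)
            }
            if (models$utr3_len[i] > 0 && utr3_r > 0 && d > 0) {
              p3 <- (cds_to[i] + 1L):(L_tx[i] - 1L)
              v[p3 + 1L] <- v[p3 + 1L] +
                stats::rpois(length(p3), region_g() * utr3_r * d)
            }
            if (models$utr5_len[i] > 0 && config$utr5_rate > 0 && d > 0) {
              p5 <- 0:(models$utr5_len[i] - 1L)
              v[p5 + 1L] <- v[p5 + 1L] +
                stats::rpois(length(p5), region_g() * config$utr5_rate * d)
            }
            uo <- uorf_by_tx[[models$transcript_id[i]]]
            if (!is.null(uo) && d > 0) {
              for (k in seq_len(nrow(uo))) {
                pos <- uo$start[k]:(uo$stop[k] + 2L)
                frame <- (pos - uo$start[k]) %% 3L
                mu_p <- config$uorf_rel_density * uorf_gain * d * frame_w[frame + 1L]
                boost <- ifelse(pos < uo$start[k] + 3L, config$uorf_start_boost, 1)
                v[pos + 1L] <- v[pos + 1L] +
                  stats::rpois(length(pos), region_g() * mu_p * boost)
              }
            }
            track[[i]] <- v
          }
        }
        list(sf = sf, counts = totals, track = track)
      }
    })
    size_factors[j] <- res$sf
    counts[, j] <- res$counts
    if (!is.null(res$track)) {
      track_list[[lib$library_id]] <- positional_counts(res$track, models)
    }
  }

  list(matrix = count_matrix(counts, libraries),
       tracks = track_list,
       size_factors = size_factors,
       models = models, te = sim$te, abundance = sim$abundance,
       effects = sim$effects, uorf_truth = sim$uorf_truth, config = config)
}

#' Write a full synthetic dataset to disk
#'
#' Emits annotation (GFF3), sequences (FASTA), one wiggle track per RPF
#' library, the count matrix and metadata TSVs, and a truth TSV (basal TE,
#' abundance, planted effects) for recovery tests.
#'
#' @param data output of [simulate_counts()] (with tracks).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    annotation = file.path(dir, "annotation.gff3"),
    fasta = file.path(dir, "transcripts.fa"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "libraries.tsv"),
    truth = file.path(dir, "truth.tsv"),
    uorf_truth = file.path(dir, "uorf_truth.tsv")
  )
  write_annotation(data$models, paths[["annotation"]], "gff3")
  write_transcript_fasta(data$models, paths[["fasta"]])
  write_count_matrix(data$matrix, paths[["counts"]], paths[["metadata"]])
  truth <- tibble::tibble(
    transcript_id = data$models$transcript_id,
    gene_id = data$models$gene_id,
    basal_te = data$te, abundance = data$abundance,
    planted_log2dte = data$effects
  )
  readr::write_tsv(truth, paths[["truth"]], progress = FALSE)
  readr::write_tsv(data$uorf_truth, paths[["uorf_truth"]], progress = FALSE)
  for (lib in names(data$tracks)) {
    p <- file.path(dir, paste0(lib, ".wig"))
    write_positional_counts(data$tracks[[lib]], p, "wiggle")
    paths[[lib]] <- p
  }
  invisible(paths)
}
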