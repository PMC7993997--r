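#' Near-cognate start codons (single mismatch to ATG)
#' @export
near_cognate_codons <- function() {
  c("GTG", "TTG", "CTG", "ATA", "ATT", "ATC", "ACG", "AGG", "AAG")
}

#' Enumerate candidate uORFs in a 5'UTR
#'
#' Scans the 5'UTR for ATG and the nine near-cognate start codons (single
#' mismatch to ATG) and extends each in frame to the first stop codon.
#' Candidates are kept only if they terminate wholly inside the 5'UTR
#' (`stop + 3 <= utr5_len`), are at least 3 codons long including the stop
#' codon, and start at position >= 3 (so a -1 triplet exists upstream).
#'
#' @param model a one-row `transcript_models` table with a sequence.
#' @return tibble of candidates sorted by start: `transcript_id`, `uorf_id`
#'   (`transcript:start:codon`), `start` (0-based first nt of the start
#'   codon), `start_codon`, `n_codons` (including the stop codon), `stop`
#'   (0-based first nt of the stop codon).
#' @export
enumerate_candidates <- function(model) {
  stopifnot(nrow(model) == 1L)
  if (is.na(model$sequence)) stop("sequence missing for ", model$transcript_id)
  utr5 <- model$utr5_len
  empty <- tibble::tibble(transcript_id = character(), uorf_id = character(),
                          start = integer(), start_codon = character(),
                          n_codons = integer(), stop = integer())
  if (utr5 < 9L) return(empty)
  seq5 <- substr(model$sequence, 1L, utr5)
  starts_set <- c("ATG", near_cognate_codons())
  rows <- list()
  for (s in 3:(utr5 - 3L)) {                     # 0-based start position
    codon <- substr(seq5, s + 1L, s + 3L)
    if (!codon %in% starts_set) next
    # extend in frame to the first stop wholly inside the UTR
    p <- s + 3L
    stop_at <- NA_integer_
    while (p + 3L <= utr5) {
      c2 <- substr(seq5, p + 1L, p + 3L)
      if (c2 %in% c("TAA", "TAG", "TGA")) { stop_at <- p; break }
      p <- p + 3L
    }
    if (is.na(stop_at)) next                     # runs into the CDS: discard
    n_codons <- (stop_at - s) / 3L + 1L
    if (n_codons < 3L) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = model$transcript_id,
      uorf_id = sprintf("%s:%d:%s", model$transcript_id, s, codon),
      start = as.integer(s), start_codon = codon,
      n_codons = as.integer(n_codons), stop = as.integer(stop_at)
    )
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Enumerate candidate uORFs for many transcripts
#' @param models a `transcript_models` table with sequences.
#' @return row-bound candidate tibble (see [enumerate_candidates()]).
#' @export
enumerate_candidates_all <- function(models) {
  do.call(rbind, lapply(seq_len(nrow(models)),
                        function(i) enumerate_candidates(models[i, ])))
}

#' Start-site footprint filters for a uORF candidate
#'
#' Computes the yassour-uorf style start-site statistics from a P-site track:
#' `plus1_count` sums the 3 nt of the start codon (+1 "position" read as a
#' codon-width window), `minus1_count` the 3 nt immediately upstream. Filters:
#' ratio `plus1/minus1 > 4` (when `minus1 == 0`, pass iff `plus1 > 4`),
#' combined `plus1 + minus1 > 14`, and frame fraction (share of uORF counts
#' at positions congruent to the start mod 3) `> 0.5`. Single-nucleotide
#' windows are available via `codon_window = FALSE`.
#'
#' @param candidates candidate tibble for one transcript.
#' @param track integer count vector for that transcript.
#' @param ratio_threshold,combined_threshold,frame_threshold filter
#'   thresholds (defaults 4, 14, 0.5; all strict inequalities).
#' @param codon_window if `FALSE`, +1/-1 are single nucleotides.
#' @return `candidates` with columns `plus1_count`, `minus1_count`,
#'   `ratio_pass`, `count_pass`, `frame_fraction`, `frame_pass` appended.
#' @export
start_site_filter <- function(candidates, track, ratio_threshold = 4,
                              combined_threshold = 14, frame_threshold = 0.5,
                              codon_window = TRUE) {
  w <- if (codon_window) 3L else 1L
  n <- nrow(candidates)
  plus1 <- minus1 <- integer(n)
  frame_fraction <- numeric(n)
  for (i in seq_len(n)) {
    s <- candidates$start[i]
    plus1[i] <- sum(track[(s + 1L):(s + w)])
    minus1[i] <- sum(track[(s - w + 1L):s])
    body <- s:(candidates$stop[i] + 2L)            # whole uORF, 0-based
    total <- sum(track[body + 1L])
    in_frame <- sum(track[body[(body - s) %% 3L == 0L] + 1L])
    frame_fraction[i] <- if (total > 0) in_frame / total else 0
  }
  candidates$plus1_count <- plus1
  candidates$minus1_count <- minus1
  candidates$ratio_pass <- ifelse(minus1 > 0L,
                                  plus1 / minus1 > ratio_threshold,
                                  plus1 > ratio_threshold)
  candidates$count_pass <- (plus1 + minus1) > combined_threshold
  candidates$frame_fraction <- frame_fraction
  candidates$frame_pass <- frame_fraction > frame_threshold
  candidates
}

#' Periodicity/uniformity translation score
#'
#' A deterministic surrogate for a trained periodicity classifier, built from
#' the two features it uses: 3-nt periodicity and uniformity of reads across
#' uORF codons. The score is `sqrt(f0_hat * PME)` where
#' `f0_hat = clip((frame_fraction - 1/3) / (2/3), 0, 1)` rescales the frame
#' fraction so random-frame reads score 0 and perfectly phased reads score 1,
#' and `PME` is the Shannon entropy of the per-codon count distribution
#' divided by `log(n_codons)` (1 = perfectly uniform, 0 = one codon carries
#' everything). `periodicity_pass` requires score > `threshold` (default
#' 0.5); `translated` additionally requires all start-site filters.
#'
#' @param candidates output of [start_site_filter()] for one transcript.
#' @param track integer count vector for that transcript.
#' @param threshold probability threshold (default 0.5, strict).
#' @return `candidates` with `periodicity_prob`, `periodicity_pass` and
#'   `translated` appended.
#' @export
periodicity_score <- function(candidates, track, threshold = 0.5) {
  n <- nrow(candidates)
  score <- numeric(n)
  for (i in seq_len(n)) {
    s <- candidates$start[i]
    nc <- candidates$n_codons[i]
    codon_counts <- vapply(seq_len(nc), function(k) {
      sum(track[(s + 3L * (k - 1L) + 1L):(s + 3L * k)])
    }, numeric(1))
    total <- sum(codon_counts)
    if (total == 0) { score[i] <- 0; next }
    f0_hat <- min(max((candidates$frame_fraction[i] - 1 / 3) / (2 / 3), 0), 1)
    p <- codon_counts[codon_counts > 0] / total
    pme <- -sum(p * log(p)) / log(nc)
    score[i] <- sqrt(f0_hat * pme)
  }
  candidates$periodicity_prob <- score
  candidates$periodicity_pass <- score > threshold
  candidates$translated <- candidates$ratio_pass & candidates$count_pass &
    candidates$frame_pass & candidates$periodicity_pass
  candidates
}

#' Run the full translation-calling cascade over many transcripts
#'
#' Enumerates candidates and applies the start-site and periodicity filters
#' using one P-site track set (typically pooled RPF libraries of the
#' reference condition).
#'
#' @param models a `transcript_models` table with sequences.
#' @param tracks a `positional_counts` object.
#' @param ... thresholds passed to [start_site_filter()] and
#'   [periodicity_score()].
#' @return filter-report tibble, one row per candidate with every filter
#'   field and the final `translated` call.
#' @export
call_translated_uorfs <- function(models, tracks,
                                  ratio_threshold = 4, combined_threshold = 14,
                                  frame_threshold = 0.5,
                                  periodicity_threshold = 0.5) {
  out <- lapply(seq_len(nrow(models)), function(i) {
    cand <- enumerate_candidates(models[i, ])
    if (!nrow(cand)) return(NULL)
    track <- tracks[[models$transcript_id[i]]]
    if (is.null(track)) return(NULL)
    cand <- start_site_filter(cand, track, ratio_threshold,
                              combined_threshold, frame_threshold)
    periodicity_score(cand, track, periodicity_threshold)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    stop("no uORF candidates with tracks found")
  }
  do.call(rbind, out)
}

#' RRO counting windows for one uORF
#'
#' Relative ribosome occupancy compares footprints in a uORF to its main
#' CDS, using interior windows that avoid initiation/termination peaks: the
#' uORF window is its sense codons minus the first and last (the stop codon
#' itself, like the CDS stop, is excluded to avoid the termination peak), and
#' any positions inside the 5'UTR's first or last nucleotide triplet are
#' masked; the CDS window drops the first 20 codons and the final (stop)
#' codon. A 3-codon uORF (start + one sense codon + stop) therefore has an
#' empty window and is excluded.
#'
#' @param candidate one-row candidate tibble.
#' @param model the matching one-row `transcript_models` table.
#' @return list of 0-based position vectors `uorf_window`, `cds_window`; the
#'   uORF window may be empty (3-codon uORFs have no interior).
#' @export
rro_windows <- function(candidate, model) {
  stopifnot(nrow(candidate) == 1L, nrow(model) == 1L)
  utr5 <- model$utr5_len
  s <- candidate$start; st <- candidate$stop
  uorf_win <- if (st - 4L >= s + 3L) (s + 3L):(st - 4L) else integer(0)
  edge_mask <- c(0:2, (utr5 - 3L):(utr5 - 1L))
  uorf_win <- setdiff(uorf_win, edge_mask)
  cds_from <- cds_first(model) + 60L            # skip first 20 codons
  cds_to <- stop_codon_first(model) - 1L        # skip the stop codon
  cds_win <- if (cds_from <= cds_to) cds_from:cds_to else integer(0)
  list(uorf_window = uorf_win, cds_window = cds_win)
}

#' Per-library RRO ingredients for translated uORFs
#'
#' Sums P-site counts over the RRO windows of each uORF and its main CDS in
#' every RPF library. The RRO itself is the ratio of uORF to CDS window
#' counts (scale factors cancel in the ratio, so it is invariant under
#' per-library scaling).
#'
#' @param candidates filter-report tibble (normally only `translated` rows).
#' @param models a `transcript_models` table.
#' @param tracks named list of `positional_counts`, one per RPF library.
#' @return list with `uorf_counts` and `cds_counts` (uORF x library integer
#'   matrices), `rro` (matrix of per-library ratios, `NA` where the CDS
#'   window is empty of counts) and `excluded` (tibble of uORFs dropped for
#'   an empty interior window, with reasons).
#' @export
compute_rro <- function(candidates, models, tracks) {
  stopifnot(length(tracks) >= 1L)
  libs <- names(tracks)
  model_of <- match(candidates$transcript_id, models$transcript_id)
  keep <- logical(nrow(candidates))
  reasons <- character(nrow(candidates))
  uorf_counts <- cds_counts <- matrix(
    0L, nrow(candidates), length(libs),
    dimnames = list(candidates$uorf_id, libs))
  for (i in seq_len(nrow(candidates))) {
    win <- rro_windows(candidates[i, ], models[model_of[i], ])
    if (!length(win$uorf_window)) {
      reasons[i] <- "empty_uorf_interior"
      next
    }
    if (!length(win$cds_window)) {
      reasons[i] <- "empty_cds_interior"
      next
    }
    keep[i] <- TRUE
    tx <- candidates$transcript_id[i]
    for (j in seq_along(libs)) {
      v <- tracks[[libs[j]]][[tx]]
      uorf_counts[i, j] <- sum(v[win$uorf_window + 1L])
      cds_counts[i, j] <- sum(v[win$cds_window + 1L])
    }
  }
  excluded <- tibble::tibble(uorf_id = candidates$uorf_id[!keep],
                             reason = reasons[!keep])
  uorf_counts <- uorf_counts[keep, , drop = FALSE]
  cds_counts <- cds_counts[keep, , drop = FALSE]
  rro <- ifelse(cds_counts > 0, uorf_counts / cds_counts, NA_real_)
  list(uorf_counts = uorf_counts, cds_counts = cds_counts, rro = rro,
       excluded = excluded)
}

#' Differential relative ribosome occupancy
#'
#' Tests for condition-dependent changes in uORF-to-CDS occupancy. uORFs with
#' mean uORF-window RPF counts < `uorf_floor` (default 2) or mean CDS-window
#' counts < `cds_floor` (default 32) across the RPF libraries are excluded.
#' The remaining uORF/CDS count pairs are fit with the same NB interaction
#' GLM as [fit_dte()], treating region (uORF vs CDS) as the assay factor, so
#' `log2dRRO` is the region x condition interaction; BH FDR across tested
#' uORFs.
#'
#' @param rro output of [compute_rro()].
#' @param libraries metadata tibble for the RPF libraries named in the RRO
#'   matrices (`library_id`, `condition`, `replicate`).
#' @param sf per-library size factors (named; defaults to 1s).
#' @param uorf_floor,cds_floor mean-count exclusion floors.
#' @param fdr_threshold classification threshold.
#' @return an `rro_result` tibble: `uorf_id`, `rro_reference`,
#'   `rro_perturbed`, `log2dRRO`, `se`, `wald_z`, `p_value`, `fdr`, `class`,
#'   plus `excluded` rows carried in the `excluded` attribute.
#' @export
diff_rro <- function(rro, libraries, sf = NULL, uorf_floor = 2, cds_floor = 32,
                     fdr_threshold = 0.05) {
  libs <- colnames(rro$uorf_counts)
  meta <- libraries[match(libs, libraries$library_id), ]
  if (anyNA(meta$library_id)) stop("metadata missing for some RPF libraries")
  if (is.null(sf)) sf <- stats::setNames(rep(1, length(libs)), libs)
  sf <- sf[libs]

  mean_uorf <- rowMeans(rro$uorf_counts)
  mean_cds <- rowMeans(rro$cds_counts)
  keep <- mean_uorf >= uorf_floor & mean_cds >= cds_floor
  excluded <- rbind(
    rro$excluded,
    tibble::tibble(uorf_id = rownames(rro$uorf_counts)[!keep],
                   reason = ifelse(mean_uorf[!keep] < uorf_floor,
                                   "mean_uorf_counts_below_floor",
                                   "mean_cds_counts_below_floor"))
  )
  u <- rro$uorf_counts[keep, , drop = FALSE]
  cc <- rro$cds_counts[keep, , drop = FALSE]
  if (!nrow(u)) stop("no uORF passes the count floors")

  # stack CDS and uORF windows as the two levels of the 'assay' factor
  counts <- cbind(cc, u)
  colnames(counts) <- c(paste0("cds_", libs), paste0("uorf_", libs))
  f_region <- factor(rep(c("CDS", "uORF"), each = length(libs)),
                     levels = c("CDS", "uORF"))
  f_cond <- factor(rep(meta$condition, 2), levels = c("reference", "perturbed"))
  sf2 <- rep(sf, 2)

  # dispersions from the stacked matrix, cells = region x condition
  cm <- count_matrix(counts, tibble::tibble(
    library_id = colnames(counts),
    condition = as.character(f_cond),
    assay = ifelse(f_region == "uORF", "RPF", "RNA"),
    replicate = rep(meta$replicate, 2)
  ))
  disp <- estimate_dispersions(cm, sf2)
  fit <- nb_interaction_fit(counts, f_region, f_cond, sf2, disp$alpha)

  ref_libs <- libs[meta$condition == "reference"]
  per_libs <- libs[meta$condition == "perturbed"]
  rro_mean <- function(which_libs) {
    rowSums(u[, which_libs, drop = FALSE]) /
      pmax(rowSums(cc[, which_libs, drop = FALSE]), 1)
  }
  res <- tibble::tibble(
    uorf_id = rownames(u),
    rro_reference = rro_mean(ref_libs),
    rro_perturbed = rro_mean(per_libs),
    log2dRRO = fit$beta_int / log(2),
    se = fit$se_int / log(2),
    wald_z = fit$wald_z,
    p_value = ifelse(fit$converged, fit$p_value, NA_real_),
    converged = fit$converged
  )
  res$fdr <- NA_real_
  res$fdr[res$converged] <- stats::p.adjust(res$p_value[res$converged], "BH")
  res$class <- ifelse(!res$converged | is.na(res$fdr) | res$fdr >= fdr_threshold,
                      "ns", ifelse(res$log2dRRO > 0, "up", "down"))
  attr(res, "excluded") <- excluded
  class(res) <- c("rro_result", class(res))
  res
}
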