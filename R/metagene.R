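#' Stop-codon-anchored metagene profile
#'
#' Averages P-site density around stop codons across transcripts. Offsets are
#' relative to the first nucleotide of the stop codon (offset 0 = stop codon
#' start; negative = upstream, into the CDS). Each included transcript's
#' window counts are divided by that transcript's mean CDS per-nucleotide
#' density, then averaged with equal weight per transcript at each offset
#' over the transcripts defined there (transcripts shorter than the window
#' contribute only their defined offsets). This self-normalization makes the
#' profile scale-invariant and stops highly expressed genes from dominating;
#' a pooled raw-count mode is available via `pooled = TRUE`.
#'
#' @param tracks a `positional_counts` object (or plain named list of
#'   per-transcript count vectors).
#' @param models a `transcript_models` table.
#' @param window `c(upstream, downstream)` extent in nt around the stop-codon
#'   start (default 60 nt upstream, 90 downstream).
#' @param min_cds_counts transcripts with fewer total CDS counts are excluded
#'   (default 64).
#' @param pooled if `TRUE`, sum raw counts across transcripts instead of
#'   averaging normalized densities.
#' @return a `metagene_profile` tibble with columns `offset`, `mean_density`,
#'   `n_transcripts`.
#' @export
metagene_at_stop <- function(tracks, models, window = c(60L, 90L),
                             min_cds_counts = 64, pooled = FALSE) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] >= 0)
  offsets <- seq.int(-window[1], window[2])
  acc <- numeric(length(offsets))
  n_at <- integer(length(offsets))
  stop_first <- stats::setNames(stop_codon_first(models), models$transcript_id)
  c_from <- stats::setNames(cds_first(models), models$transcript_id)
  c_to <- stats::setNames(cds_last(models), models$transcript_id)
  n_used <- 0L
  n_seen <- 0L
  for (tx in intersect(models$transcript_id, names(tracks))) {
    v <- tracks[[tx]]
    n_seen <- n_seen + 1L
    cds_sum <- sum(v[(c_from[[tx]] + 1L):(c_to[[tx]] + 1L)])
    if (cds_sum < min_cds_counts) next
    n_used <- n_used + 1L
    dens <- cds_sum / (c_to[[tx]] - c_from[[tx]] + 1L)
    pos <- stop_first[[tx]] + offsets            # 0-based
    ok <- pos >= 0L & pos < length(v)
    vals <- v[pos[ok] + 1L]
    if (!pooled) vals <- vals / dens
    acc[ok] <- acc[ok] + vals
    n_at[ok] <- n_at[ok] + 1L
  }
  if (n_used == 0L) {
    stop("no transcript passed min_cds_counts = ", min_cds_counts,
         " (", n_seen, " transcripts had tracks)")
  }
  mean_density <- ifelse(n_at > 0L, acc / if (pooled) 1L else pmax(n_at, 1L), NA_real_)
  profile <- tibble::tibble(offset = offsets, mean_density = mean_density,
                            n_transcripts = n_at)
  class(profile) <- c("metagene_profile", class(profile))
  profile
}

#' Detect a queuing peak in a metagene profile
#'
#' Scans a search window upstream of the stop codon for the maximum mean
#' density (ties broken toward the most upstream offset) and reports its
#' enrichment over the mean density in a disjoint local CDS background
#' window. `is_queued` flags enrichment above `threshold` (default 1.5).
#'
#' @param profile a `metagene_profile`.
#' @param search_window `c(from, to)` offsets to scan (default `c(-50, -10)`).
#' @param background_window `c(from, to)` offsets for the background mean
#'   (default `c(-60, -51)`), disjoint from the search window.
#' @param threshold enrichment above which `is_queued` is `TRUE`.
#' @return a one-row tibble: `peak_offset`, `enrichment`, `is_queued`.
#' @export
detect_queue_peak <- function(profile, search_window = c(-50L, -10L),
                              background_window = c(-60L, -51L),
                              threshold = 1.5) {
  in_win <- function(w) profile$offset >= w[1] & profile$offset <= w[2]
  s <- in_win(search_window); b <- in_win(background_window)
  if (!any(s) || !any(b)) stop("window outside profile range")
  if (any(s & b)) stop("search and background windows must be disjoint")
  bg <- mean(profile$mean_density[b], na.rm = TRUE)
  if (!is.finite(bg) || bg == 0) stop("background mean density is zero")
  dens <- profile$mean_density[s]
  offs <- profile$offset[s]
  peak_i <- which.max(dens)   # which.max takes the first = most upstream tie
  enrichment <- dens[peak_i] / bg
  tibble::tibble(peak_offset = offs[peak_i], enrichment = enrichment,
                 is_queued = enrichment > threshold)
}

#' 3'UTR-to-ORF footprint ratio per transcript
#'
#' The reinitiation statistic: raw 3'UTR P-site counts over raw CDS counts,
#' with one pseudocount added to both numerator and denominator so the ratio
#' is always defined. Transcripts with no 3'UTR are skipped with a message.
#' Per-nucleotide density mode divides each region's counts by its length
#' before the pseudocount ratio.
#'
#' @param tracks a `positional_counts` object.
#' @param models a `transcript_models` table.
#' @param density if `TRUE` use per-nt densities instead of raw counts.
#' @return a tibble with `transcript_id`, `gene_id`, `utr3_counts`,
#'   `cds_counts`, `ratio` and `log2_ratio`.
#' @export
utr3_orf_ratio <- function(tracks, models, density = FALSE) {
  keep <- models$utr3_len > 0L
  if (any(!keep)) {
    message(sum(!keep), " transcript(s) without a 3'UTR skipped")
  }
  m <- models[keep, ]
  c_from <- cds_first(m); c_to <- cds_last(m)
  L_tx <- tx_length(m)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tx <- m$transcript_id[i]
    v <- tracks[[tx]]
    if (is.null(v)) return(NULL)
    cds <- sum(v[(c_from[i] + 1L):(c_to[i] + 1L)])
    utr3 <- sum(v[(c_to[i] + 2L):L_tx[i]])
    num <- if (density) utr3 / m$utr3_len[i] else utr3
    den <- if (density) cds / m$cds_len[i] else cds
    tibble::tibble(transcript_id = tx, gene_id = m$gene_id[i],
                   utr3_counts = utr3, cds_counts = cds,
                   ratio = (num + 1) / (den + 1))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no transcripts with tracks and a 3'UTR")
  out$log2_ratio <- log2(out$ratio)
  out
}
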