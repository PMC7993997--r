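#' Per-transcript positional P-site counts
#'
#' Positional counts are stored as a named list of non-negative integer
#' vectors, one per transcript, with one entry per transcript nucleotide
#' (0-based internally: `counts[[tx]][p + 1]` is the count at 0-based
#' position `p`). The constructor validates lengths against the models.
#'
#' @param counts named list of non-negative integer vectors.
#' @param models a `transcript_models` table covering every name in `counts`.
#' @return the validated list, classed `positional_counts`.
#' @export
positional_counts <- function(counts, models) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  len <- stats::setNames(tx_length(models), models$transcript_id)
  unknown <- setdiff(names(counts), names(len))
  if (length(unknown)) stop("counts for unknown transcripts: ",
                            paste(unknown, collapse = ", "))
  for (tx in names(counts)) {
    v <- counts[[tx]]
    if (length(v) != len[[tx]]) {
      stop("counts length ", length(v), " != transcript length ", len[[tx]],
           " for ", tx)
    }
    if (any(v < 0) || any(v != floor(v))) stop("non-integer or negative count in ", tx)
    counts[[tx]] <- as.integer(v)
  }
  structure(counts, class = c("positional_counts", "list"))
}

#' Read per-transcript positional counts (wiggle or TSV)
#'
#' The wiggle dialect is `variableStep` with 1-based positions and one
#' declaration line per transcript; the TSV dialect has columns
#' `transcript_id`, `pos` (0-based) and `count`. Positions absent from the
#' file are zero-filled; transcripts absent entirely get all-zero vectors.
#'
#' @param path track file.
#' @param models a `transcript_models` table (defines vector lengths).
#' @param format `"wiggle"` or `"tsv"`.
#' @return a `positional_counts` object covering every transcript in `models`.
#' @export
read_positional_counts <- function(path, models, format = c("wiggle", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("track file not found: ", path)
  len <- stats::setNames(tx_length(models), models$transcript_id)
  counts <- lapply(len, function(L) integer(L))
  if (format == "wiggle") {
    gr <- rtracklayer::import(path, format = "wig")
    tx <- as.character(GenomicRanges::seqnames(gr))
    from <- GenomicRanges::start(gr)
    w <- GenomicRanges::width(gr)
    pos <- sequence(w, from = from)               # 1-based, runs expanded
    val <- rep(as.integer(gr$score), w)
    tx_all <- rep(tx, w)
    by_tx <- split(seq_along(pos), tx_all)
    for (id in names(by_tx)) {
      if (!id %in% names(counts)) stop("track for unknown transcript: ", id)
      i <- by_tx[[id]]
      if (max(pos[i]) > len[[id]]) {
        stop("position ", max(pos[i]), " exceeds length ", len[[id]],
             " of ", id)
      }
      counts[[id]][pos[i]] <- val[i]
    }
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      transcript_id = readr::col_character(),
      pos = readr::col_integer(),
      count = readr::col_integer()
    ), progress = FALSE)
    for (id in unique(tab$transcript_id)) {
      if (!id %in% names(counts)) stop("track for unknown transcript: ", id)
      sub <- tab[tab$transcript_id == id, ]
      if (any(sub$pos < 0L) || any(sub$pos >= len[[id]])) {
        stop("position outside transcript ", id)
      }
      counts[[id]][sub$pos + 1L] <- sub$count
    }
  }
  positional_counts(counts, models)
}

#' Write positional counts as variableStep wiggle (or TSV)
#'
#' Only nonzero positions are emitted (wiggle convention); transcripts with
#' no signal get no declaration line. Byte-stable for identical inputs.
#'
#' @param counts a `positional_counts` object.
#' @param path output path.
#' @param format `"wiggle"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_positional_counts <- function(counts, path, format = c("wiggle", "tsv")) {
  format <- match.arg(format)
  ids <- sort(names(counts))
  if (format == "wiggle") {
    blocks <- lapply(ids, function(id) {
      v <- counts[[id]]
      nz <- which(v != 0L)
      if (!length(nz)) return(character(0))
      c(sprintf("variableStep chrom=%s", id), sprintf("%d %d", nz, v[nz]))
    })
    writeLines(unlist(blocks), path)
  } else {
    rows <- lapply(ids, function(id) {
      v <- counts[[id]]
      nz <- which(v != 0L)
      if (!length(nz)) return(NULL)
      tibble::tibble(transcript_id = id, pos = nz - 1L, count = v[nz])
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) tab <- tibble::tibble(transcript_id = character(),
                                            pos = integer(), count = integer())
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Map 5'-end read positions to P-sites by a fixed offset
#'
#' Helper for tracks recorded as read 5' ends rather than P-sites. Reads of
#' length 25-34 nt are shifted 3'-ward by a fixed offset (default +13 nt, the
#' conventional yeast 80S choice), overridable per read length.
#'
#' @param five_prime_positions 0-based 5'-end positions.
#' @param read_lengths read lengths in nt (25-34).
#' @param offsets named integer vector mapping read length to offset;
#'   lengths not named fall back to `default_offset`.
#' @param default_offset offset in nt for unlisted lengths.
#' @return 0-based P-site positions.
#' @export
psite_from_5p <- function(five_prime_positions, read_lengths,
                          offsets = integer(0), default_offset = 13L) {
  if (any(read_lengths < 25L | read_lengths > 34L)) {
    stop("read lengths outside the 25-34 nt size selection")
  }
  off <- rep.int(as.integer(default_offset), length(read_lengths))
  if (length(offsets)) {
    hit <- match(as.character(read_lengths), names(offsets))
    off[!is.na(hit)] <- as.integer(offsets[hit[!is.na(hit)]])
  }
  as.integer(five_prime_positions + off)
}
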