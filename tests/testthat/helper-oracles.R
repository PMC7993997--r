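# independent oracles, written as plain straight-line code so they share no
# machinery with the implementation they check

# brute-force uORF scan: test every (start, stop) pair explicitly
oracle_scan_uorfs <- function(sequence, utr5_len) {
  starts <- c("ATG", "GTG", "TTG", "CTG", "ATA", "ATT", "ATC", "ACG",
              "AGG", "AAG")
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  if (utr5_len < 9) {
    return(data.frame(start = integer(), stop = integer(),
                      n_codons = integer(), start_codon = character()))
  }
  for (s in seq(4, utr5_len - 2)) {          # 1-based first nt of start codon
    if (s < 4) next                          # need a -1 triplet
    cod <- substr(sequence, s, s + 2)
    if (!cod %in% starts) next
    stop_1b <- NA
    p <- s + 3
    repeat {
      if (p + 2 > utr5_len) break
      if (substr(sequence, p, p + 2) %in% stops) { stop_1b <- p; break }
      p <- p + 3
    }
    if (is.na(stop_1b)) next
    n_codons <- (stop_1b - s) / 3 + 1
    if (n_codons < 3) next
    found[[length(found) + 1]] <- data.frame(
      start = s - 1L, stop = stop_1b - 1L, n_codons = n_codons,
      start_codon = cod, stringsAsFactors = FALSE)
  }
  if (!length(found)) {
    return(data.frame(start = integer(), stop = integer(),
                      n_codons = integer(), start_codon = character()))
  }
  do.call(rbind, found)
}

# straight-line transcription of the published filter cascade for one uORF:
# +1/-1 ratio > 4, combined counts > 14, zero-frame fraction > 0.5, then the
# periodicity/uniformity probability > 0.5
oracle_translated <- function(track, start, stop, n_codons) {
  plus1 <- track[start + 1] + track[start + 2] + track[start + 3]
  minus1 <- track[start - 2] + track[start - 1] + track[start]
  if (minus1 > 0) {
    if (!(plus1 / minus1 > 4)) return(FALSE)
  } else {
    if (!(plus1 > 4)) return(FALSE)
  }
  if (!(plus1 + minus1 > 14)) return(FALSE)
  body <- track[(start + 1):(stop + 3)]
  if (sum(body) == 0) return(FALSE)
  frame_frac <- sum(body[seq(1, length(body), by = 3)]) / sum(body)
  if (!(frame_frac > 0.5)) return(FALSE)
  per_codon <- numeric(n_codons)
  for (k in seq_len(n_codons)) {
    per_codon[k] <- sum(body[(3 * k - 2):(3 * k)])
  }
  f0 <- (frame_frac - 1 / 3) / (2 / 3)
  f0 <- min(max(f0, 0), 1)
  pr <- per_codon[per_codon > 0] / sum(per_codon)
  pme <- -sum(pr * log(pr)) / log(n_codons)
  sqrt(f0 * pme) > 0.5
}

# the cascade oracle over a whole transcript set: returns the set of
# translated uorf ids
oracle_translated_set <- function(models, tracks) {
  out <- character(0)
  for (i in seq_len(nrow(models))) {
    tid <- models$transcript_id[i]
    track <- tracks[[tid]]
    if (is.null(track)) next
    cands <- oracle_scan_uorfs(models$sequence[i], models$utr5_len[i])
    for (j in seq_len(nrow(cands))) {
      if (oracle_translated(track, cands$start[j], cands$stop[j],
                            cands$n_codons[j])) {
        out <- c(out, sprintf("%s:%d:%s", tid, cands$start[j],
                              cands$start_codon[j]))
      }
    }
  }
  out
}
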