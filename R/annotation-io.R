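#' Construct a table of transcript models
#'
#' A transcript model records the architecture of one mRNA in transcript
#' coordinates: 5'UTR, CDS (including the stop codon) and 3'UTR lengths, plus
#' an optional nucleotide sequence. Position 0 is the 5' cap; the CDS occupies
#' the 0-based half-open interval `[utr5_len, utr5_len + cds_len)`.
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param utr5_len,cds_len,utr3_len non-negative integer region lengths in
#'   nucleotides; `cds_len` includes the stop codon, must be >= 6 and a
#'   multiple of 3.
#' @param sequence optional character vector of nucleotide sequences over
#'   A/C/G/T (U is accepted and canonicalized to T); length must equal
#'   `utr5_len + cds_len + utr3_len`. `NA` if unknown.
#' @param gene_id gene identifiers; defaults to `transcript_id`.
#' @return a `tbl_df` with class `transcript_models`.
#' @export
transcript_models <- function(transcript_id, utr5_len, cds_len, utr3_len,
                              sequence = NA_character_,
                              gene_id = transcript_id) {
  models <- tibble::tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    sequence = canonicalize_seq(sequence)
  )
  class(models) <- c("transcript_models", class(models))
  validate_transcript_models(models)
  models
}

canonicalize_seq <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x), NA_character_, toupper(chartr("Uu", "Tt", x)))
}

#' Validate a transcript-model table
#'
#' Checks the invariants every downstream module relies on: unique ids,
#' `cds_len >= 6` and divisible by 3, non-negative UTR lengths, and sequence
#' length equal to the summed region lengths where a sequence is present.
#'
#' @param models a `transcript_models` table.
#' @return `models`, invisibly, or an error naming the offending transcripts.
#' @export
validate_transcript_models <- function(models) {
  stopifnot(is.data.frame(models))
  need <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")
  missing_cols <- setdiff(need, names(models))
  if (length(missing_cols)) {
    stop("transcript models lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(models$transcript_id)) {
    dup <- unique(models$transcript_id[duplicated(models$transcript_id)])
    stop("duplicate transcript_id: ", paste(dup, collapse = ", "))
  }
  bad_cds <- models$cds_len < 6L | models$cds_len %% 3L != 0L
  if (any(bad_cds)) {
    stop("CDS length must be >= 6 and divisible by 3 for: ",
         paste(models$transcript_id[bad_cds], collapse = ", "))
  }
  if (any(models$utr5_len < 0L) || any(models$utr3_len < 0L)) {
    stop("negative UTR length")
  }
  if ("sequence" %in% names(models)) {
    has_seq <- !is.na(models$sequence)
    exp_len <- models$utr5_len + models$cds_len + models$utr3_len
    bad_seq <- has_seq & nchar(models$sequence) != exp_len
    if (any(bad_seq)) {
      stop("sequence length != utr5+cds+utr3 for: ",
           paste(models$transcript_id[bad_seq], collapse = ", "))
    }
  }
  invisible(models)
}

#' Transcript length in nucleotides
#' @param models a `transcript_models` table.
#' @return integer vector `utr5_len + cds_len + utr3_len`.
#' @export
tx_length <- function(models) {
  as.integer(models$utr5_len + models$cds_len + models$utr3_len)
}

#' Stop-codon position accessors
#'
#' All positional modules locate the stop codon through these accessors, which
#' encode the coordinate law: in 0-based transcript coordinates the stop
#' codon's first nucleotide is `utr5_len + cds_len - 3` and its last is
#' `utr5_len + cds_len - 1`.
#'
#' @param models a `transcript_models` table.
#' @return 0-based integer positions.
#' @export
stop_codon_first <- function(models) {
  as.integer(models$utr5_len + models$cds_len - 3L)
}

#' @rdname stop_codon_first
#' @export
stop_codon_last <- function(models) {
  as.integer(models$utr5_len + models$cds_len - 1L)
}

#' 0-based CDS interval accessors
#' @param models a `transcript_models` table.
#' @return integer vector: `cds_first` is the first CDS position
#'   (`utr5_len`), `cds_last` the last (stop codon's final nucleotide).
#' @export
cds_first <- function(models) as.integer(models$utr5_len)

#' @rdname cds_first
#' @export
cds_last <- function(models) stop_codon_last(models)

#' Read transcript annotation (GFF3 or BED12)
#'
#' Reads single-CDS transcript models from GFF3 (1-based inclusive) or BED12
#' (0-based half-open) and converts them to transcript coordinates, resolving
#' strand so that position 0 is the 5' cap. Exons must be contiguous (this
#' package analyses transcript-space annotation; genome-to-transcript splice
#' projection is out of scope) and each transcript must carry exactly one CDS
#' block.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return a `transcript_models` table (no sequences; attach via
#'   [read_transcript_fasta()]).
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gff3") read_annotation_gff3(path) else read_annotation_bed12(path)
}

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  type <- as.character(gr$type)
  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript records in ", path)
  tid <- as.character(mrna$ID)
  if (anyNA(tid)) stop("mRNA record without ID attribute in ", path)
  parent_of <- function(sub) {
    p <- sub$Parent
    if (any(lengths(p) != 1L)) stop("exon/CDS record without a single Parent in ", path)
    as.character(unlist(p))
  }
  exons <- gr[type == "exon"]
  cdss <- gr[type == "CDS"]
  exon_parent <- parent_of(exons)
  cds_parent <- parent_of(cdss)

  out <- lapply(seq_along(mrna), function(i) {
    id <- tid[i]
    ex <- exons[exon_parent == id]
    if (length(ex) == 0L) ex <- mrna[i]  # exonless dialect: mRNA span is the exon
    cd <- cdss[cds_parent == id]
    if (length(cd) != 1L) {
      stop("transcript ", id, " must have exactly one CDS block, found ", length(cd))
    }
    ex_r <- IRanges::reduce(GenomicRanges::ranges(ex))
    if (length(ex_r) != 1L) stop("non-contiguous exons for transcript ", id)
    strand <- as.character(GenomicRanges::strand(mrna[i]))
    if (!strand %in% c("+", "-")) stop("transcript ", id, " has unresolved strand")
    tx_start <- IRanges::start(ex_r); tx_end <- IRanges::end(ex_r)
    cd_start <- GenomicRanges::start(cd); cd_end <- GenomicRanges::end(cd)
    if (cd_start < tx_start || cd_end > tx_end) {
      stop("CDS outside transcript span for ", id)
    }
    cds_len <- cd_end - cd_start + 1L
    utr5 <- if (strand == "+") cd_start - tx_start else tx_end - cd_end
    utr3 <- (tx_end - tx_start + 1L) - utr5 - cds_len
    gene <- if (length(mrna[i]$Parent[[1]])) as.character(mrna[i]$Parent[[1]]) else id
    list(transcript_id = id, gene_id = gene,
         utr5_len = utr5, cds_len = cds_len, utr3_len = utr3)
  })
  transcript_models(
    transcript_id = vapply(out, `[[`, "", "transcript_id"),
    gene_id = vapply(out, `[[`, "", "gene_id"),
    utr5_len = vapply(out, `[[`, 0L, "utr5_len"),
    cds_len = vapply(out, `[[`, 0L, "cds_len"),
    utr3_len = vapply(out, `[[`, 0L, "utr3_len")
  )
}

read_annotation_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("malformed BED12 in ", path, ": ", conditionMessage(e))
  )
  if (is.null(gr$thick)) stop("BED file lacks thickStart/thickEnd (need BED12): ", path)
  n_blocks <- if (is.null(gr$blocks)) rep(1L, length(gr)) else lengths(gr$blocks)
  if (any(n_blocks != 1L)) {
    stop("multi-block BED12 transcripts unsupported (splice projection out of scope): ",
         paste(gr$name[n_blocks != 1L], collapse = ", "))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("BED12 record with unresolved strand in ", path)
  tx_start <- GenomicRanges::start(gr); tx_end <- GenomicRanges::end(gr)
  th_start <- IRanges::start(gr$thick); th_end <- IRanges::end(gr$thick)
  cds_len <- th_end - th_start + 1L
  utr5 <- ifelse(strand == "+", th_start - tx_start, tx_end - th_end)
  utr3 <- (tx_end - tx_start + 1L) - utr5 - cds_len
  transcript_models(
    transcript_id = as.character(gr$name),
    utr5_len = utr5, cds_len = cds_len, utr3_len = utr3
  )
}

#' Write transcript annotation (GFF3 or BED12)
#'
#' Emits each transcript as its own reference sequence spanning
#' `1..tx_length` on the + strand, with one exon and one CDS block. Output is
#' byte-stable: identical inputs produce identical files.
#'
#' @param models a `transcript_models` table.
#' @param path output path.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  validate_transcript_models(models)
  len <- tx_length(models)
  if (dialect == "gff3") {
    cds_from <- models$utr5_len + 1L          # 1-based inclusive
    cds_to <- models$utr5_len + models$cds_len
    lines <- c("##gff-version 3", unlist(lapply(seq_len(nrow(models)), function(i) {
      id <- models$transcript_id[i]
      c(
        sprintf("%s\triboflux\tgene\t1\t%d\t.\t+\t.\tID=%s", id, len[i], models$gene_id[i]),
        sprintf("%s\triboflux\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s",
                id, len[i], id, models$gene_id[i]),
        sprintf("%s\triboflux\texon\t1\t%d\t.\t+\t.\tParent=%s", id, len[i], id),
        sprintf("%s\triboflux\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s",
                id, cds_from[i], cds_to[i], id, id)
      )
    })))
  } else {
    thick_start <- models$utr5_len            # 0-based half-open
    thick_end <- models$utr5_len + models$cds_len
    lines <- sprintf("%s\t0\t%d\t%s\t0\t+\t%d\t%d\t0\t1\t%d,\t0,",
                     models$transcript_id, len, models$transcript_id,
                     thick_start, thick_end, len)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write transcript sequences as FASTA
#'
#' FASTA records are matched to transcripts by name; U is canonicalized to T.
#'
#' @param models a `transcript_models` table.
#' @param path FASTA path.
#' @return for the reader, `models` with the `sequence` column filled for
#'   every transcript present in the file; for the writer, `path` invisibly.
#' @export
read_transcript_fasta <- function(models, path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  hit <- match(models$transcript_id, nm)
  seq_chr <- canonicalize_seq(ifelse(is.na(hit), NA_character_,
                                     as.character(seqs)[hit]))
  models$sequence <- seq_chr
  validate_transcript_models(models)
  models
}

#' @rdname read_transcript_fasta
#' @export
write_transcript_fasta <- function(models, path) {
  validate_transcript_models(models)
  has <- !is.na(models$sequence)
  if (!any(has)) stop("no sequences to write")
  set <- Biostrings::DNAStringSet(models$sequence[has])
  names(set) <- models$transcript_id[has]
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
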