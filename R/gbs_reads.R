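#' Read and validate a barcode table
#'
#' @param x path to a TSV with columns `sample`, `barcode`, `population`, or
#'   a data.frame with those columns.
#' @return the validated data.frame.
#' @export
read_barcode_table <- function(x) {
  bc <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x)
  need <- c("sample", "barcode", "population")
  if (!all(need %in% names(bc)))
    stop_data("barcode table needs columns %s", paste(need, collapse = ", "))
  bc$barcode <- toupper(bc$barcode)
  if (anyDuplicated(bc$barcode)) stop_data("barcodes must be unique")
  if (anyDuplicated(bc$sample)) stop_data("sample ids must be unique")
  ln <- nchar(bc$barcode)
  if (any(ln < 5 | ln > 10))
    stop_data("barcode lengths must be within 5-10 bp")
  if (any(grepl("[^ACGT]", bc$barcode)))
    stop_data("barcodes must use the A/C/G/T alphabet")
  bc
}

## Read a FASTQ file (plain or gzipped) into a character vector of sequences.
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

## Hamming distances between every read prefix and one barcode; Inf for
## reads shorter than the barcode.
prefix_mismatches <- function(reads, barcode) {
  L <- nchar(barcode)
  mm <- rep(0, length(reads))
  short <- nchar(reads) < L
  bc <- strsplit(barcode, "", fixed = TRUE)[[1]]
  for (p in seq_len(L)) {
    mm <- mm + (substr(reads, p, p) != bc[p])
  }
  mm[short] <- Inf
  mm
}

#' Demultiplex reads by barcode prefix
#'
#' A read is assigned to the sample whose barcode matches the read prefix
#' (of that barcode's length) with at most `max_mismatch` substitutions. If
#' two or more barcodes tie at the minimal distance -- including barcodes of
#' different lengths -- the read is left unassigned rather than arbitrarily
#' inflating one sample. The winning barcode prefix is removed from the
#' read.
#'
#' @param reads FASTQ path or character vector of read sequences.
#' @param barcodes a barcode table, see [read_barcode_table()].
#' @param max_mismatch maximum barcode mismatches (default 1).
#' @return a list of class `demux_result` with `reads` (named list of
#'   barcode-stripped read vectors per sample), `unassigned` (unstripped),
#'   and a `tally` data.frame. Assigned + unassigned always equals the
#'   input read count.
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 1) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq_seqs(reads)
  bc <- read_barcode_table(barcodes)
  n <- length(reads)
  nb <- nrow(bc)
  if (n == 0 || nb == 0) {
    res <- list(reads = setNames(rep(list(character(0)), nb), bc$sample),
                unassigned = reads,
                tally = data.frame(n_input = n, n_assigned = 0L,
                                   n_unassigned = n))
    class(res) <- "demux_result"
    return(res)
  }
  mm <- matrix(Inf, n, nb)
  for (j in seq_len(nb)) mm[, j] <- prefix_mismatches(reads, bc$barcode[j])
  best <- do.call(pmin, as.data.frame(mm))
  n_at_best <- rowSums(mm == best)
  assigned <- is.finite(best) & best <= max_mismatch & n_at_best == 1
  winner <- max.col(-mm, ties.method = "first")

  out <- setNames(vector("list", nb), bc$sample)
  for (j in seq_len(nb)) {
    sel <- assigned & winner == j
    out[[j]] <- substring(reads[sel], nchar(bc$barcode[j]) + 1L)
  }
  res <- list(
    reads = out,
    unassigned = reads[!assigned],
    tally = data.frame(n_input = n, n_assigned = sum(assigned),
                       n_unassigned = sum(!assigned))
  )
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d reads, %d assigned to %d samples, %d unassigned\n",
              x$tally$n_input, x$tally$n_assigned, length(x$reads),
              x$tally$n_unassigned))
  invisible(x)
}

#' Trim reads to the tag length
#'
#' Reads longer than `target_length` are truncated from the 3' end; shorter
#' reads are discarded (tags must be exactly collapsible, so padding is not
#' an option) and tallied.
#'
#' @param reads character vector of read sequences.
#' @param target_length tag length (default 100).
#' @return list with `reads` (trimmed) and `n_discarded`.
#' @export
trim_reads <- function(reads, target_length = 100) {
  keep <- nchar(reads) >= target_length
  list(reads = substr(reads[keep], 1L, target_length),
       n_discarded = sum(!keep))
}

#' Collapse trimmed per-sample reads into a tag count table
#'
#' Identical sequences are collapsed into unique tags; per-individual counts
#' are retained and per-population counts are available through
#' [population_counts()]. Tag ids are assigned in sequence order, so the
#' result is invariant to read order.
#'
#' @param sample_reads named list (sample id -> character vector of trimmed
#'   reads).
#' @param barcodes barcode table mapping samples to populations.
#' @return a [tag_count_table()].
#' @export
count_tags <- function(sample_reads, barcodes) {
  bc <- read_barcode_table(barcodes)
  unknown <- setdiff(names(sample_reads), bc$sample)
  if (length(unknown))
    stop_data("samples absent from the barcode table: %s",
              paste(head(unknown, 3), collapse = ", "))
  lens <- lengths(sample_reads)
  dt <- data.table::data.table(
    sample = rep(names(sample_reads), lens),
    seq = unlist(sample_reads, use.names = FALSE)
  )
  if (nrow(dt)) {
    dt <- dt[, .(count = .N), by = .(sample, seq)]
    tags <- data.table::data.table(seq = sort(unique(dt$seq)))
  } else {
    dt <- data.table::data.table(sample = character(), seq = character(),
                                 count = integer())
    tags <- data.table::data.table(seq = character())
  }
  tags[, tag_id := sprintf("T%07d", seq_len(.N))]
  counts <- merge(dt, tags, by = "seq", sort = FALSE)[, .(tag_id, sample, count)]
  data.table::setorder(counts, tag_id, sample)
  tag_count_table(tags = tags[, .(tag_id, seq)], counts = counts,
                  samples = bc[, c("sample", "population")])
}

#' Back-transform unique tags to FASTQ
#'
#' One record per unique tag; the identifier encodes the tag id and its
#' total count, and the quality string is a dummy maximal quality (the
#' downstream aligner does not use it).
#'
#' @param x a [tag_count_table()].
#' @param path optional output FASTQ path; when `NULL` the records are
#'   returned invisibly as a named character vector (id -> sequence).
#' @return invisibly, the named sequence vector.
#' @export
tags_to_fastq <- function(x, path = NULL) {
  stopifnot(inherits(x, "tag_count_table"))
  totals <- x$counts[, .(total = sum(count)), by = tag_id]
  tot <- setNames(rep(0L, nrow(x$tags)), x$tags$tag_id)
  tot[totals$tag_id] <- totals$total
  ids <- sprintf("%s count=%d", x$tags$tag_id, tot)
  seqs <- setNames(x$tags$seq, ids)
  if (!is.null(path)) {
    ss <- Biostrings::DNAStringSet(seqs)
    qual <- Biostrings::BStringSet(strrep("I", nchar(x$tags$seq)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  }
  invisible(seqs)
}
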