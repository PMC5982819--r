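## Minimal SAM text I/O for unique-tag alignments. Only the standard
## columns QNAME/FLAG/RNAME/POS/SEQ are used; SEQ is stored
## reference-forward per the SAM specification (bit 0x10 set means the
## original read is the reverse complement of the stored sequence).

#' Read unique-tag alignments from a SAM file
#'
#' Parses the mandatory SAM columns and returns one row per mapped record.
#' Unmapped records (FLAG bit 0x4 or RNAME "*") are dropped. Sequences are
#' returned in the original read orientation (reverse-complemented back when
#' FLAG bit 0x10 is set), so they are directly comparable with tag
#' sequences.
#'
#' @param path SAM file path.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`, `seq`.
#' @export
read_sam_tags <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop_data("malformed SAM record at line %d (%d fields)",
              which(nf < 11)[1], min(nf))
  m <- matrix(unlist(lapply(f, `[`, 1:11)), ncol = 11, byrow = TRUE)
  out <- data.frame(
    qname = m[, 1], flag = as.integer(m[, 2]), rname = m[, 3],
    pos = as.integer(m[, 4]), seq = m[, 10], stringsAsFactors = FALSE
  )
  mapped <- bitwAnd(out$flag, 4L) == 0L & out$rname != "*"
  out <- out[mapped, , drop = FALSE]
  rev <- bitwAnd(out$flag, 16L) == 16L
  if (any(rev)) out$seq[rev] <- revcomp(out$seq[rev])
  rownames(out) <- NULL
  out
}

#' Write unique-tag alignments as a SAM file
#'
#' Emits a headerful SAM (@HD and one @SQ per scaffold) with one record per
#' aligned tag: 1-based POS, FLAG 0 or 16 (strand), CIGAR of full-length
#' matches, and the tag sequence stored reference-forward.
#'
#' @param x a [tag_count_table()] whose tags carry `flag`, `scaffold`, `pos`.
#' @param path output path.
#' @param ref_length scaffold length to declare in the header.
#' @return invisibly, the path.
#' @export
write_sam_tags <- function(x, path, ref_length = 1000000L) {
  stopifnot(inherits(x, "tag_count_table"))
  tg <- x$tags
  if (!all(c("flag", "scaffold", "pos") %in% names(tg)))
    stop_data("tag table carries no alignment keys")
  tg <- tg[!is.na(tg$scaffold), ]
  scafs <- unique(tg$scaffold)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", scafs, ref_length))
  seq_out <- tg$seq
  rev <- bitwAnd(tg$flag, 16L) == 16L
  if (any(rev)) seq_out[rev] <- revcomp(seq_out[rev])
  rec <- sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s",
                 tg$tag_id, tg$flag, tg$scaffold, tg$pos,
                 nchar(tg$seq), seq_out, strrep("I", nchar(tg$seq)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Generate a barcode table for a set of samples
#'
#' Random 5-10 bp barcodes with pairwise guarantees that keep single-error
#' demultiplexing unambiguous: no barcode is within two substitutions of
#' another barcode's prefix of its own length.
#'
#' @param samples data.frame with columns `sample`, `population`.
#' @param lengths candidate barcode lengths.
#' @param seed integer seed.
#' @return a barcode table (`sample`, `barcode`, `population`).
#' @export
generate_barcodes <- function(samples, lengths = 5:10, seed = 1L) {
  set.seed(seed)
  n <- nrow(samples)
  chosen <- character(0)
  conflicts <- function(b, existing) {
    if (!length(existing)) return(FALSE)
    any(vapply(existing, function(e) {
      L <- min(nchar(e), nchar(b))
      sum(strsplit(substr(e, 1, L), "")[[1]] !=
            strsplit(substr(b, 1, L), "")[[1]]) < 3
    }, logical(1)))
  }
  while (length(chosen) < n) {
    b <- random_dna(sample(lengths, 1))
    if (!conflicts(b, chosen)) chosen <- c(chosen, b)
  }
  data.frame(sample = samples$sample, barcode = chosen,
             population = samples$population, stringsAsFactors = FALSE)
}

#' Write a multiplexed FASTQ run from a tag count table
#'
#' Expands counts into individual reads, prepends each sample's barcode and
#' pads reads with random bases up to `read_length` (emulating the raw
#' sequencer output from which barcodes are stripped and tags trimmed).
#'
#' @param x a [tag_count_table()].
#' @param barcodes barcode table covering all samples in `x`.
#' @param path output FASTQ path.
#' @param read_length total raw read length (default 126).
#' @param seed seed for the padding bases.
#' @return invisibly, the number of reads written.
#' @export
write_run_fastq <- function(x, barcodes, path, read_length = 126L,
                            seed = 1L) {
  stopifnot(inherits(x, "tag_count_table"))
  set.seed(seed)
  bc <- read_barcode_table(barcodes)
  cnt <- merge(x$counts, x$tags[, c("tag_id", "seq")], by = "tag_id")
  reads_sample <- rep(cnt$sample, cnt$count)
  reads_seq <- rep(cnt$seq, cnt$count)
  bcs <- bc$barcode[match(reads_sample, bc$sample)]
  if (anyNA(bcs)) stop_data("samples missing from the barcode table")
  full <- paste0(bcs, reads_seq)
  pad <- read_length - nchar(full)
  if (any(pad < 0)) stop_data("read_length shorter than barcode + tag")
  pad_chars <- vapply(pad, function(p)
    if (p > 0) random_dna(p) else "", character(1))
  full <- paste0(full, pad_chars)
  ss <- Biostrings::DNAStringSet(full)
  names(ss) <- sprintf("read%d", seq_along(full))
  qual <- Biostrings::BStringSet(strrep("I", nchar(full)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(length(full))
}
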