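## GBS read-depth and sequencing-error simulation on top of a truth set.

## Draw per-cell read depth under the configured model.
draw_depth <- function(n, dm) {
  if (isTRUE(dm$fixed)) return(rep(as.integer(round(dm$mean)), n))
  disp <- dm$dispersion %||% Inf
  if (is.infinite(disp)) stats::rpois(n, dm$mean)
  else rnbinom(n, mu = dm$mean, size = disp)
}

## Mutate one uniformly chosen position of each read to a different base;
## fully vectorised. Returns the mutated sequences.
mutate_once <- function(seqs, tag_len) {
  n <- length(seqs)
  p <- sample.int(tag_len, n, replace = TRUE)
  old <- substr(seqs, p, p)
  shift <- sample.int(3L, n, replace = TRUE)
  new <- DNA_BASES[((match(old, DNA_BASES) - 1L + shift) %% 4L) + 1L]
  substr(seqs, p, p) <- new
  seqs
}

#' Simulate a tag count table from planted diplotypes
#'
#' Per individual and locus, a total read depth is drawn from the configured
#' depth model and split binomially between the individual's two haplotypes
#' (all reads fall on the single haplotype of a homozygote). Each read then
#' acquires substitution errors independently per base at `seq_error_rate`;
#' reads with at least one error become distinct, typically singleton, tag
#' sequences. Every tag, including error-derived ones, carries the true
#' alignment key (strand flag, scaffold, 1-based position) of its locus.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the [sim_config()] used to build `truth`.
#' @param samples individuals to sequence (default: all offspring).
#' @return a [tag_count_table()] whose `tags` table carries `locus`, `flag`,
#'   `scaffold`, `pos` and `is_error` columns.
#' @export
simulate_tag_counts <- function(truth, config = truth$config,
                                samples = truth$offspring$ids) {
  set.seed(substream(config$seed, 3L))
  idx <- match(samples, truth$offspring$ids)
  if (anyNA(idx)) stop_data("unknown samples requested")
  n <- length(idx)
  L <- config$n_tag_loci
  tag_len <- config$tag_length
  if (n == 0 || L == 0) {
    return(tag_count_table(
      tags = data.frame(tag_id = character(), seq = character(),
                        locus = character(), flag = integer(),
                        scaffold = character(), pos = integer(),
                        is_error = logical()),
      counts = data.frame(tag_id = character(), sample = character(),
                          count = integer()),
      samples = truth$offspring$membership[
        truth$offspring$membership$sample %in% samples, , drop = FALSE]))
  }

  h1 <- truth$offspring$h1[idx, , drop = FALSE]
  h2 <- truth$offspring$h2[idx, , drop = FALSE]
  depth <- draw_depth(n * L, config$depth_model)
  het <- as.vector(h1 != h2)
  c1 <- depth
  c1[het] <- rbinom(sum(het), depth[het], 0.5)
  c2 <- depth - c1
  c2[!het] <- 0L

  cell_sample <- rep(samples, times = L)
  cell_locus <- rep(seq_len(L), each = n)
  rows <- function(cnt, hap) {
    keep <- cnt > 0
    data.table::data.table(sample = cell_sample[keep],
                           locus_idx = cell_locus[keep],
                           allele = as.vector(hap)[keep],
                           count = as.integer(cnt[keep]))
  }
  dt <- rbind(rows(c1, h1), rows(c2, h2))

  ## per-allele tag sequence lookup ((locus, allele) -> tag sequence)
  lens <- lengths(truth$loci$allele_seqs)
  lut_key <- rep(seq_len(L), lens) * 8L + sequence(lens)
  lut_seq <- unlist(truth$loci$allele_seqs, use.names = FALSE)
  seq_of <- function(locus_idx, allele) {
    lut_seq[match(locus_idx * 8L + allele, lut_key)]
  }
  ## sequencing error: peel error-bearing reads off their source tags
  err_dt <- NULL
  e <- config$seq_error_rate
  if (e > 0 && nrow(dt)) {
    p_read <- 1 - (1 - e)^tag_len
    n_err <- rbinom(nrow(dt), dt$count, p_read)
    dt[, count := count - n_err]
    src <- rep(seq_len(nrow(dt)), n_err)
    if (length(src)) {
      seqs <- seq_of(dt$locus_idx[src], dt$allele[src])
      ## number of errored bases per read, conditional on >= 1
      p0 <- stats::dbinom(0, tag_len, e)
      u <- runif(length(src), p0, 1)
      n_mut <- stats::qbinom(u, tag_len, e)
      for (t in seq_len(max(n_mut))) {
        hit <- n_mut >= t
        seqs[hit] <- mutate_once(seqs[hit], tag_len)
      }
      err_dt <- data.table::data.table(
        sample = dt$sample[src], locus_idx = dt$locus_idx[src],
        seq = seqs, count = 1L)
      err_dt <- err_dt[, .(count = sum(count)), by = .(sample, locus_idx, seq)]
    }
    dt <- dt[count > 0]
  }

  dt[, seq := seq_of(locus_idx, allele)]
  all_counts <- rbind(dt[, .(sample, locus_idx, seq, count)], err_dt)
  all_counts <- all_counts[, .(count = sum(count)),
                           by = .(sample, locus_idx, seq)]

  tags <- unique(all_counts[, .(locus_idx, seq)])
  data.table::setorder(tags, locus_idx, seq)
  tags[, tag_id := sprintf("T%07d", .I)]
  tags[, locus := truth$loci$locus[locus_idx]]
  tags[, flag := truth$loci$flag[locus_idx]]
  tags[, scaffold := truth$loci$scaffold[locus_idx]]
  tags[, pos := truth$loci$pos[locus_idx]]
  true_keys <- paste(rep(seq_len(L), lens), lut_seq)
  tags[, is_error := !(paste(locus_idx, seq) %in% true_keys)]

  counts <- merge(all_counts, tags[, .(locus_idx, seq, tag_id)],
                  by = c("locus_idx", "seq"), sort = FALSE)
  counts <- counts[, .(tag_id, sample, count)]
  data.table::setorder(counts, tag_id, sample)

  mem <- truth$offspring$membership
  tag_count_table(
    tags = tags[, .(tag_id, seq, locus, flag, scaffold, pos, is_error)],
    counts = counts,
    samples = mem[mem$sample %in% samples, , drop = FALSE])
}
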