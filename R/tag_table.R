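#' Tag count table
#'
#' The central container of the read-processing stages: unique 100 bp tag
#' sequences together with per-individual read counts and the mapping from
#' individuals to their pair-cross populations. Per-population counts (the
#' level at which the discovery filters operate) are derived sums, see
#' [population_counts()].
#'
#' @param tags data.frame with columns `tag_id`, `seq`, and optionally the
#'   alignment key columns `flag`, `scaffold`, `pos` (plus `locus`,
#'   `is_error` when simulated).
#' @param counts data.frame with columns `tag_id`, `sample`, `count`.
#' @param samples data.frame with columns `sample`, `population`.
#' @return an object of class `tag_count_table`.
#' @export
tag_count_table <- function(tags, counts, samples) {
  tags <- data.table::as.data.table(tags)
  counts <- data.table::as.data.table(counts)
  samples <- as.data.frame(samples)
  if (!all(c("tag_id", "seq") %in% names(tags)))
    stop_data("tags must have columns tag_id, seq")
  if (!all(c("tag_id", "sample", "count") %in% names(counts)))
    stop_data("counts must have columns tag_id, sample, count")
  if (!all(c("sample", "population") %in% names(samples)))
    stop_data("samples must have columns sample, population")
  if (anyDuplicated(tags$tag_id)) stop_data("duplicated tag ids")
  if (any(counts$count < 0)) stop_data("negative tag counts")
  if (nrow(tags) && length(unique(nchar(tags$seq))) > 1)
    stop_data("all tag sequences must have the same length")
  unknown <- setdiff(unique(counts$sample), samples$sample)
  if (length(unknown))
    stop_data("counts reference samples absent from the sample table: %s",
              paste(head(unknown, 3), collapse = ", "))
  structure(list(tags = tags, counts = counts, samples = samples),
            class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat(sprintf(
    "tag_count_table: %d tags x %d samples (%d populations), %s reads\n",
    nrow(x$tags), nrow(x$samples), length(unique(x$samples$population)),
    format(sum(x$counts$count), big.mark = ",")))
  invisible(x)
}

#' Per-population tag counts
#'
#' Sums the per-individual counts over the members of each pair-cross
#' population.
#'
#' @param x a [tag_count_table()].
#' @return a data.table with columns `tag_id`, `population`, `count`.
#' @export
population_counts <- function(x) {
  stopifnot(inherits(x, "tag_count_table"))
  dt <- data.table::as.data.table(x$counts)
  dt[, population := x$samples$population[match(sample, x$samples$sample)]]
  dt[, .(count = sum(count)), by = .(tag_id, population)]
}

#' Total read count in a tag count table
#' @param x a [tag_count_table()].
#' @return total number of reads represented.
#' @export
total_reads <- function(x) sum(x$counts$count)
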