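## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' A single global seed drives the whole simulator; each stage (founders,
#' crosses, read depth, traits, ...) draws from its own derived substream so
#' that rerunning one stage does not perturb the others. The derivation is a
#' fixed affine map modulo the largest 32-bit prime, so any integer global
#' seed yields valid per-stage seeds.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset (>= 0).
#' @return an integer seed suitable for [set.seed()].
#' @keywords internal
substream <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stage) * 16807
  as.integer(s %% 2147483629)
}

## Random DNA sequence of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Canonical unordered genotype label: lexicographically sorted haplotypes
## joined by "/" (DNA alphabet is uppercase ASCII, so ordering is
## locale-independent). Vectorised over equal-length character vectors.
genotype_label <- function(h1, h2) {
  first <- ifelse(h1 <= h2, h1, h2)
  second <- ifelse(h1 <= h2, h2, h1)
  paste(first, second, sep = "/")
}

## Upos key string from its components
upos_key <- function(flag, scaffold, pos) {
  paste(flag, scaffold, pos, sep = ":")
}

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

is_prob <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
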