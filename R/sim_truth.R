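## Simulation of founder diplotypes, pair-cross offspring and the truth set.

## Build haplotype strings for k alleles over s polymorphic sites: every site
## carries at least two distinct bases across alleles (so it really is an
## Isite) and all allele haplotypes are pairwise distinct.
make_allele_haps <- function(k, s) {
  stopifnot(k >= 2, s >= 1, k <= 4)
  repeat {
    m <- matrix("", nrow = s, ncol = k)
    for (j in seq_len(s)) {
      repeat {
        l <- sample(DNA_BASES, k, replace = TRUE)
        if (length(unique(l)) >= 2) break
      }
      m[j, ] <- l
    }
    haps <- apply(m, 2, paste, collapse = "")
    if (!anyDuplicated(haps)) return(haps)
  }
}

## Substitute haplotype bases into a base tag sequence at the given
## 0-based offsets.
apply_hap <- function(base_seq, offsets0, hap) {
  chars <- strsplit(base_seq, "", fixed = TRUE)[[1]]
  chars[offsets0 + 1L] <- strsplit(hap, "", fixed = TRUE)[[1]]
  paste(chars, collapse = "")
}

## Assign founder allele pairs at one locus so that (a) each founder is
## heterozygous with probability het_p (when k >= 2) and (b) the union of
## founder alleles covers all k alleles.
assign_founder_alleles <- function(k, n_f, het_p) {
  if (k == 1) return(list(h1 = rep(1L, n_f), h2 = rep(1L, n_f)))
  het <- runif(n_f) < het_p
  h1 <- integer(n_f); h2 <- integer(n_f)
  for (f in seq_len(n_f)) {
    if (het[f]) {
      ab <- sample.int(k, 2)
      h1[f] <- ab[1]; h2[f] <- ab[2]
    } else {
      h1[f] <- h2[f] <- sample.int(k, 1)
    }
  }
  ## fix-up pass: plant any allele missing from the union, preserving each
  ## founder's het/hom status; founders are revisited in random order
  for (iter in 1:100) {
    missing <- setdiff(seq_len(k), unique(c(h1, h2)))
    if (!length(missing)) break
    a <- missing[1]
    f <- sample.int(n_f, 1)
    if (het[f]) {
      if (h1[f] != a) h2[f] <- a else h2[f] <- sample(setdiff(1:k, a), 1)
    } else {
      h1[f] <- h2[f] <- a
    }
  }
  missing <- setdiff(seq_len(k), unique(c(h1, h2)))
  if (length(missing)) { # deterministic fallback for tiny founder sets
    for (i in seq_along(missing)) {
      f <- ((i - 1) %% n_f) + 1
      h1[f] <- missing[i]
      if (!het[f]) h2[f] <- missing[i]
      else if (h2[f] == missing[i]) h2[f] <- (missing[i] %% k) + 1
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate founder diplotypes at unlinked 100 bp tag loci
#'
#' Draws, per locus, the number of segregating tag alleles (1..4), the number
#' of polymorphic sites (Isites) within the tag, the allele haplotypes and
#' full tag sequences, a unique alignment key (strand, scaffold, 1-based
#' position), and a diplotype for every founder. The union of founder alleles
#' at a locus always has the drawn cardinality.
#'
#' @param config a [sim_config()].
#' @return a list with elements `loci` (data.frame with per-locus metadata,
#'   including list-columns `isite_offsets` (0-based), `allele_seqs` and
#'   `allele_haps`) and `founders` (list of integer matrices `h1`, `h2` of
#'   dimension founders x loci holding allele indices).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(substream(config$seed, 1L))
  L <- config$n_tag_loci
  n_f <- config$n_founders
  ad <- config$alleles_per_locus_dist
  sd_ <- config$snps_per_tag_dist
  n_alleles <- if (L) sample(seq_along(ad), L, TRUE, prob = ad) else integer()
  n_isites <- integer(L)
  poly <- n_alleles >= 2
  n_isites[poly] <- sample(seq_along(sd_), sum(poly), TRUE, prob = sd_)

  ## unique alignment keys; a configurable fraction of loci shares a scaffold
  ## with another locus so scaffold-level collapsing can be exercised
  n_share <- min(round(config$scaffold_sharing * L), max(L - 1L, 0L))
  n_host <- max(L - n_share, min(L, 1L))
  scaffold_idx <- c(seq_len(n_host),
                    if (n_share) sample.int(n_host, n_share, replace = TRUE))
  scaffold_idx <- scaffold_idx[seq_len(L)]
  scaffold <- sprintf("scaffold_%d", scaffold_idx)
  pos <- integer(L)
  if (L) {
    repeat {
      pos <- sample.int(500000L, L, replace = TRUE)
      if (!anyDuplicated(paste(scaffold, pos))) break
    }
  }
  flag <- if (L) sample(c(0L, 16L), L, TRUE) else integer()

  isite_offsets <- vector("list", L)
  allele_haps <- vector("list", L)
  allele_seqs <- vector("list", L)
  base_seq <- character(L)
  for (i in seq_len(L)) {
    base_seq[i] <- random_dna(config$tag_length)
    k <- n_alleles[i]
    if (k == 1) {
      isite_offsets[[i]] <- integer(0)
      allele_haps[[i]] <- ""
      allele_seqs[[i]] <- base_seq[i]
    } else {
      s <- n_isites[i]
      off <- sort(sample.int(config$tag_length, s) - 1L)
      haps <- make_allele_haps(k, s)
      isite_offsets[[i]] <- off
      allele_haps[[i]] <- haps
      allele_seqs[[i]] <- vapply(haps, function(h)
        apply_hap(base_seq[i], off, h), character(1), USE.NAMES = FALSE)
    }
  }

  f_h1 <- matrix(1L, n_f, L)
  f_h2 <- matrix(1L, n_f, L)
  for (i in seq_len(L)) {
    ass <- assign_founder_alleles(n_alleles[i], n_f,
                                  config$founder_heterozygosity)
    f_h1[, i] <- ass$h1
    f_h2[, i] <- ass$h2
  }

  loci <- data.frame(
    locus = sprintf("L%05d", seq_len(L)),
    scaffold = scaffold, pos = pos, flag = flag,
    n_alleles = n_alleles, n_isites = n_isites,
    base_seq = base_seq, stringsAsFactors = FALSE
  )
  loci$isite_offsets <- isite_offsets
  loci$allele_haps <- allele_haps
  loci$allele_seqs <- allele_seqs
  rownames(f_h1) <- rownames(f_h2) <- sprintf("F%d", seq_len(n_f))
  list(loci = loci, founders = list(h1 = f_h1, h2 = f_h2))
}

#' Simulate one pair-cross
#'
#' Each offspring receives, independently at every locus, one uniformly
#' chosen haplotype from each parent (Mendelian transmission of unlinked
#' loci; no recombination model is needed because tags are treated as
#' independent loci).
#'
#' @param parent_a,parent_b lists with integer vectors `h1`, `h2` of allele
#'   indices over the same locus set.
#' @param n_offspring number of offspring to draw.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @return list of integer matrices `h1`, `h2` (offspring x loci).
#' @export
simulate_cross <- function(parent_a, parent_b, n_offspring, seed) {
  La <- length(parent_a$h1); Lb <- length(parent_b$h1)
  if (La != Lb || length(parent_a$h2) != La || length(parent_b$h2) != Lb)
    stop_data("parents are defined over different locus sets")
  set.seed(seed)
  L <- La
  pick_a <- matrix(runif(n_offspring * L) < 0.5, n_offspring, L)
  pick_b <- matrix(runif(n_offspring * L) < 0.5, n_offspring, L)
  h1 <- matrix(rep(parent_a$h1, each = n_offspring), n_offspring, L)
  h1[!pick_a] <- matrix(rep(parent_a$h2, each = n_offspring),
                        n_offspring, L)[!pick_a]
  h2 <- matrix(rep(parent_b$h1, each = n_offspring), n_offspring, L)
  h2[!pick_b] <- matrix(rep(parent_b$h2, each = n_offspring),
                        n_offspring, L)[!pick_b]
  list(h1 = h1, h2 = h2)
}

#' Simulate the full truth set for a multiparental study
#'
#' Founders are simulated with [simulate_founders()], every pair-cross in the
#' design with [simulate_cross()], and genotypes are assigned to the two
#' yearly phenotyping campaigns with the configured overlap.
#'
#' @param config a [sim_config()].
#' @return an object of class `gbs_truth`: a list with `config`, `loci`,
#'   `founders`, `offspring` (ids, `membership` data.frame, matrices `h1`,
#'   `h2`), `years` (character vectors `year1`, `year2`) and `qtl`.
#' @export
simulate_truth <- function(config) {
  fd <- simulate_founders(config)
  cr <- config$crosses
  ids <- character(0); mem <- character(0)
  h1 <- h2 <- matrix(integer(0), 0, config$n_tag_loci)
  for (i in seq_len(nrow(cr))) {
    pa <- list(h1 = fd$founders$h1[cr$mother[i], ],
               h2 = fd$founders$h2[cr$mother[i], ])
    pb <- list(h1 = fd$founders$h1[cr$father[i], ],
               h2 = fd$founders$h2[cr$father[i], ])
    off <- simulate_cross(pa, pb, cr$n_offspring[i],
                          seed = substream(config$seed, 100L + i))
    ids_i <- sprintf("%s_%03d", cr$population[i], seq_len(cr$n_offspring[i]))
    ids <- c(ids, ids_i)
    mem <- c(mem, rep(cr$population[i], cr$n_offspring[i]))
    h1 <- rbind(h1, off$h1)
    h2 <- rbind(h2, off$h2)
  }
  if (length(ids)) { rownames(h1) <- rownames(h2) <- ids }

  set.seed(substream(config$seed, 2L))
  yr <- config$years
  n_off <- length(ids)
  year1 <- if (yr$n_year1) sample(ids, yr$n_year1) else character(0)
  overlap <- if (yr$n_overlap) sample(year1, yr$n_overlap) else character(0)
  pool2 <- setdiff(ids, year1)
  extra2 <- yr$n_year2 - yr$n_overlap
  year2 <- c(overlap, if (extra2) sample(pool2, extra2) else character(0))

  qtl <- config$qtl_spec
  if (!is.null(qtl)) {
    if (is.character(qtl$locus)) {
      qtl$locus_idx <- match(qtl$locus, fd$loci$locus)
    } else {
      qtl$locus_idx <- as.integer(qtl$locus)
      qtl$locus <- fd$loci$locus[qtl$locus_idx]
    }
    if (anyNA(qtl$locus_idx) || any(qtl$locus_idx < 1) ||
        any(qtl$locus_idx > nrow(fd$loci)))
      stop_data("qtl_spec references unknown loci")
    if (any(qtl$allele > fd$loci$n_alleles[qtl$locus_idx]))
      stop_data("qtl_spec references an allele absent at its locus")
  }

  structure(list(
    config = config, loci = fd$loci, founders = fd$founders,
    offspring = list(ids = ids,
                     membership = data.frame(sample = ids,
                                             population = mem,
                                             stringsAsFactors = FALSE),
                     h1 = h1, h2 = h2),
    years = list(year1 = sort(year1), year2 = sort(year2)),
    qtl = qtl
  ), class = "gbs_truth")
}

#' @export
print.gbs_truth <- function(x, ...) {
  cat(sprintf(
    "gbs_truth: %d founders, %d offspring in %d populations, %d loci (%d polymorphic)\n",
    x$config$n_founders, length(x$offspring$ids),
    length(unique(x$offspring$membership$population)),
    nrow(x$loci), sum(x$loci$n_alleles >= 2)))
  if (!is.null(x$qtl))
    cat(sprintf("planted QTL at: %s\n", paste(x$qtl$locus, collapse = ", ")))
  invisible(x)
}

#' Genotype matrix implied by the truth set
#'
#' Converts planted diplotypes into the same label format the genotype caller
#' emits ("hap1/hap2", haplotypes sorted), restricted to polymorphic loci.
#' Useful as ground truth for caller validation and as a caller-free input to
#' the association stage.
#'
#' @param truth a `gbs_truth`.
#' @param samples which individuals to include (default all offspring).
#' @return a character matrix (individuals x loci) with a `locus_info`
#'   attribute as produced by [call_genotypes()].
#' @export
truth_genotype_matrix <- function(truth, samples = truth$offspring$ids) {
  keep <- which(truth$loci$n_alleles >= 2)
  loci <- truth$loci[keep, , drop = FALSE]
  idx <- match(samples, truth$offspring$ids)
  if (anyNA(idx)) stop_data("unknown samples requested")
  m <- matrix(NA_character_, length(samples), length(keep),
              dimnames = list(samples, loci$locus))
  for (j in seq_along(keep)) {
    haps <- loci$allele_haps[[j]]
    a1 <- haps[truth$offspring$h1[idx, keep[j]]]
    a2 <- haps[truth$offspring$h2[idx, keep[j]]]
    m[, j] <- genotype_label(a1, a2)
  }
  info <- data.frame(
    locus = loci$locus,
    upos = upos_key(loci$flag, loci$scaffold, loci$pos),
    flag = loci$flag, scaffold = loci$scaffold, pos = loci$pos,
    n_isites = loci$n_isites, stringsAsFactors = FALSE
  )
  info$isite_offsets <- loci$isite_offsets
  info$alleles <- loci$allele_haps
  attr(m, "locus_info") <- info
  m
}
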