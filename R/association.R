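#' Parameters of the nonparametric association scan
#'
#' @param maf_min minor haplotype frequency threshold applied to each Itag
#'   locus before testing (frequency of the second most common haplotype
#'   among called alleles, two per individual).
#' @param min_genotypes minimum number of non-missing genotype calls at a
#'   locus (100 for a campaign of ~313 genotypes, 50 for ~116).
#' @param n_perm number of phenotype permutations per test (default 10,000).
#' @param lod_threshold Kruskal-Wallis LOD (-log10 asymptotic p) required
#'   for significance (default 3.0).
#' @param perm_alpha permutation p-value required for significance
#'   (default 0.01); both conditions must hold.
#' @param dunn_alpha significance level of the Bonferroni corrected Dunn
#'   post hoc comparisons (default 0.05).
#' @param min_class_size genotype classes smaller than this are dropped
#'   before testing (default 2).
#' @param perm_mode `"per_locus"` (default) estimates a permutation p-value
#'   per test; `"max_T"` computes an experiment-wise null distribution of
#'   the maximum statistic across loci per trait.
#' @param seed integer seed driving all permutations.
#' @return a named list of class `gwas_params`.
#' @export
gwas_params <- function(maf_min = 0.10, min_genotypes = 100,
                        n_perm = 10000, lod_threshold = 3.0,
                        perm_alpha = 0.01, dunn_alpha = 0.05,
                        min_class_size = 2,
                        perm_mode = c("per_locus", "max_T"),
                        seed = 1L) {
  p <- list(maf_min = maf_min, min_genotypes = as.integer(min_genotypes),
            n_perm = as.integer(n_perm), lod_threshold = lod_threshold,
            perm_alpha = perm_alpha, dunn_alpha = dunn_alpha,
            min_class_size = as.integer(min_class_size),
            perm_mode = match.arg(perm_mode), seed = as.integer(seed))
  stopifnot(p$maf_min > 0, p$maf_min < 1, p$perm_alpha > 0,
            p$perm_alpha < 1, p$dunn_alpha > 0, p$dunn_alpha < 1,
            p$n_perm >= 1, p$lod_threshold > 0)
  class(p) <- "gwas_params"
  p
}

## Haplotype frequencies of one locus column ("a/b" calls, NA missing).
hap_frequencies <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(numeric(0))
  alleles <- unlist(strsplit(calls, "/", fixed = TRUE), use.names = FALSE)
  sort(table(alleles) / length(alleles), decreasing = TRUE)
}

#' Filter Itag loci for association testing
#'
#' A locus is testable when it has at least `min_genotypes` non-missing
#' calls and its minor haplotype frequency (the second most common
#' haplotype among called alleles, two per individual) is at least
#' `maf_min`.
#'
#' @param calls genotype matrix (individuals x loci) or `tag_genotypes`.
#' @param params [gwas_params()].
#' @return logical vector over loci (named by locus).
#' @export
filter_itags <- function(calls, params) {
  if (inherits(calls, "tag_genotypes")) calls <- calls$calls
  keep <- vapply(seq_len(ncol(calls)), function(j) {
    cc <- calls[, j]
    n <- sum(!is.na(cc))
    if (n < params$min_genotypes) return(FALSE)
    fr <- hap_frequencies(cc)
    length(fr) >= 2 && fr[2] >= params$maf_min
  }, logical(1))
  setNames(keep, colnames(calls))
}

#' Tie-corrected Kruskal-Wallis test with LOD
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic on midranks, the
#' asymptotic chi-square p-value with k-1 degrees of freedom, and the
#' association LOD defined as -log10(p). When every observation is tied the
#' tie correction degenerates; this is treated as no signal (H = 0, p = 1,
#' LOD = 0).
#'
#' @param values numeric trait values.
#' @param classes genotype class labels (factor or character).
#' @return list with `H`, `p`, `lod`, `k` (classes used), `n`.
#' @export
kw_test <- function(values, classes) {
  ok <- !is.na(values) & !is.na(classes)
  v <- values[ok]
  g <- factor(classes[ok])
  g <- droplevels(g)
  k <- nlevels(g)
  n <- length(v)
  if (k < 2 || n < 2)
    stop_data("kw_test needs at least two classes with observations")
  r <- rank(v)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H0 <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(v)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) return(list(H = 0, p = 1, lod = 0, k = k, n = n))
  H <- H0 / C
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  list(H = H, p = p, lod = -log10(p), k = k, n = n)
}

## Internal: H statistics for B permutations of the ranks against fixed
## class labels. Ranks and the tie correction are permutation-invariant, so
## they are computed once.
perm_H <- function(r, gi, nj, C, n_perm) {
  n <- length(r)
  const <- 12 / (n * (n + 1))
  H <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rp <- r[sample.int(n)]
    Rj <- rowsum(rp, gi) # reordered: group i in row i, aligned with nj
    H[b] <- (const * sum(Rj^2 / nj) - 3 * (n + 1)) / C
  }
  H
}

#' Permutation p-value for a Kruskal-Wallis association
#'
#' The phenotype vector is randomly permuted against the fixed genotype
#' class labels `n_perm` times; the p-value is
#' (1 + #\{H_perm >= H_obs\}) / (n_perm + 1), which can never be zero.
#'
#' @inheritParams kw_test
#' @param n_perm number of permutations.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside [run_gwas()], which seeds once globally).
#' @return list with `p_perm`, `H_obs`, `n_perm`.
#' @export
permutation_pvalue <- function(values, classes, n_perm = 10000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(values) & !is.na(classes)
  v <- values[ok]
  g <- droplevels(factor(classes[ok]))
  n <- length(v)
  r <- rank(v)
  ties <- table(v)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  obs <- kw_test(v, g)
  if (C <= 0) # all observations tied: every permutation is equivalent
    return(list(p_perm = 1, H_obs = 0, n_perm = n_perm))
  gi <- as.integer(g)
  nj <- tabulate(gi)
  Hp <- perm_H(r, gi, nj, C, n_perm)
  p <- (1 + sum(Hp >= obs$H - 1e-10)) / (n_perm + 1)
  list(p_perm = p, H_obs = obs$H, n_perm = n_perm)
}

#' Dunn's post hoc test with Bonferroni correction and letter display
#'
#' Pairwise Dunn z statistics on mean ranks with tie correction; two-sided
#' normal p-values are Bonferroni-adjusted by the number of pairwise
#' comparisons k(k-1)/2. Compact letters are assigned (insert-and-absorb)
#' so that classes sharing a letter are not significantly different at
#' `alpha`; letter `a` goes to the class with the highest median.
#'
#' @inheritParams kw_test
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return list with `pairs` (data.frame `class1`, `class2`, `z`, `p`,
#'   `p_adj`) and `letters` (named character vector, classes ordered by
#'   decreasing median).
#' @export
dunn_posthoc <- function(values, classes, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(classes)
  v <- values[ok]
  g <- droplevels(factor(classes[ok]))
  k <- nlevels(g)
  if (k < 2) stop_data("dunn_posthoc needs at least two classes")
  n <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  nj <- tabulate(g)
  ties <- table(v)
  tie_sum <- sum(ties^3 - ties)
  sigma2 <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  cmb <- combn(k, 2)
  m <- ncol(cmb)
  z <- p <- numeric(m)
  for (i in seq_len(m)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt(sigma2 * (1 / nj[a] + 1 / nj[b]))
    z[i] <- if (se > 0) (rbar[a] - rbar[b]) / se else 0
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  p_adj <- pmin(1, p * m)
  meds <- tapply(v, g, median)
  ord <- order(-meds)
  sig <- which(p_adj <= alpha)
  sig_pairs <- cbind(cmb[1, sig], cmb[2, sig])
  letters <- cld_letters(k, sig_pairs, ord)
  names(letters) <- levels(g)
  list(
    pairs = data.frame(class1 = levels(g)[cmb[1, ]],
                       class2 = levels(g)[cmb[2, ]],
                       z = z, p = p, p_adj = p_adj,
                       stringsAsFactors = FALSE),
    letters = letters[ord]
  )
}

## Compact letter display by insert-and-absorb: start from one group holding
## all classes; for every significant pair split the groups containing both;
## absorb groups that are subsets of others; letter groups in the order of
## their best class (per `ord`, classes ranked best first).
cld_letters <- function(k, sig_pairs, ord = seq_len(k)) {
  groups <- list(seq_len(k))
  if (length(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[i, 1]; b <- sig_pairs[i, 2]
      new_groups <- list()
      for (gset in groups) {
        if (a %in% gset && b %in% gset) {
          new_groups <- c(new_groups, list(setdiff(gset, a)),
                          list(setdiff(gset, b)))
        } else new_groups <- c(new_groups, list(gset))
      }
      ## absorb: drop duplicates and any group properly contained in another
      new_groups <- unique(lapply(new_groups, sort))
      keep <- rep(TRUE, length(new_groups))
      for (x in seq_along(new_groups)) {
        for (y in seq_along(new_groups)) {
          if (x != y && keep[x] &&
              length(new_groups[[x]]) < length(new_groups[[y]]) &&
              all(new_groups[[x]] %in% new_groups[[y]]))
            keep[x] <- FALSE
        }
      }
      groups <- new_groups[keep]
    }
  }
  rank_of <- match(seq_len(k), ord)
  best <- vapply(groups, function(gset) min(rank_of[gset]), numeric(1))
  groups <- groups[order(best)]
  labs <- vapply(seq_len(k), function(cl) {
    paste(letters[which(vapply(groups, function(gset) cl %in% gset,
                               logical(1)))], collapse = "")
  }, character(1))
  labs
}

#' Class medians of a trait
#'
#' @inheritParams kw_test
#' @return named numeric vector of per-class medians over non-missing
#'   values (`NA` for empty classes), ordered by decreasing median.
#' @export
class_medians <- function(values, classes) {
  g <- factor(classes)
  meds <- tapply(values, g, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) median(x) else NA_real_
  })
  meds <- setNames(as.numeric(meds), names(meds))
  meds[order(-replace(meds, is.na(meds), -Inf))]
}
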