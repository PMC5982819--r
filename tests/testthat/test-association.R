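test_that("the tie-corrected H statistic and p match the reference implementation", {
  set.seed(77)
  for (i in 1:20) {
    v <- sample(c(0, 0, 0, 1, 2, 5, 9, 13), 30, TRUE) # heavy ties
    g <- sample(c("A/A", "A/B", "B/B"), 30, TRUE)
    kw <- kw_test(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(kw$H, unname(ref$statistic))
    expect_equal(kw$p, ref$p.value)
    expect_equal(kw$lod, -log10(ref$p.value))
  }
})

test_that("fully tied data carry no signal", {
  kw <- kw_test(rep(3, 12), rep(c("a", "b", "c"), 4))
  expect_equal(kw$H, 0)
  expect_equal(kw$lod, 0)
  pp <- permutation_pvalue(rep(3, 12), rep(c("a", "b", "c"), 4), n_perm = 50)
  expect_equal(pp$p_perm, 1)
})

test_that("the permutation estimator matches exhaustive enumeration on a toy", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  obs <- kw_test(v, g)$H
  ## enumerate all 20 assignments of the values to groups of 3
  combos <- combn(6, 3)
  H_all <- apply(combos, 2, function(ix)
    kw_test(v, replace(rep("b", 6), ix, "a"))$H)
  exact <- mean(H_all >= obs - 1e-10)
  expect_equal(exact, 0.1) # both perfectly separated assignments are extreme
  pp <- permutation_pvalue(v, g, n_perm = 4000, seed = 1)
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(pp$p_perm - exact), 3 * mc_se + 1 / 4001)
})

test_that("an observation more extreme than every permutation attains the +1-corrected floor", {
  v <- 1:30
  g <- rep(c("a", "b"), each = 15)
  pp <- permutation_pvalue(v, g, n_perm = 200, seed = 7)
  expect_equal(pp$p_perm, 1 / 201)
})

test_that("Dunn letters separate only genuinely different classes", {
  ## planted: one high class, two equivalent low classes
  set.seed(3)
  v <- c(rnorm(30, 10), rnorm(30, 0), rnorm(30, 0))
  g <- rep(c("hi", "lo1", "lo2"), each = 30)
  dn <- dunn_posthoc(v, g)
  expect_equal(unname(dn$letters["hi"]), "a")
  expect_equal(unname(dn$letters["lo1"]), "b")
  expect_equal(unname(dn$letters["lo2"]), "b")
  ## the Bonferroni factor is the number of pairwise comparisons
  expect_equal(dn$pairs$p_adj, pmin(1, dn$pairs$p * 3))
  ## two identical classes share a letter with adjusted p = 1
  v2 <- rep(c(1, 2, 3, 4), 2)
  g2 <- rep(c("x", "y"), each = 4)
  dn2 <- dunn_posthoc(v2, g2)
  expect_equal(dn2$pairs$p_adj, 1)
  expect_equal(unname(dn2$letters), c("a", "a"))
  ## for two classes, the Dunn z statistic squares to the K-W H
  v3 <- c(1, 3, 2, 8, 9, 7, 7)
  g3 <- c(rep("a", 3), rep("b", 4))
  expect_equal(dunn_posthoc(v3, g3)$pairs$z^2, kw_test(v3, g3)$H)
})

test_that("under the null all classes usually share one letter", {
  set.seed(9)
  shared <- vapply(1:100, function(i) {
    v <- rnorm(60)
    g <- rep(c("a", "b", "c"), each = 20)
    all(dunn_posthoc(v, g)$letters == "a")
  }, logical(1))
  expect_gte(mean(shared), 0.95)
})

test_that("class medians are ordered and match the order-statistics oracle", {
  m <- class_medians(c(0, 0, 4, 8, 100), c("a", "a", "a", "a", "b"))
  expect_equal(unname(m), c(100, 2))
  expect_equal(names(m), c("b", "a"))
  set.seed(4)
  v <- rnorm(90)
  g <- sample(c("p", "q", "r"), 90, TRUE)
  m2 <- class_medians(v, g)
  for (cl in names(m2)) {
    sorted <- sort(v[g == cl])
    n <- length(sorted)
    manual <- if (n %% 2) sorted[(n + 1) / 2] else
      mean(sorted[n / 2 + 0:1])
    expect_equal(unname(m2[cl]), manual)
  }
})

test_that("locus filtering enforces call counts and minor haplotype frequency", {
  mk_col <- function(n_called, n_total, maf) {
    n_minor <- round(2 * n_called * maf)
    calls <- c(rep("A/B", n_minor), rep("A/A", n_called - n_minor),
               rep(NA_character_, n_total - n_called))
    calls
  }
  m <- cbind(l1 = mk_col(95, 120, 0.2), # too few calls
             l2 = mk_col(110, 120, 0.09), # minor frequency below 10%
             l3 = mk_col(110, 120, 0.11))
  rownames(m) <- sprintf("I%03d", 1:120)
  keep <- filter_itags(m, gwas_params(min_genotypes = 100))
  expect_equal(unname(keep), c(FALSE, FALSE, TRUE))
  ## brute-force oracle on random matrices
  set.seed(21)
  for (rep in 1:3) {
    mm <- replicate(8, sample(c("A/A", "A/B", "B/B", NA), 60, TRUE,
                              prob = c(.4, .2, .1, .3)))
    colnames(mm) <- paste0("L", 1:8)
    keep <- filter_itags(mm, gwas_params(min_genotypes = 30, maf_min = 0.2))
    oracle <- apply(mm, 2, function(cc) {
      called <- cc[!is.na(cc)]
      if (length(called) < 30) return(FALSE)
      al <- unlist(strsplit(called, "/"))
      fr <- sort(table(al) / length(al), decreasing = TRUE)
      length(fr) >= 2 && fr[2] >= 0.2
    })
    expect_equal(unname(keep), unname(oracle))
  }
})

test_that("significance requires both the LOD and the permutation condition", {
  cfg <- biallelic_config(
    n_tag_loci = 6,
    qtl_spec = data.frame(locus = 2L, allele = 1L, beta_response = 0.4,
                          beta_els = 0.35, beta_green = 0, beta_albino = 0),
    seed = 14)
  tr <- simulate_truth(cfg)
  traits <- derive_traits(simulate_traits(tr))
  geno <- truth_genotype_matrix(tr)
  res <- run_gwas(geno, traits[traits$year == 1, ],
                  gwas_params(n_perm = 100, min_genotypes = 100, seed = 2))
  r <- res$records
  expect_true(all(r$significant ==
                    (r$lod >= 3 & r$perm_p <= 0.01)))
  ## letters attach only to significant records
  sig_keys <- paste(r$locus, r$trait)[r$significant]
  cl <- res$classes
  has_letters <- !is.na(cl$letter)
  expect_true(all(paste(cl$locus, cl$trait)[has_letters] %in% sig_keys))
})

test_that("all rank statistics are invariant under monotone trait transforms", {
  cfg <- biallelic_config(
    n_tag_loci = 4,
    qtl_spec = data.frame(locus = 1L, allele = 1L, beta_response = 1.2,
                          beta_els = 1, beta_green = 0, beta_albino = 0),
    seed = 15)
  tr <- simulate_truth(cfg)
  traits <- derive_traits(simulate_traits(tr))
  traits <- traits[traits$year == 1, ]
  geno <- truth_genotype_matrix(tr)
  p <- gwas_params(n_perm = 100, min_genotypes = 100, seed = 5)
  base <- run_gwas(geno, traits, p, trait_cols = "ELS_per_100AC")
  for (f in list(exp = function(x) exp(x / 50),
                 log1p = function(x) log1p(x))) {
    tt <- traits
    tt$ELS_per_100AC <- f(tt$ELS_per_100AC)
    res <- run_gwas(geno, tt, p, trait_cols = "ELS_per_100AC")
    expect_equal(res$records$H, base$records$H)
    expect_equal(res$records$lod, base$records$lod)
    expect_equal(res$records$perm_p, base$records$perm_p)
    expect_equal(res$records$significant, base$records$significant)
    expect_equal(res$classes$letter, base$classes$letter)
  }
})

test_that("significant records collapse to distinct scaffolds with sub-labels", {
  rec <- data.frame(
    locus = sprintf("0:scf%d:%d", c(1:12, 13, 13), c(1:12, 5, 9)),
    scaffold = sprintf("scf%d", c(1:12, 13, 13)),
    trait = c(rep("RA_pct", 7), rep("ELS_per_100AC", 7)),
    significant = TRUE, stringsAsFactors = FALSE
  )
  col <- collapse_to_scaffolds(rec)
  expect_equal(col$n_scaffolds, 13) # 14 records, two sharing a scaffold
  labs <- col$labels$label[col$labels$scaffold == "scf13"]
  expect_setequal(labs, c("scf13_1", "scf13_2"))
  ## no significant records: empty result
  rec$significant <- FALSE
  expect_equal(collapse_to_scaffolds(rec)$n_scaffolds, 0)
})

test_that("the PCA diagnostic reflects planted structure and normalises proportions", {
  ## two subpopulations fixed for different alleles at most loci
  n <- 40
  m <- cbind(
    l1 = c(rep("A/A", n), rep("B/B", n)),
    l2 = c(rep("C/C", n), rep("G/G", n)),
    l3 = c(rep("A/T", n), rep("A/A", n)),
    l4 = sample(c("A/A", "A/B"), 2 * n, TRUE)
  )
  rownames(m) <- sprintf("I%03d", seq_len(2 * n))
  prop <- pca_check(m)
  expect_true(all(diff(prop) <= 1e-12)) # nonincreasing
  expect_equal(sum(prop), 1)
  expect_gt(prop[1], 0.5)
  scores <- attr(prop, "scores")
  side <- scores[, 1] > 0
  expect_true(all(side[1:n] == side[1]) && all(side[(n + 1):(2 * n)] != side[1]))
  ## identical rows: nothing to explain
  m2 <- matrix("A/B", 10, 3, dimnames = list(paste0("I", 1:10), NULL))
  expect_length(pca_check(m2), 0)
})
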