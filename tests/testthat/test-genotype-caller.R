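pops <- data.frame(sample = c("I1", "I2", "I3"),
                   population = c("P1", "P1", "P2"),
                   stringsAsFactors = FALSE)

base_tag <- strrep("A", 100)

test_that("tags group by the exact (strand, scaffold, position) triple", {
  m <- matrix(c(5L, 0L, 0L, 200L, 0L, 0L), 2, 3,
              dimnames = list(c(base_tag, mutate_at(base_tag, 3, "C")),
                              pops$sample))
  tab <- toy_tag_table(list(
    list(flag = 0L, scaffold = "scf1", pos = 10L, tags = m),
    list(flag = 16L, scaffold = "scf1", pos = 10L,
         tags = matrix(150L, 1, 3, dimnames = list(
           mutate_at(base_tag, 9, "G"), pops$sample)))
  ), pops)
  g <- group_by_upos(sam_from_tags(tab), tab)
  expect_length(g, 2)
  sizes <- sort(vapply(g, function(x) nrow(x$tags), integer(1)))
  expect_equal(unname(sizes), c(1L, 2L))
  ## a SAM record without counts entry is a data error naming the tag
  sam <- sam_from_tags(tab)
  sam$qname[1] <- "Tmissing"
  expect_error(group_by_upos(sam, tab), "Tmissing")
})

test_that("grouping recovers the planted loci on simulated alignments", {
  cfg <- small_config(n_tag_loci = 20)
  tr <- simulate_truth(cfg)
  tc <- simulate_tag_counts(tr)
  g <- group_by_upos(sam_from_tags(tc), tc)
  expect_length(g, 20)
  ## group membership equals truth: all tags in a group share one locus
  for (grp in g) {
    loci <- tc$tags$locus[match(grp$tags$tag_id, tc$tags$tag_id)]
    expect_length(unique(loci), 1)
  }
})

test_that("the coverage filter applies a strict population-count cutoff", {
  mk <- function(count) {
    m <- matrix(c(count, 0L, 0L), 1, 3,
                dimnames = list(base_tag, pops$sample))
    toy_tag_table(list(list(flag = 0L, scaffold = "s", pos = 1L, tags = m)),
                  pops)
  }
  p <- caller_params()
  t101 <- mk(101L)
  g101 <- group_by_upos(sam_from_tags(t101), t101)
  expect_length(filter_low_coverage_upos(g101, p, counts = t101), 1)
  t100 <- mk(100L)
  g100 <- group_by_upos(sam_from_tags(t100), t100)
  expect_length(filter_low_coverage_upos(g100, p, counts = t100), 0)
})

test_that("the coverage filter agrees with a brute-force scan on random groups", {
  set.seed(31)
  for (rep in 1:5) {
    n_loci <- 12
    spec <- lapply(seq_len(n_loci), function(i) {
      n_tags <- sample(1:4, 1)
      seqs <- vapply(seq_len(n_tags), function(j)
        mutate_at(base_tag, j, "G"), character(1))
      m <- matrix(sample(0:120, n_tags * 3, TRUE), n_tags, 3,
                  dimnames = list(seqs, pops$sample))
      list(flag = 0L, scaffold = sprintf("s%d", i), pos = i, tags = m)
    })
    tab <- toy_tag_table(spec, pops)
    p <- caller_params(maf_count = 100)
    groups <- group_by_upos(sam_from_tags(tab), tab)
    kept <- names(filter_low_coverage_upos(groups, p, counts = tab))
    ## oracle: per population, scan the raw matrices
    oracle <- vapply(spec, function(l) {
      bypop <- cbind(P1 = l$tags[, "I1"] + l$tags[, "I2"],
                     P2 = l$tags[, "I3"])
      any(apply(bypop, 2, max) > 100)
    }, logical(1))
    spec_keys <- vapply(spec, function(l)
      paste(l$flag, l$scaffold, l$pos, sep = ":"), character(1))
    expect_setequal(kept, spec_keys[oracle])
  }
})

test_that("rare tags are removed by a strict 5% frequency rule", {
  mk <- function(major, minor) {
    m <- matrix(c(major, 0L, 0L, minor, 0L, 0L), 2, 3, byrow = TRUE,
                dimnames = list(c(base_tag, mutate_at(base_tag, 50, "T")),
                                pops$sample))
    toy_tag_table(list(list(flag = 0L, scaffold = "s", pos = 1L, tags = m)),
                  pops)
  }
  p <- caller_params()
  for (case in list(list(940L, 60L, 2L), list(960L, 40L, 1L),
                    list(950L, 50L, 1L))) {
    tab <- mk(case[[1]], case[[2]])
    g <- group_by_upos(sam_from_tags(tab), tab)[[1]]
    out <- filter_rare_tags(g, p, counts = tab)
    expect_equal(nrow(out$tags), case[[3]])
  }
})

test_that("isites are the disagreeing offsets and haplotypes their concatenation", {
  seqs <- c(mutate_at(mutate_at(base_tag, 5, "G"), 98, "T"),
            mutate_at(mutate_at(base_tag, 5, "T"), 98, "C"))
  m <- matrix(c(300L, 300L, 0L, 0L, 0L, 0L), 2, 3,
              dimnames = list(seqs, pops$sample))
  tab <- toy_tag_table(list(list(flag = 0L, scaffold = "s", pos = 1L,
                                 tags = m)), pops)
  g <- group_by_upos(sam_from_tags(tab), tab)[[1]]
  locus <- find_isites(g)
  expect_equal(locus$isite_offsets, c(4L, 97L)) # 0-based within the tag
  expect_setequal(unname(locus$haplotypes), c("GT", "TC"))
  ## single retained tag: monomorphic, not informative
  g1 <- g
  g1$tags <- g1$tags[1, , drop = FALSE]
  expect_null(find_isites(g1))
  ## one differing offset
  seqs2 <- c(base_tag, mutate_at(base_tag, 4, "C"))
  g2 <- g
  g2$tags <- data.frame(tag_id = c("Ta", "Tb"), seq = seqs2)
  l2 <- find_isites(g2)
  expect_equal(l2$isite_offsets, 3L)
})

test_that("exclusion rules catch excess alleles and excess haplotypes per individual", {
  locus <- list(upos = "0:s:1", flag = 0L, scaffold = "s", pos = 1L,
                tags = data.frame(tag_id = paste0("T", 1:4),
                                  seq = paste0("X", 1:4)),
                isite_offsets = 0L,
                haplotypes = setNames(c("A", "C", "G", "T"),
                                      paste0("T", 1:4)))
  obs <- data.frame(sample = "I1", hap = "A", count = 10)
  ## 4 alleles tolerated at max_alleles = 4, excluded at 3
  expect_true(apply_exclusions(locus, obs, caller_params()))
  res <- apply_exclusions(locus, obs, caller_params(max_alleles = 3))
  expect_false(isTRUE(res))
  expect_equal(attr(res, "reason"), "isite_alleles")
  ## an individual with three haplotypes violates diploidy
  obs3 <- data.frame(sample = "I1", hap = c("A", "C", "G"), count = 5)
  res3 <- apply_exclusions(locus, obs3, caller_params())
  expect_equal(attr(res3, "reason"), "ploidy")
  ## alternative reading: more isites than the ploidy level
  locus2 <- locus
  locus2$isite_offsets <- c(0L, 4L, 9L)
  locus2$haplotypes <- setNames(c("ACG", "CGT"), c("T1", "T2"))
  res4 <- apply_exclusions(locus2, obs,
                           caller_params(exclusion_rule = "isites_per_ploidy"))
  expect_equal(attr(res4, "reason"), "isites")
})

test_that("individual calls follow the heterozygote and minAC rules", {
  locus <- list(haplotypes = setNames(c("C", "T"), c("T1", "T2")))
  p <- caller_params()
  expect_equal(call_individual(locus, c(C = 20), p), "C/C")
  expect_true(is.na(call_individual(locus, c(C = 5), p)))
  expect_true(is.na(call_individual(locus, c(C = 8), p))) # boundary: not > 8
  expect_equal(call_individual(locus, c(C = 9, T = 1), p), "C/T")
  expect_true(is.na(call_individual(locus, setNames(numeric(0),
                                                    character(0)), p)))
  ## canonical multi-site label ordering
  locus2 <- list(haplotypes = setNames(c("GAG", "CGA"), c("T1", "T2")))
  expect_equal(call_individual(locus2, c(GAG = 10, CGA = 12), p), "CGA/GAG")
})

test_that("error-free deep calls recover the truth exactly", {
  cfg <- small_config(n_tag_loci = 60, seed = 2)
  tr <- simulate_truth(cfg)
  tc <- simulate_tag_counts(tr)
  geno <- call_genotypes(tc, caller_params())
  acc <- call_accuracy(geno, tr)
  expect_gt(acc$n_loci, 20)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$missing_rate, 0)
})

test_that("zero depth yields an all-missing matrix", {
  cfg <- small_config(n_tag_loci = 8,
                      depth_model = list(mean = 0, dispersion = 1,
                                         fixed = TRUE))
  tr <- simulate_truth(cfg)
  tc <- simulate_tag_counts(tr)
  geno <- call_genotypes(tc, caller_params())
  expect_equal(ncol(geno$calls), 0) # nothing passes discovery without reads
})

test_that("the caller is invariant to row order of counts and samples", {
  cfg <- small_config(n_tag_loci = 15, seed = 5)
  tr <- simulate_truth(cfg)
  tc <- simulate_tag_counts(tr)
  g1 <- call_genotypes(tc, caller_params())
  set.seed(1)
  tc2 <- tc
  tc2$counts <- tc$counts[sample(nrow(tc$counts)), ]
  tc2$tags <- tc$tags[sample(nrow(tc$tags)), ]
  g2 <- call_genotypes(tc2, caller_params())
  expect_identical(g1$calls, g2$calls[rownames(g1$calls),
                                      colnames(g1$calls)])
})

test_that("raising the sequencing error rate degrades calls monotonically", {
  degradation <- function(err, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- small_config(n_tag_loci = 25, seed = s, seq_error_rate = err,
                          depth_model = list(mean = 20, dispersion = 2,
                                             fixed = FALSE))
      tr <- simulate_truth(cfg)
      tc <- simulate_tag_counts(tr)
      geno <- call_genotypes(tc, caller_params(maf_count = 100))
      n_total <- 25
      n_excluded <- nrow(geno$excluded)
      miss <- if (ncol(geno$calls)) mean(is.na(geno$calls)) else 1
      (n_excluded / n_total) + miss
    }, numeric(1)))
  }
  lo <- degradation(0.005, 1:3)
  hi <- degradation(0.03, 1:3)
  expect_gt(hi, lo)
})
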