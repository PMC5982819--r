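#' Parameters of the tag-haplotype genotype caller
#'
#' The caller mirrors a ploidy-constrained discovery procedure: tags are
#' grouped by unique alignment position (Upos), low-coverage groups are
#' removed by requiring at least one tag with a population count above
#' `maf_count`, tags below a 5% within-group frequency are dropped,
#' polymorphic sites (Isites) are identified among the retained tags, and
#' per-individual genotypes are called as unordered haplotype pairs.
#'
#' @param maf_count absolute count cutoff: a Upos group is kept only if one
#'   of its tags exceeds this population count (strictly).
#' @param min_allele_count minAC: a single observed haplotype is called
#'   homozygous only when its count strictly exceeds this value; otherwise
#'   the call is missing (a second allele cannot be excluded).
#' @param ploidy individual ploidy; an individual presenting more distinct
#'   haplotypes than this excludes the locus.
#' @param max_alleles maximum distinct alleles tolerated at one Isite across
#'   the population before the locus is excluded.
#' @param tag_freq_min within-group frequency below which a tag is removed
#'   (strictly greater-than retains).
#' @param het_min_count optional per-allele minimum count for heterozygous
#'   calls (0 disables it; provided for robustness studies, the default
#'   caller attaches a count requirement only to homozygous calls).
#' @param maf_scope `"population"` applies `maf_count` and the frequency
#'   filter within each pair-cross population (a tag survives if it passes
#'   in at least one population whose group coverage qualifies);
#'   `"joint"` pools all individuals.
#' @param exclusion_rule `"individual_haplotypes"` (default) excludes a
#'   locus when any individual shows more haplotypes than the ploidy;
#'   `"isites_per_ploidy"` is the alternative reading that instead excludes
#'   loci with more Isites than the ploidy level.
#' @return a named list of class `caller_params`.
#' @export
caller_params <- function(maf_count = 100, min_allele_count = 8,
                          ploidy = 2, max_alleles = 4,
                          tag_freq_min = 0.05, het_min_count = 0,
                          maf_scope = c("population", "joint"),
                          exclusion_rule = c("individual_haplotypes",
                                             "isites_per_ploidy")) {
  p <- list(maf_count = maf_count, min_allele_count = min_allele_count,
            ploidy = as.integer(ploidy), max_alleles = as.integer(max_alleles),
            tag_freq_min = tag_freq_min, het_min_count = het_min_count,
            maf_scope = match.arg(maf_scope),
            exclusion_rule = match.arg(exclusion_rule))
  stopifnot(p$maf_count >= 0, p$min_allele_count >= 0, p$ploidy >= 1,
            p$max_alleles >= 1, p$tag_freq_min > 0, p$tag_freq_min < 1)
  class(p) <- "caller_params"
  p
}

#' Group aligned tags by unique position (Upos)
#'
#' The Upos key is the exact triple (orientation flag, reference scaffold,
#' 1-based position); tags aligned to the same position on opposite strands
#' form distinct groups. Every mapped tag lands in exactly one group
#' (multi-mapped tags must have been suppressed at alignment).
#'
#' @param sam data.frame of mapped unique-tag records as returned by
#'   [read_sam_tags()] (`qname` must equal the tag id in `counts`).
#' @param counts a [tag_count_table()]; every SAM record must have a counts
#'   entry.
#' @return a named list of groups, each a list with `upos`, `flag`,
#'   `scaffold`, `pos` and a `tags` data.frame (`tag_id`, `seq`).
#' @export
group_by_upos <- function(sam, counts) {
  stopifnot(inherits(counts, "tag_count_table"))
  missing_tag <- setdiff(sam$qname, counts$tags$tag_id)
  if (length(missing_tag))
    stop_data("SAM record without a counts entry: tag %s", missing_tag[1])
  seqs <- counts$tags$seq[match(sam$qname, counts$tags$tag_id)]
  key <- upos_key(bitwAnd(sam$flag, 16L), sam$rname, sam$pos)
  idx <- split(seq_len(nrow(sam)), key)
  lapply(idx, function(i) {
    list(upos = key[i[1]],
         flag = bitwAnd(sam$flag[i[1]], 16L),
         scaffold = sam$rname[i[1]],
         pos = sam$pos[i[1]],
         tags = data.frame(tag_id = sam$qname[i], seq = seqs[i],
                           stringsAsFactors = FALSE))
  })
}

## Per-tag counts within the populations relevant for discovery filters.
## Returns a data.table (tag_id, population, count); under joint scope all
## samples count as a single pseudo-population.
discovery_counts <- function(counts, params) {
  pc <- population_counts(counts)
  if (params$maf_scope == "joint")
    pc <- pc[, .(count = sum(count)), by = tag_id][, population := "__all__"]
  pc
}

#' Remove low-coverage Upos groups
#'
#' A group is retained if and only if the maximum population count over its
#' tags strictly exceeds `maf_count` (in at least one population, or jointly
#' under `maf_scope = "joint"`).
#'
#' @param groups result of [group_by_upos()].
#' @param params [caller_params()].
#' @param pop_counts optional precomputed [discovery_counts()] table.
#' @param counts the [tag_count_table()] (used when `pop_counts` is `NULL`).
#' @return the retained subset of `groups`.
#' @export
filter_low_coverage_upos <- function(groups, params, counts = NULL,
                                     pop_counts = NULL) {
  if (is.null(pop_counts)) pop_counts <- discovery_counts(counts, params)
  keep <- vapply(groups, function(g) {
    cc <- pop_counts$count[pop_counts$tag_id %in% g$tags$tag_id]
    length(cc) > 0 && max(cc) > params$maf_count
  }, logical(1))
  groups[keep]
}

#' Remove rare tags within a Upos group
#'
#' Tag frequency is computed on population counts over the group total
#' before any removal; a tag is kept when its frequency strictly exceeds
#' `tag_freq_min` in at least one population whose group coverage passes the
#' `maf_count` criterion (all populations under joint scope).
#'
#' @param group one group from [group_by_upos()].
#' @inheritParams filter_low_coverage_upos
#' @return the group with its `tags` reduced, or `NULL` when no tag
#'   survives.
#' @export
filter_rare_tags <- function(group, params, counts = NULL,
                             pop_counts = NULL) {
  if (is.null(pop_counts)) pop_counts <- discovery_counts(counts, params)
  pc <- pop_counts[pop_counts$tag_id %in% group$tags$tag_id]
  if (!nrow(pc)) return(NULL)
  pc <- pc[, .(count = sum(count)), by = .(tag_id, population)]
  totals <- pc[, .(total = sum(count), maxc = max(count)), by = population]
  qualifying <- totals$population[totals$maxc > params$maf_count]
  if (!length(qualifying)) return(NULL)
  pc <- pc[population %in% qualifying]
  pc[, total := sum(count), by = population]
  keep_tags <- unique(pc$tag_id[pc$count / pc$total > params$tag_freq_min])
  if (!length(keep_tags)) return(NULL)
  group$tags <- group$tags[group$tags$tag_id %in% keep_tags, , drop = FALSE]
  group
}

#' Identify informative sites (Isites) within a Upos group
#'
#' Isites are the tag positions at which the retained tags disagree. Groups
#' without any polymorphic position (including single-tag groups) are
#' non-informative and return `NULL`; the tag haplotype is the concatenation
#' of its bases at the Isite offsets.
#'
#' @param group a (rare-tag filtered) group.
#' @return an Itag locus: a list with `upos`, `flag`, `scaffold`, `pos`,
#'   `tags`, `isite_offsets` (0-based) and `haplotypes` (named by tag id),
#'   or `NULL` when the group is monomorphic.
#' @export
find_isites <- function(group) {
  if (is.null(group) || nrow(group$tags) < 2) return(NULL)
  chars <- do.call(rbind, strsplit(group$tags$seq, "", fixed = TRUE))
  poly <- which(apply(chars, 2, function(col) length(unique(col)) > 1))
  if (!length(poly)) return(NULL)
  haps <- apply(chars[, poly, drop = FALSE], 1, paste, collapse = "")
  locus <- group
  locus$isite_offsets <- as.integer(poly - 1L)
  locus$haplotypes <- setNames(haps, group$tags$tag_id)
  locus
}

#' Apply the ploidy and allele-number exclusion rules to a locus
#'
#' A locus is excluded when any Isite carries more distinct alleles than
#' `max_alleles` across the retained tags, or (default rule) when any
#' individual presents more distinct haplotypes than the ploidy level. The
#' alternative reading (`exclusion_rule = "isites_per_ploidy"`) instead
#' excludes loci whose number of Isites exceeds the ploidy.
#'
#' @param locus an Itag locus from [find_isites()].
#' @param observations data.frame of per-individual observations with
#'   columns `sample`, `hap`, `count` (only haplotypes with nonzero counts).
#' @param params [caller_params()].
#' @return `TRUE` to keep the locus, otherwise `FALSE` with a `reason`
#'   attribute (`"isite_alleles"`, `"ploidy"` or `"isites"`).
#' @export
apply_exclusions <- function(locus, observations, params) {
  haps <- unique(locus$haplotypes)
  s <- nchar(haps[1])
  for (j in seq_len(s)) {
    if (length(unique(substr(haps, j, j))) > params$max_alleles)
      return(structure(FALSE, reason = "isite_alleles"))
  }
  if (params$exclusion_rule == "isites_per_ploidy") {
    if (length(locus$isite_offsets) > params$ploidy)
      return(structure(FALSE, reason = "isites"))
  } else if (nrow(observations)) {
    nh <- tapply(observations$hap, observations$sample,
                 function(h) length(unique(h)))
    if (any(nh > params$ploidy))
      return(structure(FALSE, reason = "ploidy"))
  }
  TRUE
}

#' Call one individual at one locus
#'
#' Two observed haplotypes give a heterozygous call; a single observed
#' haplotype is called homozygous only when its count strictly exceeds
#' `min_allele_count` (otherwise a second, unseen allele cannot be excluded
#' and the call is missing); no observation gives a missing call.
#'
#' @param locus an Itag locus (for the haplotype alphabet check).
#' @param hap_counts named numeric vector: observed haplotype -> read count.
#' @param params [caller_params()].
#' @return the genotype label `"hap1/hap2"` (haplotypes sorted) or
#'   `NA_character_`.
#' @export
call_individual <- function(locus, hap_counts, params) {
  hap_counts <- hap_counts[hap_counts > params$het_min_count]
  if (!length(hap_counts)) return(NA_character_)
  if (!all(names(hap_counts) %in% locus$haplotypes))
    stop_data("observed haplotype outside the locus alphabet")
  nh <- length(hap_counts)
  if (nh > params$ploidy)
    stop_data("individual presents %d haplotypes (> ploidy); locus should have been excluded", nh)
  if (nh == 2) {
    hs <- sort(names(hap_counts), method = "radix")
    return(paste(hs[1], hs[2], sep = "/"))
  }
  if (hap_counts[1] > params$min_allele_count)
    return(paste(names(hap_counts)[1], names(hap_counts)[1], sep = "/"))
  NA_character_
}

#' Call the full individuals-by-loci genotype matrix
#'
#' Applies the exclusion rules and [call_individual()] over every
#' individual and Itag locus. The heavy lifting is done in one grouped pass
#' so the call is order-invariant and fast for hundreds of individuals and
#' loci.
#'
#' @param loci list of Itag loci (from [find_isites()]).
#' @param counts a [tag_count_table()].
#' @param params [caller_params()].
#' @return an object of class `tag_genotypes`: list with `calls` (character
#'   matrix individuals x loci, `NA` missing), `locus_info` (data.frame with
#'   `upos`, `flag`, `scaffold`, `pos`, `n_isites`, list-columns
#'   `isite_offsets`, `alleles`), `excluded` (data.frame of excluded loci
#'   and reasons) and `params`.
#' @export
call_matrix <- function(loci, counts, params) {
  stopifnot(inherits(counts, "tag_count_table"))
  samples <- counts$samples$sample
  loci <- Filter(Negate(is.null), loci)
  excluded <- data.frame(upos = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!length(loci)) {
    return(structure(list(
      calls = matrix(NA_character_, length(samples), 0,
                     dimnames = list(samples, NULL)),
      locus_info = data.frame(), excluded = excluded, params = params),
      class = "tag_genotypes"))
  }
  tag_map <- data.table::rbindlist(lapply(loci, function(l)
    data.table::data.table(tag_id = l$tags$tag_id, upos = l$upos,
                           hap = unname(l$haplotypes))))
  dt <- merge(data.table::as.data.table(counts$counts), tag_map,
              by = "tag_id")
  if (params$het_min_count > 0) dt <- dt[count > params$het_min_count]
  dt <- dt[count > 0, .(count = sum(count)), by = .(upos, sample, hap)]
  data.table::setorder(dt, upos, sample, hap)
  cells <- dt[, .(n_hap = .N, h1 = hap[1], h2 = hap[.N],
                  c1 = count[1], total = sum(count)),
              by = .(upos, sample)]

  ## exclusion pass: the per-individual haplotype tally is already grouped
  ## in `cells`, so the rules of apply_exclusions() are evaluated without
  ## re-subsetting the count table per locus
  names(loci) <- vapply(loci, `[[`, character(1), "upos")
  max_nh <- cells[, .(max_nh = max(n_hap)), by = upos]
  max_nh <- setNames(max_nh$max_nh, max_nh$upos)
  keep <- logical(length(loci))
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    ok <- apply_exclusions(l, data.frame(sample = character(),
                                         hap = character(),
                                         count = integer()), params)
    reason <- if (!isTRUE(ok)) attr(ok, "reason") else NULL
    if (is.null(reason) && params$exclusion_rule == "individual_haplotypes" &&
        isTRUE(max_nh[l$upos] > params$ploidy))
      reason <- "ploidy"
    keep[i] <- is.null(reason)
    if (!keep[i])
      excluded <- rbind(excluded, data.frame(
        upos = l$upos, reason = reason, stringsAsFactors = FALSE))
  }
  loci_kept <- loci[keep]
  if (!length(loci_kept)) {
    return(structure(list(
      calls = matrix(NA_character_, length(samples), 0,
                     dimnames = list(samples, NULL)),
      locus_info = data.frame(), excluded = excluded, params = params),
      class = "tag_genotypes"))
  }
  cells <- cells[upos %in% names(loci_kept)]
  cells[, call := data.table::fifelse(
    n_hap == 2L, paste(h1, h2, sep = "/"),
    data.table::fifelse(n_hap == 1L & c1 > params$min_allele_count,
                        paste(h1, h1, sep = "/"), NA_character_))]
  ## individuals that slipped past exclusion with > ploidy haplotypes would
  ## be a logic error; the exclusion pass above guarantees n_hap <= ploidy
  cells[n_hap > params$ploidy, call := NA_character_]

  m <- matrix(NA_character_, length(samples), length(loci_kept),
              dimnames = list(samples, names(loci_kept)))
  m[cbind(match(cells$sample, samples), match(cells$upos, names(loci_kept)))] <-
    cells$call
  info <- data.frame(
    locus = names(loci_kept),
    upos = names(loci_kept),
    flag = vapply(loci_kept, `[[`, numeric(1), "flag"),
    scaffold = vapply(loci_kept, `[[`, character(1), "scaffold"),
    pos = vapply(loci_kept, `[[`, numeric(1), "pos"),
    n_isites = vapply(loci_kept, function(l) length(l$isite_offsets),
                      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  info$isite_offsets <- lapply(loci_kept, `[[`, "isite_offsets")
  info$alleles <- lapply(loci_kept, function(l)
    sort(unique(unname(l$haplotypes)), method = "radix"))
  structure(list(calls = m, locus_info = info, excluded = excluded,
                 params = params),
            class = "tag_genotypes")
}

#' Run the full genotype caller on a tag count table
#'
#' Convenience driver chaining [group_by_upos()],
#' [filter_low_coverage_upos()], [filter_rare_tags()], [find_isites()] and
#' [call_matrix()].
#'
#' @param counts a [tag_count_table()]. When `sam` is `NULL`, alignment keys
#'   are taken from the tag table's `flag`/`scaffold`/`pos` columns.
#' @param params [caller_params()].
#' @param sam optional data.frame of SAM records (see [read_sam_tags()]).
#' @return a `tag_genotypes` object (see [call_matrix()]); its `stats`
#'   element tallies groups dropped at each stage.
#' @export
call_genotypes <- function(counts, params = caller_params(), sam = NULL) {
  stopifnot(inherits(counts, "tag_count_table"))
  if (is.null(sam)) {
    tg <- counts$tags
    if (!all(c("flag", "scaffold", "pos") %in% names(tg)))
      stop_data("no SAM records given and tag table has no alignment keys")
    tg <- tg[!is.na(tg$scaffold), ]
    sam <- data.frame(qname = tg$tag_id, flag = tg$flag, rname = tg$scaffold,
                      pos = tg$pos, seq = tg$seq, stringsAsFactors = FALSE)
  }
  pop_counts <- discovery_counts(counts, params)
  groups <- group_by_upos(sam, counts)
  n_groups <- length(groups)
  groups <- filter_low_coverage_upos(groups, params, pop_counts = pop_counts)
  n_cov <- length(groups)
  loci <- lapply(groups, function(g)
    find_isites(filter_rare_tags(g, params, pop_counts = pop_counts)))
  n_poly <- sum(!vapply(loci, is.null, logical(1)))
  res <- call_matrix(loci, counts, params)
  res$stats <- data.frame(
    n_groups = n_groups, n_after_coverage = n_cov,
    n_informative = n_poly, n_excluded = nrow(res$excluded),
    n_called_loci = ncol(res$calls)
  )
  res
}

#' @export
print.tag_genotypes <- function(x, ...) {
  cat(sprintf("tag_genotypes: %d individuals x %d Itag loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0))
  if (nrow(x$excluded))
    cat(sprintf("excluded loci: %d (%s)\n", nrow(x$excluded),
                paste(sprintf("%s=%d", names(table(x$excluded$reason)),
                              table(x$excluded$reason)), collapse = ", ")))
  invisible(x)
}

#' Compare called genotypes with the simulation truth
#'
#' For every called locus, the expected call of each individual is derived
#' from its planted diplotype restricted to the caller's own Isite offsets
#' (relative to the locus tag). Accuracy is the fraction of individual x
#' locus cells whose call equals the expectation; missing calls count as
#' errors.
#'
#' @param geno a `tag_genotypes` object.
#' @param truth the `gbs_truth` the data were simulated from.
#' @return list with `accuracy`, `n_cells`, `n_loci`, `missing_rate`.
#' @export
call_accuracy <- function(geno, truth) {
  info <- geno$locus_info
  if (!nrow(info)) return(list(accuracy = NA_real_, n_cells = 0L,
                               n_loci = 0L, missing_rate = NA_real_))
  truth_upos <- upos_key(truth$loci$flag, truth$loci$scaffold,
                         truth$loci$pos)
  idx <- match(info$upos, truth_upos)
  if (anyNA(idx)) stop_data("called locus not present in truth")
  samples <- rownames(geno$calls)
  sidx <- match(samples, truth$offspring$ids)
  n_ok <- 0; n_cells <- 0
  for (j in seq_len(nrow(info))) {
    li <- idx[j]
    off <- info$isite_offsets[[j]] # 0-based within the tag
    hap_of <- vapply(truth$loci$allele_seqs[[li]], function(s)
      paste(vapply(off + 1L, function(p) substr(s, p, p), character(1)),
            collapse = ""), character(1), USE.NAMES = FALSE)
    a1 <- hap_of[truth$offspring$h1[sidx, li]]
    a2 <- hap_of[truth$offspring$h2[sidx, li]]
    expected <- genotype_label(a1, a2)
    got <- geno$calls[, info$upos[j]]
    n_ok <- n_ok + sum(!is.na(got) & got == expected)
    n_cells <- n_cells + length(expected)
  }
  list(accuracy = n_ok / n_cells, n_cells = n_cells,
       n_loci = nrow(info), missing_rate = mean(is.na(geno$calls)))
}
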