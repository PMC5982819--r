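#' Genome-wide nonparametric association scan
#'
#' For every testable Itag locus (see [filter_itags()]) and every trait, the
#' tie-corrected Kruskal-Wallis test is run on the trait values grouped by
#' genotype class, with pairwise deletion of individuals missing either the
#' genotype or the trait and removal of classes below `min_class_size`. A
#' permutation p-value is estimated for each test, and a record is declared
#' significant when LOD >= `lod_threshold` AND permutation p <=
#' `perm_alpha`. Class medians are attached to every record; Bonferroni
#' corrected Dunn letters are computed for the significant ones. The whole
#' scan is reproducible bit for bit given `params$seed`.
#'
#' @param geno genotype matrix (individuals x loci, `"hap1/hap2"` labels,
#'   `NA` missing) or a `tag_genotypes` object; a `locus_info` attribute or
#'   element supplies scaffold assignments when present.
#' @param traits a [derive_traits()] table for one campaign (one row per
#'   genotype).
#' @param params [gwas_params()].
#' @param trait_cols trait columns to scan (default the eight standard
#'   traits present in `traits`).
#' @return an object of class `gwas_result`: list with `records` (one row
#'   per locus x trait: `locus`, `scaffold`, `trait`, `n`, `k`, `H`, `p`,
#'   `lod`, `perm_p`, `significant`) and `classes` (one row per locus x
#'   trait x genotype class: `n`, `median`, `letter` -- letters only for
#'   significant records), plus the `params` used.
#' @export
run_gwas <- function(geno, traits, params = gwas_params(),
                     trait_cols = intersect(TRAIT_COLUMNS, names(traits))) {
  locus_info <- NULL
  if (inherits(geno, "tag_genotypes")) {
    locus_info <- geno$locus_info
    geno <- geno$calls
  } else {
    locus_info <- attr(geno, "locus_info")
  }
  if (!length(trait_cols)) stop_data("no trait columns to test")
  shared <- intersect(rownames(geno), traits$genotype)
  if (!length(shared))
    stop_data("genotype matrix and trait table share no individuals")
  geno <- geno[shared, , drop = FALSE]
  traits <- traits[match(shared, traits$genotype), , drop = FALSE]

  scaffold_of <- function(locus) {
    if (!is.null(locus_info) && nrow(locus_info)) {
      i <- if (!is.null(locus_info$upos)) match(locus, locus_info$upos)
      else NA_integer_
      if (is.na(i) && !is.null(locus_info$locus))
        i <- match(locus, locus_info$locus)
      if (!is.na(i)) return(locus_info$scaffold[i])
    }
    ## fall back to parsing a "flag:scaffold:pos" Upos key
    sub("^[0-9]+:", "", sub(":[0-9]+$", "", locus))
  }

  testable <- filter_itags(geno, params)
  loci <- colnames(geno)[testable]

  set.seed(params$seed)
  rec <- list(); cls <- list(); tests <- list()
  for (locus in loci) {
    calls <- geno[, locus]
    for (tr in trait_cols) {
      v <- traits[[tr]]
      ok <- !is.na(calls) & !is.na(v)
      if (!sum(ok)) next
      g <- calls[ok]; vv <- v[ok]
      sizes <- table(g)
      keep_cls <- names(sizes)[sizes >= params$min_class_size]
      sel <- g %in% keep_cls
      g <- g[sel]; vv <- vv[sel]
      if (length(unique(g)) < 2 || length(vv) < 2) next
      kw <- kw_test(vv, g)
      perm_p <- if (params$perm_mode == "per_locus")
        permutation_pvalue(vv, g, n_perm = params$n_perm)$p_perm
      else NA_real_ # filled by the max-statistic pass below
      rec[[length(rec) + 1]] <- data.frame(
        locus = locus, scaffold = scaffold_of(locus), trait = tr,
        n = kw$n, k = kw$k, H = kw$H, p = kw$p, lod = kw$lod,
        perm_p = perm_p, significant = NA,
        stringsAsFactors = FALSE)
      tests[[length(tests) + 1]] <- list(values = vv, classes = g)
    }
  }
  if (params$perm_mode == "max_T" && length(tests)) {
    ## experiment-wise null: per permutation round, every test is permuted
    ## and the maximum H across all loci of a trait is recorded
    H_obs <- vapply(rec, function(r) r$H, numeric(1))
    trait_of <- vapply(rec, function(r) r$trait, character(1))
    Hp <- matrix(0, params$n_perm, length(tests))
    for (i in seq_along(tests)) {
      t_i <- tests[[i]]
      gfac <- droplevels(factor(t_i$classes))
      r <- rank(t_i$values)
      tie <- table(t_i$values)
      n <- length(r)
      C <- 1 - sum(tie^3 - tie) / (n^3 - n)
      if (C <= 0) next
      Hp[, i] <- perm_H(r, as.integer(gfac), tabulate(gfac), C,
                        params$n_perm)
    }
    for (tr in unique(trait_of)) {
      ii <- which(trait_of == tr)
      maxH <- apply(Hp[, ii, drop = FALSE], 1, max)
      for (i in ii)
        rec[[i]]$perm_p <- (1 + sum(maxH >= H_obs[i] - 1e-10)) /
          (params$n_perm + 1)
    }
  }
  ## significance, medians and post hoc letters
  for (i in seq_along(rec)) {
    r <- rec[[i]]
    vv <- tests[[i]]$values; g <- tests[[i]]$classes
    is_sig <- (r$lod >= params$lod_threshold) &&
      (r$perm_p <= params$perm_alpha)
    rec[[i]]$significant <- is_sig
    meds <- class_medians(vv, g)
    letters_out <- setNames(rep(NA_character_, length(meds)), names(meds))
    if (is_sig && length(meds) >= 2) {
      dn <- dunn_posthoc(vv, g, alpha = params$dunn_alpha)
      letters_out[names(dn$letters)] <- dn$letters
    }
    cls[[length(cls) + 1]] <- data.frame(
      locus = r$locus, scaffold = r$scaffold, trait = r$trait,
      class = names(meds),
      n = as.integer(table(g)[names(meds)]),
      median = unname(meds),
      letter = unname(letters_out),
      stringsAsFactors = FALSE)
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(locus = character(), scaffold = character(),
               trait = character(), n = integer(), k = integer(),
               H = numeric(), p = numeric(), lod = numeric(),
               perm_p = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  classes <- if (length(cls)) do.call(rbind, cls) else
    data.frame(locus = character(), scaffold = character(),
               trait = character(), class = character(), n = integer(),
               median = numeric(), letter = character(),
               stringsAsFactors = FALSE)
  rownames(records) <- rownames(classes) <- NULL
  structure(list(records = records, classes = classes, params = params),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %d tests (%d loci x %d traits), %d significant\n",
              nrow(x$records), length(unique(x$records$locus)),
              length(unique(x$records$trait)), sum(x$records$significant)))
  invisible(x)
}

#' Collapse significant records to the scaffold level
#'
#' Several Itags can map back to the same genome scaffold; for reporting,
#' significant scaffolds are counted once per trait and once overall, and
#' Itags sharing a scaffold receive `_1`, `_2`, ... suffixes (by position)
#' so their sub-records remain distinguishable.
#'
#' @param result a `gwas_result` (or its `records` data.frame).
#' @param locus_info optional locus table with `upos` and `pos` for ordering
#'   suffixes by position.
#' @return list with `scaffolds` (character vector of distinct significant
#'   scaffolds), `n_scaffolds`, `per_trait` (data.frame `trait`,
#'   `scaffold`), and `labels` (data.frame `locus`, `scaffold`, `label`).
#' @export
collapse_to_scaffolds <- function(result, locus_info = NULL) {
  records <- if (inherits(result, "gwas_result")) result$records else result
  sig <- records[records$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(scaffolds = character(0), n_scaffolds = 0L,
                per_trait = data.frame(trait = character(),
                                       scaffold = character(),
                                       stringsAsFactors = FALSE),
                labels = data.frame(locus = character(),
                                    scaffold = character(),
                                    label = character(),
                                    stringsAsFactors = FALSE)))
  }
  loci <- unique(sig[, c("locus", "scaffold")])
  pos_of <- function(locus) {
    if (!is.null(locus_info)) {
      i <- if (!is.null(locus_info$upos)) match(locus, locus_info$upos)
      else rep(NA_integer_, length(locus))
      if (anyNA(i) && !is.null(locus_info$locus))
        i[is.na(i)] <- match(locus[is.na(i)], locus_info$locus)
      if (!anyNA(i)) return(locus_info$pos[i])
    }
    suppressWarnings(as.integer(sub(".*:", "", locus)))
  }
  loci$pos <- pos_of(loci$locus)
  loci <- loci[order(loci$scaffold, loci$pos, loci$locus), , drop = FALSE]
  loci$label <- loci$scaffold
  dup <- ave(seq_len(nrow(loci)), loci$scaffold, FUN = length) > 1
  idx <- ave(seq_len(nrow(loci)), loci$scaffold, FUN = seq_along)
  loci$label[dup] <- paste0(loci$scaffold[dup], "_", idx[dup])
  per_trait <- unique(sig[, c("trait", "scaffold")])
  rownames(per_trait) <- NULL
  scaffolds <- sort(unique(sig$scaffold))
  list(scaffolds = scaffolds, n_scaffolds = length(scaffolds),
       per_trait = per_trait,
       labels = loci[, c("locus", "scaffold", "label")])
}

#' Population-structure diagnostic by principal component analysis
#'
#' Genotype calls are encoded as per-locus haplotype dosages (for every
#' retained haplotype of a locus, the number of copies an individual
#' carries: 0, 1 or 2). Columns without variation are dropped, missing
#' dosages are imputed with the column mean, columns are centered, and the
#' proportions of variance explained by the principal components are
#' returned. This is a diagnostic only -- no structure correction is applied
#' downstream.
#'
#' @param geno genotype matrix or `tag_genotypes`.
#' @param n_components number of leading components to keep scores for.
#' @return numeric vector of variance-explained proportions (ordered,
#'   nonincreasing, summing to at most 1), with the score matrix of the
#'   leading components as attribute `scores`.
#' @export
pca_check <- function(geno, n_components = 2) {
  if (inherits(geno, "tag_genotypes")) geno <- geno$calls
  if (!ncol(geno)) stop_data("no loci to analyse")
  cols <- list(); nm <- list()
  for (j in seq_len(ncol(geno))) {
    cc <- geno[, j]
    if (all(is.na(cc))) next # all-missing column: dropped
    split_h <- strsplit(cc, "/", fixed = TRUE)
    alleles <- sort(unique(unlist(split_h[!is.na(cc)])), method = "radix")
    for (a in alleles) {
      d <- vapply(split_h, function(h)
        if (is.null(h) || anyNA(h)) NA_real_ else sum(h == a), numeric(1))
      d[is.na(cc)] <- NA_real_
      cols[[length(cols) + 1]] <- d
      nm[[length(nm) + 1]] <- paste0(colnames(geno)[j] %||% j, ":", a)
    }
  }
  if (!length(cols)) stop_data("no usable loci after dropping all-missing columns")
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(nm)
  keep <- apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && stats::var(x) > 0
  })
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) { # no variation at all: first component explains nothing
    out <- numeric(0)
    attr(out, "scores") <- matrix(0, nrow(geno), 0,
                                  dimnames = list(rownames(geno), NULL))
    return(out)
  }
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mu
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  out <- prop
  attr(out, "scores") <- pc$x[, seq_len(min(n_components, ncol(pc$x))),
                              drop = FALSE]
  out
}
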