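#' Pipeline configuration
#'
#' Exactly one input mode is used per run: a [sim_config()] (simulation
#' mode) or paths to real inputs (FASTQ + SAM + barcode TSV + raw trait
#' TSV). Stages run in order: simulate/ingest, demultiplex, count, call,
#' derive traits, association scan per campaign, report.
#'
#' @param simulation a [sim_config()], or `NULL` when real inputs are given.
#' @param fastq,sam,barcodes,raw_traits input paths (real-input mode).
#' @param caller [caller_params()].
#' @param gwas [gwas_params()] template; `min_genotypes` is taken per
#'   campaign from `min_genotypes_by_year`.
#' @param min_genotypes_by_year minimum called genotypes per campaign
#'   (defaults 100 and 50, matching campaigns of ~313 and ~116 genotypes).
#' @param out_dir output directory (created); `NULL` disables file output.
#' @param write_fixtures in simulation mode, also write FASTQ/SAM/barcode
#'   fixtures and re-ingest them through the read-processing stages instead
#'   of short-circuiting to the in-memory tag table.
#' @param seed global seed recorded in the manifest; defaults to the
#'   simulation seed.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, fastq = NULL, sam = NULL,
                            barcodes = NULL, raw_traits = NULL,
                            caller = caller_params(),
                            gwas = gwas_params(),
                            min_genotypes_by_year = c(100, 50),
                            out_dir = NULL, write_fixtures = FALSE,
                            seed = NULL) {
  sim_mode <- !is.null(simulation)
  real_mode <- !is.null(fastq) || !is.null(sam) || !is.null(raw_traits)
  if (sim_mode == real_mode)
    stop_data("exactly one of simulation or real inputs must be given")
  if (real_mode) {
    for (p in c(fastq, sam, barcodes, raw_traits))
      if (!file.exists(p)) stop_data("input path does not exist: %s", p)
  }
  cfg <- list(simulation = simulation, fastq = fastq, sam = sam,
              barcodes = barcodes, raw_traits = raw_traits,
              caller = caller, gwas = gwas,
              min_genotypes_by_year = min_genotypes_by_year,
              out_dir = out_dir, write_fixtures = isTRUE(write_fixtures),
              seed = seed %||% (if (sim_mode) simulation$seed else 1L))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage on simulated or real inputs and returns all stage
#' outputs together with a manifest (parameters, seed, package version,
#' input digests) that makes reruns comparable: the same configuration
#' reproduces identical outputs. A stage failure aborts with the failing
#' stage named; outputs of completed stages are retained in the error
#' condition's `partial` field.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `tag_counts`, `genotypes`,
#'   `traits`, `trait_summaries`, `gwas` (one result per campaign),
#'   `scaffolds` (collapsed significant scaffolds per campaign), `pca`,
#'   `truth` (simulation mode), `manifest` and `report` (text lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial <- out
      stop(cond)
    })
  }

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    truth <- stage("simulate", simulate_truth(sim))
    out$truth <- truth
    counts <- stage("simulate", simulate_tag_counts(truth, sim))
    if (config$write_fixtures && !is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      bc <- generate_barcodes(counts$samples,
                              seed = substream(sim$seed, 9L))
      fq <- file.path(config$out_dir, "run.fastq")
      samf <- file.path(config$out_dir, "tags.sam")
      bcf <- file.path(config$out_dir, "barcodes.tsv")
      stage("simulate", {
        write_run_fastq(counts, bc, fq, seed = substream(sim$seed, 10L))
        write_sam_tags(counts, samf)
        write.table(bc, bcf, sep = "\t", quote = FALSE, row.names = FALSE)
      })
      counts <- stage("ingest", {
        dmx <- demultiplex(fq, bc)
        trimmed <- lapply(dmx$reads, function(r)
          trim_reads(r, sim$tag_length)$reads)
        tab <- count_tags(trimmed, bc)
        ## attach alignments by joining tag sequences to the written SAM
        samrec <- read_sam_tags(samf)
        seqs <- counts$tags$seq[match(samrec$qname, counts$tags$tag_id)]
        i <- match(tab$tags$seq, seqs)
        tab$tags$flag <- samrec$flag[i]
        tab$tags$scaffold <- samrec$rname[i]
        tab$tags$pos <- samrec$pos[i]
        tab
      })
    }
    out$tag_counts <- counts
    raw <- stage("traits", simulate_traits(truth, sim))
  } else {
    bc <- stage("ingest", read_barcode_table(config$barcodes))
    dmx <- stage("demux", demultiplex(config$fastq, bc))
    trimmed <- stage("demux", lapply(dmx$reads, function(r)
      trim_reads(r)$reads))
    counts <- stage("count", count_tags(trimmed, bc))
    samrec <- stage("count", read_sam_tags(config$sam))
    out$tag_counts <- counts
    raw <- stage("traits", read.delim(config$raw_traits,
                                      stringsAsFactors = FALSE))
    out$sam_records <- samrec
  }

  geno <- stage("call", {
    if (!is.null(config$simulation)) call_genotypes(counts, config$caller)
    else call_genotypes(counts, config$caller, sam = out$sam_records)
  })
  out$genotypes <- geno

  traits <- stage("traits", derive_traits(raw))
  out$traits <- traits
  years <- sort(unique(traits$year))
  out$trait_summaries <- lapply(setNames(years, paste0("year", years)),
                                function(y) summarize_traits(traits, y))

  out$pca <- if (ncol(geno$calls)) stage("gwas", pca_check(geno)) else NULL

  out$gwas <- list(); out$scaffolds <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    gp <- config$gwas
    gp$min_genotypes <- as.integer(
      config$min_genotypes_by_year[min(i, length(config$min_genotypes_by_year))])
    res <- stage("gwas", run_gwas(geno, traits[traits$year == y, ,
                                               drop = FALSE], gp))
    out$gwas[[paste0("year", y)]] <- res
    out$scaffolds[[paste0("year", y)]] <-
      collapse_to_scaffolds(res, geno$locus_info)
  }

  out$manifest <- list(
    package = "tagwas",
    version = as.character(packageVersion("tagwas")),
    seed = config$seed,
    mode = if (is.null(config$simulation)) "real" else "simulation",
    caller = unclass(config$caller),
    gwas = unclass(config$gwas),
    min_genotypes_by_year = config$min_genotypes_by_year,
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation)[c("n_founders", "n_tag_loci",
                                   "seq_error_rate", "seed")],
    n_tags = nrow(out$tag_counts$tags),
    n_loci_called = ncol(geno$calls)
  )
  out$report <- write_report(out, path = if (!is.null(config$out_dir))
    file.path(config$out_dir, "report.txt"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(traits, file.path(config$out_dir, "traits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gm <- as.data.frame(geno$calls)
    gm[is.na(gm)] <- "."
    write.table(cbind(genotype = rownames(geno$calls), gm),
                file.path(config$out_dir, "genotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(out$gwas))
      write.table(out$gwas[[nm]]$records,
                  file.path(config$out_dir, paste0("gwas_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  class(out) <- "pipeline_result"
  out
}

#' Write the human-readable analysis report
#'
#' Emits a per-campaign trait summary table (min, max, median, IQR, n) and
#' a significant-association table (trait, scaffold label, LOD, genotype
#' classes with medians and post hoc letters), mirroring the layout used to
#' summarise anther-culture association studies.
#'
#' @param result a `pipeline_result` (or a list with `trait_summaries`,
#'   `gwas`, `scaffolds`).
#' @param path optional output file.
#' @return invisibly, the report lines.
#' @export
write_report <- function(result, path = NULL) {
  lines <- c("tagwas analysis report",
             strrep("=", 60))
  for (nm in names(result$trait_summaries)) {
    s <- result$trait_summaries[[nm]]
    lines <- c(lines, "", sprintf("Trait summary (%s)", nm),
               sprintf("%-18s %8s %8s %8s %8s %6s", "trait", "min", "max",
                       "median", "IQR", "n"),
               sprintf("%-18s %8.1f %8.1f %8.1f %8.1f %6d",
                       s$trait, s$min, s$max, s$median, s$iqr, s$n))
  }
  for (nm in names(result$gwas)) {
    res <- result$gwas[[nm]]
    col <- result$scaffolds[[nm]]
    sig <- res$records[res$records$significant, , drop = FALSE]
    lines <- c(lines, "", sprintf("Significant associations (%s): %d records, %d scaffolds",
                                  nm, nrow(sig), col$n_scaffolds))
    if (nrow(sig)) {
      lab <- setNames(col$labels$label, col$labels$locus)
      for (i in seq_len(nrow(sig))) {
        r <- sig[i, ]
        cl <- res$classes[res$classes$locus == r$locus &
                            res$classes$trait == r$trait, , drop = FALSE]
        cls_txt <- paste(sprintf("%s %.1f %s", cl$class, cl$median,
                                 ifelse(is.na(cl$letter), "", cl$letter)),
                         collapse = "  ")
        lines <- c(lines, sprintf("%-16s %-12s LOD %4.1f perm_p %.4g  %s",
                                  r$trait, lab[r$locus], r$lod, r$perm_p,
                                  cls_txt))
      }
    }
  }
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, path)
  }
  invisible(lines)
}
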