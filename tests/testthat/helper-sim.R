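# Shared fixtures: all test data are generated in code.

# A small, fast study: 4 pair-crosses (155 offspring), error-free reads at a
# fixed depth of 30 so that calls are essentially deterministic.
small_config <- function(n_tag_loci = 40, seed = 1L, ...) {
  args <- list(
    n_tag_loci = n_tag_loci,
    crosses = default_crosses()[1:4, ],
    years = list(n_year1 = 90, n_year2 = 45, n_overlap = 30),
    depth_model = list(mean = 30, dispersion = 2, fixed = TRUE),
    seq_error_rate = 0,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Loci where all founders are heterozygous A/B, so every cross segregates
# 1:2:1 -- convenient for planting QTL with known class sizes.
biallelic_config <- function(n_tag_loci = 30, seed = 1L, ...) {
  args <- list(
    n_tag_loci = n_tag_loci,
    crosses = data.frame(population = c("P01", "P02"),
                         mother = c(1, 3), father = c(2, 4),
                         n_offspring = c(150, 150)),
    alleles_per_locus_dist = c(0, 1, 0, 0),
    founder_heterozygosity = 1,
    years = list(n_year1 = 300, n_year2 = 50, n_overlap = 50),
    depth_model = list(mean = 30, dispersion = 2, fixed = TRUE),
    seq_error_rate = 0,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Tiny in-memory tag count table for caller unit tests. `spec` is a list of
# per-locus lists: list(flag, scaffold, pos, tags = named counts matrix
# (tag seq x sample)).
toy_tag_table <- function(spec, populations) {
  tags <- list(); counts <- list(); tid <- 0
  for (l in spec) {
    for (s in rownames(l$tags)) {
      tid <- tid + 1
      id <- sprintf("T%07d", tid)
      tags[[tid]] <- data.frame(tag_id = id, seq = s, flag = l$flag,
                                scaffold = l$scaffold, pos = l$pos,
                                stringsAsFactors = FALSE)
      for (smp in colnames(l$tags)) {
        if (l$tags[s, smp] > 0)
          counts[[length(counts) + 1]] <- data.frame(
            tag_id = id, sample = smp, count = l$tags[s, smp],
            stringsAsFactors = FALSE)
      }
    }
  }
  tag_count_table(
    tags = do.call(rbind, tags),
    counts = if (length(counts)) do.call(rbind, counts) else
      data.frame(tag_id = character(), sample = character(),
                 count = integer()),
    samples = populations
  )
}

sam_from_tags <- function(x) {
  tg <- x$tags
  data.frame(qname = tg$tag_id, flag = tg$flag, rname = tg$scaffold,
             pos = tg$pos, seq = tg$seq, stringsAsFactors = FALSE)
}

# Random 100 bp tag sequence pool with controlled differences
mutate_at <- function(s, pos1, base) {
  substr(s, pos1, pos1) <- base
  s
}
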