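#' Default pair-cross design
#'
#' Eleven pair-cross populations derived from nine heterozygous founders, with
#' per-cross offspring counts summing to 351 (the number of genotypes
#' phenotyped in at least one of the two anther-culture campaigns: 313 in the
#' first, 116 in the second, 78 in both). Per-cross sizes are a design choice
#' of the simulator; only the totals are constrained by the study design being
#' emulated.
#'
#' @param n_founders number of founder genotypes available.
#' @return a data.frame with columns `population`, `mother`, `father`,
#'   `n_offspring`.
#' @export
default_crosses <- function(n_founders = 9) {
  stopifnot(n_founders >= 9)
  data.frame(
    population = sprintf("P%02d", 1:11),
    mother = c(1, 1, 2, 4, 4, 5, 7, 7, 8, 1, 3),
    father = c(2, 3, 3, 5, 6, 6, 8, 9, 9, 5, 7),
    n_offspring = c(45, 40, 35, 35, 30, 30, 30, 28, 28, 25, 25)
  )
}

#' Default trait generative model parameters
#'
#' A hurdle model for the zero-inflated anther-culture response: a genotype
#' responds (produces at least one embryo-like structure, ELS) with a
#' logistic probability; conditional on response, ELS counts follow a
#' negative binomial, a fraction of ELS are transferred to regeneration
#' medium (ELS cultured, EC), and green/albino regenerant counts follow
#' negative binomials with EC-proportional means. Green-plant production has
#' its own hurdle, reflecting that most responsive genotypes regenerate no
#' green plants at all while a few produce several plants per cultured ELS.
#' QTL allele effects act additively on the logit of each hurdle and
#' multiplicatively (log scale) on the magnitudes.
#'
#' Defaults are calibrated so that, at the default population size, the
#' simulated trait marginals have the qualitative shape of the real
#' campaigns: response fraction around 0.6, median ELS per 100 anthers
#' cultured in the tens, median green plants per 100 EC equal to 0 with
#' maxima above 100, and albino regeneration common among responders.
#'
#' @param anthers_cultured anthers plated per genotype (fixed).
#' @param response_baseline baseline logit of the response (ELS > 0) hurdle.
#' @param ra_shape1,ra_shape2 Beta parameters for the per-genotype
#'   anther-response probability among responders.
#' @param els_log_mean,els_size log-mean and NB size of ELS counts among
#'   responders (one ELS is guaranteed for a responder).
#' @param ec_prob probability that an individual ELS is cultured on.
#' @param green_baseline baseline logit of the green-plant hurdle.
#' @param green_rate,green_size per-EC mean and NB size of green plant counts
#'   when the green hurdle is passed (one plant guaranteed).
#' @param albino_rate,albino_size per-EC mean and NB size of albino plant
#'   counts (no separate hurdle).
#' @param year_response_shift,year_els_shift additive year-2 shifts on the
#'   response logit and the ELS log-mean.
#' @return a named list of class `trait_model`.
#' @export
trait_model <- function(anthers_cultured = 120L,
                        response_baseline = 0.4,
                        ra_shape1 = 0.6, ra_shape2 = 2.4,
                        els_log_mean = log(55),
                        els_size = 0.6,
                        ec_prob = 0.5,
                        green_baseline = -0.85,
                        green_rate = 0.5, green_size = 0.5,
                        albino_rate = 0.3, albino_size = 0.5,
                        year_response_shift = 0.3,
                        year_els_shift = 0.5) {
  tm <- list(
    anthers_cultured = as.integer(anthers_cultured),
    response_baseline = response_baseline,
    ra_shape1 = ra_shape1, ra_shape2 = ra_shape2,
    els_log_mean = els_log_mean, els_size = els_size,
    ec_prob = ec_prob,
    green_baseline = green_baseline,
    green_rate = green_rate, green_size = green_size,
    albino_rate = albino_rate, albino_size = albino_size,
    year_response_shift = year_response_shift,
    year_els_shift = year_els_shift
  )
  stopifnot(tm$anthers_cultured >= 0, is_prob(tm$ec_prob))
  class(tm) <- "trait_model"
  tm
}

#' Simulation configuration for a multiparental GBS + trait study
#'
#' Defines the study conditions the simulator emulates: nine heterozygous
#' founders pair-crossed into eleven populations, around two thousand 100 bp
#' tag loci with up to four alleles each, roughly a quarter of polymorphic
#' tags carrying two or more SNPs, negative-binomial read depth with
#' per-base sequencing error, and heavily zero-inflated androgenic-capacity
#' traits scored in two partially overlapping yearly campaigns.
#'
#' @param n_founders number of founders (default 9).
#' @param crosses pair-cross design, see [default_crosses()].
#' @param n_tag_loci number of 100 bp tag loci.
#' @param alleles_per_locus_dist probability vector over 1..4 for the number
#'   of distinct tag alleles segregating among the founders at a locus.
#' @param founder_heterozygosity probability that a founder is heterozygous
#'   at a polymorphic locus.
#' @param snps_per_tag_dist probability vector over 1..4 for the number of
#'   polymorphic sites (Isites) within a polymorphic tag.
#' @param depth_model list with `mean`, `dispersion` (negative-binomial size;
#'   `Inf` for Poisson) and `fixed` (logical; `TRUE` makes depth exactly
#'   `mean` everywhere).
#' @param seq_error_rate per-base substitution error probability.
#' @param tag_length tag length in bp (100 for the emulated protocol).
#' @param scaffold_sharing fraction of loci placed on a scaffold that already
#'   carries another locus (so that scaffold collapsing is exercised).
#' @param qtl_spec `NULL` or a data.frame with columns `locus` (index or
#'   locus id), `allele` (beneficial allele index), `beta_response`,
#'   `beta_els`, `beta_green`, `beta_albino` (per-allele-copy effects).
#' @param trait_model see [trait_model()].
#' @param years list with `n_year1`, `n_year2`, `n_overlap` genotype counts.
#' @param seed integer; fully determines every simulator output.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 9,
                       crosses = default_crosses(max(n_founders, 9)),
                       n_tag_loci = 2000,
                       alleles_per_locus_dist = c(0.45, 0.40, 0.10, 0.05),
                       founder_heterozygosity = 0.45,
                       snps_per_tag_dist = c(0.75, 0.17, 0.05, 0.03),
                       depth_model = list(mean = 20, dispersion = 2,
                                          fixed = FALSE),
                       seq_error_rate = 0.001,
                       tag_length = 100L,
                       scaffold_sharing = 0.05,
                       qtl_spec = NULL,
                       trait_model = tagwas::trait_model(),
                       years = list(n_year1 = 313, n_year2 = 116,
                                    n_overlap = 78),
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    crosses = crosses,
    n_tag_loci = as.integer(n_tag_loci),
    alleles_per_locus_dist = alleles_per_locus_dist,
    founder_heterozygosity = founder_heterozygosity,
    snps_per_tag_dist = snps_per_tag_dist,
    depth_model = depth_model,
    seq_error_rate = seq_error_rate,
    tag_length = as.integer(tag_length),
    scaffold_sharing = scaffold_sharing,
    qtl_spec = qtl_spec,
    trait_model = trait_model,
    years = years,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_founders < 1) stop_data("n_founders must be positive")
  dist_ok <- function(p) {
    is.numeric(p) && length(p) >= 1 && length(p) <= 4 && all(p >= 0) &&
      sum(p) > 0
  }
  if (!dist_ok(cfg$alleles_per_locus_dist))
    stop_data("alleles_per_locus_dist must be a probability vector over 1..4")
  if (!dist_ok(cfg$snps_per_tag_dist))
    stop_data("snps_per_tag_dist must be a probability vector over 1..4")
  if (!is_prob(cfg$founder_heterozygosity))
    stop_data("founder_heterozygosity must be a probability")
  if (!is_prob(cfg$seq_error_rate))
    stop_data("seq_error_rate must be a probability")
  if (!is_prob(cfg$scaffold_sharing))
    stop_data("scaffold_sharing must be a probability")
  cr <- cfg$crosses
  need <- c("population", "mother", "father", "n_offspring")
  if (!all(need %in% names(cr)))
    stop_data("crosses must have columns %s", paste(need, collapse = ", "))
  if (nrow(cr) > 0 && (any(cr$mother > cfg$n_founders) ||
                       any(cr$father > cfg$n_founders) ||
                       any(cr$mother < 1) || any(cr$father < 1)))
    stop_data("crosses reference founders outside 1..n_founders")
  dm <- cfg$depth_model
  if (!is.numeric(dm$mean) || dm$mean < 0)
    stop_data("depth_model$mean must be nonnegative")
  yr <- cfg$years
  n_off <- sum(cr$n_offspring)
  if (yr$n_overlap > min(yr$n_year1, yr$n_year2))
    stop_data("year overlap larger than a campaign")
  if (yr$n_year1 + yr$n_year2 - yr$n_overlap > n_off)
    stop_data("campaign sizes exceed the total number of offspring (%d)",
              n_off)
  if (!is.null(cfg$qtl_spec)) {
    qs <- cfg$qtl_spec
    needq <- c("locus", "allele")
    if (!all(needq %in% names(qs)))
      stop_data("qtl_spec must have columns locus and allele")
    bad <- setdiff(names(qs), c("locus", "allele", "beta_response",
                                "beta_els", "beta_green", "beta_albino"))
    if (length(bad))
      stop_data("unknown qtl_spec columns (unknown trait effect?): %s",
                paste(bad, collapse = ", "))
  }
  invisible(cfg)
}
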