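## Hurdle / negative-binomial simulation of anther-culture response counts.

## Sum of planted QTL effects (per allele copy) for each individual.
qtl_effect <- function(truth, samples, column) {
  eff <- numeric(length(samples))
  qtl <- truth$qtl
  if (is.null(qtl) || !column %in% names(qtl)) return(eff)
  idx <- match(samples, truth$offspring$ids)
  for (q in seq_len(nrow(qtl))) {
    li <- qtl$locus_idx[q]
    dosage <- (truth$offspring$h1[idx, li] == qtl$allele[q]) +
      (truth$offspring$h2[idx, li] == qtl$allele[q])
    eff <- eff + qtl[[column]][q] * dosage
  }
  eff
}

#' Simulate raw anther-culture counts for both campaigns
#'
#' Implements the hurdle model described in [trait_model()]: a genotype
#' responds with logistic probability (baseline + planted QTL response
#' effects + year shift); conditional on response, embryo-like structure
#' (ELS), cultured-ELS, green-plant and albino-plant counts are drawn from
#' negative binomial magnitudes whose log-means include the planted QTL
#' effects and a year effect. Non-responders score zero everywhere. The
#' output is deterministic given the configuration seed.
#'
#' @param truth a [simulate_truth()] result (QTL positions and campaign
#'   membership are taken from it).
#' @param config the [sim_config()] used to build `truth`.
#' @return a data.frame of raw culture counts, one row per genotype and
#'   campaign year, with columns `genotype`, `year`, `anthers_cultured`,
#'   `responding_anthers`, `els_produced`, `els_cultured`, `plants_green`,
#'   `plants_albino`.
#' @export
simulate_traits <- function(truth, config = truth$config) {
  set.seed(substream(config$seed, 4L))
  tm <- config$trait_model
  out <- vector("list", 2)
  for (year in 1:2) {
    ids <- truth$years[[year]]
    n <- length(ids)
    if (n == 0) next
    resp_shift <- if (year == 2) tm$year_response_shift else 0
    els_shift <- if (year == 2) tm$year_els_shift else 0

    eta_resp <- tm$response_baseline + resp_shift +
      qtl_effect(truth, ids, "beta_response")
    responds <- runif(n) < plogis(eta_resp)

    ac <- rep(tm$anthers_cultured, n)
    ra <- els <- ec <- gp <- ap <- integer(n)

    r <- which(responds)
    if (length(r)) {
      els_mu <- exp(tm$els_log_mean + els_shift +
                      qtl_effect(truth, ids, "beta_els")[r])
      els[r] <- 1L + rnbinom(length(r), mu = els_mu, size = tm$els_size)
      ra_p <- rbeta(length(r), tm$ra_shape1, tm$ra_shape2)
      ra[r] <- pmax(1L, rbinom(length(r), ac[r], ra_p))
      ec[r] <- rbinom(length(r), els[r], tm$ec_prob)

      has_ec <- r[ec[r] > 0]
      if (length(has_ec)) {
        g_eff <- qtl_effect(truth, ids, "beta_green")[has_ec]
        green_on <- runif(length(has_ec)) <
          plogis(tm$green_baseline + g_eff)
        g_on <- has_ec[green_on]
        if (length(g_on)) {
          gp[g_on] <- 1L + rnbinom(
            length(g_on),
            mu = ec[g_on] * tm$green_rate *
              exp(qtl_effect(truth, ids, "beta_green")[g_on]),
            size = tm$green_size)
        }
        a_eff <- qtl_effect(truth, ids, "beta_albino")[has_ec]
        ap[has_ec] <- rnbinom(
          length(has_ec),
          mu = ec[has_ec] * tm$albino_rate * exp(a_eff),
          size = tm$albino_size)
      }
    }
    out[[year]] <- data.frame(
      genotype = ids, year = year,
      anthers_cultured = ac, responding_anthers = ra,
      els_produced = els, els_cultured = ec,
      plants_green = gp, plants_albino = ap,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
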