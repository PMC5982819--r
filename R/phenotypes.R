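TRAIT_COLUMNS <- c("RA_pct", "ELS_per_100AC", "plants_per_100AC",
                   "plants_per_100EC", "GP_per_100AC", "GP_per_100EC",
                   "AP_per_100AC", "AP_per_100EC")

#' Derive the eight androgenic-capacity traits from raw culture counts
#'
#' Trait definitions: anther response as the percentage of cultured anthers
#' producing macroscopic embryo-like structures (ELS); embryo production as
#' ELS per 100 anthers cultured (AC); total plant, green plant and albino
#' plant production per 100 AC; and total plant, green plant and albino
#' plant regeneration per 100 ELS cultured (EC). Total plants are green +
#' albino. A trait whose denominator is zero is missing, not zero -- this is
#' what makes the per-trait n differ in summary tables. Values above 100 are
#' legal (several plants can regenerate from one cultured ELS).
#'
#' @param raw data.frame with columns `genotype`, `year`,
#'   `anthers_cultured`, `responding_anthers`, `els_produced`,
#'   `els_cultured`, `plants_green`, `plants_albino`.
#' @return data.frame with `genotype`, `year` and the eight trait columns.
#' @export
derive_traits <- function(raw) {
  need <- c("genotype", "year", "anthers_cultured", "responding_anthers",
            "els_produced", "els_cultured", "plants_green", "plants_albino")
  if (!all(need %in% names(raw)))
    stop_data("raw counts need columns %s", paste(need, collapse = ", "))
  cnt <- c("anthers_cultured", "responding_anthers", "els_produced",
           "els_cultured", "plants_green", "plants_albino")
  for (cc in cnt) {
    bad <- which(is.na(raw[[cc]]) | raw[[cc]] < 0)
    if (length(bad))
      stop_data("negative or missing %s for genotype %s", cc,
                raw$genotype[bad[1]])
  }
  bad <- which(raw$responding_anthers > raw$anthers_cultured)
  if (length(bad))
    stop_data("responding_anthers > anthers_cultured for genotype %s",
              raw$genotype[bad[1]])
  bad <- which(raw$els_cultured > raw$els_produced)
  if (length(bad))
    stop_data("els_cultured > els_produced for genotype %s",
              raw$genotype[bad[1]])

  ac <- ifelse(raw$anthers_cultured > 0, raw$anthers_cultured, NA_real_)
  ec <- ifelse(raw$els_cultured > 0, raw$els_cultured, NA_real_)
  plants <- raw$plants_green + raw$plants_albino
  data.frame(
    genotype = raw$genotype, year = raw$year,
    RA_pct = 100 * raw$responding_anthers / ac,
    ELS_per_100AC = 100 * raw$els_produced / ac,
    plants_per_100AC = 100 * plants / ac,
    plants_per_100EC = 100 * plants / ec,
    GP_per_100AC = 100 * raw$plants_green / ac,
    GP_per_100EC = 100 * raw$plants_green / ec,
    AP_per_100AC = 100 * raw$plants_albino / ac,
    AP_per_100EC = 100 * raw$plants_albino / ec,
    stringsAsFactors = FALSE
  )
}

#' Summarize traits (min, max, median, interquartile range, n)
#'
#' Statistics are computed over non-missing values only; `n` is the count of
#' genotypes with a defined value, so denominators of zero shrink `n` for
#' the per-EC traits.
#'
#' @param traits a [derive_traits()] table.
#' @param year optional campaign year to restrict to.
#' @param quantile_type quantile convention for the IQR (default 7, linear
#'   interpolation between order statistics).
#' @return data.frame with one row per trait: `trait`, `min`, `max`,
#'   `median`, `iqr`, `n`.
#' @export
summarize_traits <- function(traits, year = NULL, quantile_type = 7) {
  if (!is.null(year)) traits <- traits[traits$year %in% year, , drop = FALSE]
  rows <- lapply(TRAIT_COLUMNS, function(tr) {
    v <- traits[[tr]]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(trait = tr, min = NA_real_, max = NA_real_,
                        median = NA_real_, iqr = NA_real_, n = 0L))
    q <- quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
    data.frame(trait = tr, min = min(v), max = max(v),
               median = median(v), iqr = q[2] - q[1], n = length(v))
  })
  do.call(rbind, rows)
}
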