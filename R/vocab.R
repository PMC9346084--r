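# Declared factor vocabularies for survival tables.  Levels outside these
# sets are schema errors at read time, never silently coerced.

survival_vocab <- function() {
  list(
    experiment         = c("additive", "parental", "juvenile", "microbiome"),
    regime             = c("T_SFB", "T_VCH"),
    population         = c("SFB84", "VCH97", "VCH08"),
    cross_status       = c("own", "crossed"),
    clutch             = c("1", "2"),                  # NA allowed
    parental_treatment = c("control", "mother", "father"), # NA allowed
    phase1_regime      = c("T_SFB", "T_VCH"),          # NA allowed
    microbiome         = c("SFB", "VCH", "LAB")        # NA allowed
  )
}

survival_columns <- function() {
  c("experiment", "regime", "population", "cross_status", "clutch",
    "parental_treatment", "phase1_regime", "microbiome", "family_id",
    "tube_id", "n_total", "n_alive")
}

# Factors where NA is a legal level (factor not manipulated in that experiment)
na_ok_factors <- function() {
  c("clutch", "parental_treatment", "phase1_regime", "microbiome", "family_id")
}

#' Reference-genome regions excluded from mitochondrial SNP calling
#'
#' Three regions of the mitochondrial reference show a systematic drop in
#' mapping coverage and are excluded from variant calling by default.
#' Intervals are 1-based inclusive.
#'
#' @return A data frame with columns `start` and `end`.
#' @export
study_excluded_regions <- function() {
  data.frame(start = c(14045L, 14682L, 15409L),
             end   = c(14394L, 14835L, 15806L))
}

#' Daily temperature cycles of the two thermal regimes
#'
#' The two regimes are categorical labels throughout the analyses; the
#' hour-by-hour profiles are recorded here for documentation only and never
#' enter any computation. Temperatures in degrees Celsius, durations in hours.
#'
#' @return A named list of data frames, one per regime.
#' @export
regime_temperature_cycles <- function() {
  list(
    T_SFB = data.frame(temp_c = c(16, 22, 27, 22, 16),
                       hours  = c(2, 8, 4, 8, 2)),
    T_VCH = data.frame(temp_c = c(26, 32, 35, 32, 26),
                       hours  = c(2, 8, 4, 8, 2))
  )
}
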