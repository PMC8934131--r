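# Sitting-time exposure: three sedentary-behaviour categories per sex x age band.

#' Sedentary-behaviour category definitions
#'
#' The three daily-sitting-time categories: low (< 4 h), moderate (4-8 h) and
#' high (> 8 h).  Bounds are half-open `[lower, upper)` minutes/day, so
#' 240 min maps to moderate and 480 min to high; the top category is closed at
#' 1440 (a full day).
#'
#' @return data.frame with columns `name`, `lower`, `upper` (minutes/day).
#' @export
sb_categories <- function() {
  data.frame(
    name = SB_LEVELS,
    lower = c(0, 240, 480),
    upper = c(240, 480, 1440)
  )
}

#' Classify minutes/day of sitting into an exposure category
#'
#' @param minutes numeric vector, 0 <= minutes <= 1440.
#' @return character vector in `c("low", "moderate", "high")`.
#' @examples
#' category_of(c(239, 240, 600))
#' @export
category_of <- function(minutes) {
  if (any(!is.finite(minutes)) || any(minutes < 0) || any(minutes > 1440)) {
    abort_domain("minutes/day must lie in [0, 1440]")
  }
  out <- character(length(minutes))
  out[minutes < 240] <- "low"
  out[minutes >= 240 & minutes < 480] <- "moderate"
  out[minutes >= 480] <- "high"
  out
}

# internal: validate (and renormalise) a long-format exposure data.frame
validate_exposure_table <- function(df, complete = TRUE) {
  require_columns(df, c("sex", "age_band", "category", "proportion",
                        "proportion_se", "mean_minutes", "mean_se"),
                  "exposure table")
  df$sex <- as.character(df$sex)
  df$age_band <- as.character(df$age_band)
  df$category <- as.character(df$category)
  if (!all(df$category %in% SB_LEVELS)) {
    abort_validation("exposure categories must be low/moderate/high")
  }
  if (complete) {
    want <- expand.grid(sex = SEXES, age_band = AGE_BANDS, category = SB_LEVELS,
                        stringsAsFactors = FALSE)
    have <- paste(df$sex, df$age_band, df$category)
    missing <- setdiff(paste(want$sex, want$age_band, want$category), have)
    if (length(missing)) {
      abort_validation(sprintf("exposure table missing stratum/category cells: %s",
                               paste(missing, collapse = "; ")))
    }
  }
  if (any(df$proportion < 0 | df$proportion > 1)) {
    abort_validation("exposure proportions must lie in [0, 1]")
  }
  if (any(df$proportion_se < 0) || any(df$mean_se < 0)) {
    abort_validation("exposure standard errors must be >= 0")
  }
  key <- paste(df$sex, df$age_band)
  for (k in unique(key)) {
    idx <- which(key == k)
    sl <- df[idx, ]
    sl <- sl[match(SB_LEVELS, sl$category), ]
    tot <- sum(sl$proportion)
    if (tot < 0.98 || tot > 1.02) {
      abort_validation(sprintf(
        "stratum %s: category proportions sum to %.4f (outside [0.98, 1.02])",
        k, tot))
    }
    df$proportion[idx] <- df$proportion[idx] / tot
    if (!(sl$mean_minutes[1] < sl$mean_minutes[2] &&
          sl$mean_minutes[2] < sl$mean_minutes[3])) {
      abort_validation(sprintf(
        "stratum %s: category means must be strictly increasing low < moderate < high", k))
    }
  }
  # canonical ordering: sex, band, category
  df <- df[order(match(df$sex, SEXES), match(df$age_band, AGE_BANDS),
                 match(df$category, SB_LEVELS)), ]
  rownames(df) <- NULL
  class(df) <- c("exposure_table", "data.frame")
  df
}

#' Load a sitting-time exposure table from CSV
#'
#' Expects one row per sex x age band x category with columns
#' `sex, age_band, category, proportion, proportion_se, mean_minutes, mean_se`.
#' Proportions within each stratum are renormalised to sum to 1 when their raw
#' sum lies in `[0.98, 1.02]` (printed survey tables round to 4 digits);
#' anything further off is a validation error naming the stratum.
#'
#' The packaged fixture with the national survey estimates is available at
#' `system.file("extdata", "table2_exposure.csv", package = "sedlift")`.
#'
#' @param path CSV file path.
#' @param complete require the full 2 sexes x 7 bands grid (default TRUE).
#' @return an `exposure_table` (data.frame subclass).
#' @export
load_exposure_table <- function(path, complete = TRUE) {
  if (!file.exists(path)) abort_validation(sprintf("exposure file not found: %s", path))
  validate_exposure_table(read.csv(path, stringsAsFactors = FALSE), complete = complete)
}

#' Built-in national survey exposure fixture
#' @return the packaged exposure table.
#' @export
default_exposure_table <- function() {
  load_exposure_table(system.file("extdata", "table2_exposure.csv",
                                  package = "sedlift"))
}

#' Extract one stratum (3 category rows) from an exposure table
#' @param table an `exposure_table`.
#' @param sex `"female"` or `"male"`.
#' @param age_band one of the seven band labels.
#' @return 3-row data.frame ordered low, moderate, high.
#' @export
exposure_stratum <- function(table, sex, age_band) {
  sl <- table[table$sex == sex & table$age_band == age_band, ]
  if (nrow(sl) != 3) {
    abort_validation(sprintf("stratum %s %s not present (found %d rows)",
                             sex, age_band, nrow(sl)))
  }
  sl <- sl[match(SB_LEVELS, sl$category), ]
  rownames(sl) <- NULL
  sl
}

#' Population-weighted mean sitting time of a stratum
#' @param stratum 3-row stratum slice (see [exposure_stratum()]).
#' @return minutes/day.
#' @export
stratum_mean <- function(stratum) {
  sum(stratum$proportion * stratum$mean_minutes)
}

#' Move a fraction of one category's population to another category
#'
#' In every stratum, `fraction` of the `from_cat` proportion is moved to
#' `to_cat`.  Category mean sitting times are left unchanged: movers adopt the
#' destination category's existing mean.  Total probability mass is conserved
#' exactly.
#'
#' @param table an `exposure_table`.
#' @param from_cat,to_cat distinct category names.
#' @param fraction fraction in `[0, 1]` of the `from_cat` proportion to move.
#' @return the shifted `exposure_table`.
#' @export
apply_prevalence_shift <- function(table, from_cat, to_cat, fraction) {
  if (!from_cat %in% SB_LEVELS || !to_cat %in% SB_LEVELS || from_cat == to_cat) {
    abort_domain("from_cat and to_cat must be distinct sitting-time categories")
  }
  if (fraction < 0 || fraction > 1) abort_domain("fraction must lie in [0, 1]")
  key <- paste(table$sex, table$age_band)
  for (k in unique(key)) {
    i_from <- which(key == k & table$category == from_cat)
    i_to <- which(key == k & table$category == to_cat)
    moved <- fraction * table$proportion[i_from]
    table$proportion[i_from] <- table$proportion[i_from] - moved
    table$proportion[i_to] <- table$proportion[i_to] + moved
  }
  table
}

#' Reduce mean sitting time within selected categories
#'
#' Subtracts `minutes` from the mean sitting time of every targeted category in
#' every stratum, flooring at the category lower bound.  Proportions are
#' unchanged; downstream impact is computed with the relative-risk shift, not
#' by re-binning individuals.
#'
#' @param table an `exposure_table`.
#' @param minutes minutes/day to remove (>= 0).
#' @param categories categories targeted (default moderate and high).
#' @return the modified `exposure_table`.
#' @export
apply_sitting_reduction <- function(table, minutes,
                                    categories = c("moderate", "high")) {
  if (minutes < 0) abort_domain("minutes must be >= 0")
  cats <- sb_categories()
  for (cat in categories) {
    lo <- cats$lower[cats$name == cat]
    idx <- table$category == cat
    table$mean_minutes[idx] <- pmax(table$mean_minutes[idx] - minutes, lo)
  }
  table
}
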