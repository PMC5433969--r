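# Morphometric strandings records: schema, validation, auto-assignment of
# age class (from length) and season (from stranding month), CSV round trip.

MORPH_COLUMNS <- c("id", "sex", "date", "cod_class", "age_class", "season",
                   "mass_kg", "length_cm", "girth_cm",
                   "blubber_dorsal_mm", "blubber_lateral_mm",
                   "blubber_ventral_mm")

#' Classification cutoffs for age class and season
#'
#' Adults are animals at or above the male length at sexual maturity
#' (135 cm); calves are at or below 90 cm; everything between is a
#' juvenile. The breeding season covers the calving/mating months
#' June-August; the rest of the year is "nonbreeding".
#'
#' @param adult_min_cm Minimum adult length (cm).
#' @param calf_max_cm Maximum calf length (cm).
#' @param breeding_months Integer months making up the breeding season.
#' @return A list of cutoffs used by [assign_age_class()], [assign_season()]
#'   and [read_morphometrics()].
#' @export
morph_cutoffs <- function(adult_min_cm = 135, calf_max_cm = 90,
                          breeding_months = 6:8) {
  stopifnot(calf_max_cm < adult_min_cm,
            all(breeding_months %in% 1:12))
  list(adult_min_cm = adult_min_cm, calf_max_cm = calf_max_cm,
       breeding_months = as.integer(breeding_months))
}

#' Assign age class from body length
#'
#' @param length_cm Numeric vector of body lengths (cm).
#' @param cutoffs See [morph_cutoffs()].
#' @return Character vector in `{"calf", "juvenile", "adult"}`.
#' @export
assign_age_class <- function(length_cm, cutoffs = morph_cutoffs()) {
  ifelse(length_cm >= cutoffs$adult_min_cm, "adult",
         ifelse(length_cm <= cutoffs$calf_max_cm, "calf", "juvenile"))
}

#' Assign season from stranding date
#'
#' @param date A `Date` vector.
#' @param cutoffs See [morph_cutoffs()].
#' @return Character vector in `{"breeding", "nonbreeding"}`.
#' @export
assign_season <- function(date, cutoffs = morph_cutoffs()) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m %in% cutoffs$breeding_months, "breeding", "nonbreeding")
}

#' Validate a morphometric record table
#'
#' Checks column presence, positivity of mass/length/girth, non-negative
#' blubber thicknesses, level sets of the categorical fields, and (when
#' `check_consistency`) agreement of `age_class` and `season` with the
#' configured cutoffs.
#'
#' @param records Data frame with the columns of a morphometrics CSV.
#' @param cutoffs See [morph_cutoffs()].
#' @param check_consistency Verify auto-assignable labels against cutoffs.
#' @return `records`, invisibly; errors of class `cetacond_schema_error`
#'   on violation.
#' @export
validate_morphometrics <- function(records, cutoffs = morph_cutoffs(),
                                   check_consistency = TRUE) {
  missing_cols <- setdiff(MORPH_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    cc_stop(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
            "cetacond_schema_error")
  for (col in c("mass_kg", "length_cm", "girth_cm")) {
    bad <- !is.na(records[[col]]) & records[[col]] <= 0
    if (any(bad))
      cc_stop(paste0(col, " must be positive (rows ",
                     paste(utils::head(which(bad), 5), collapse = ","), ")"),
              "cetacond_schema_error")
  }
  for (col in grep("^blubber_", MORPH_COLUMNS, value = TRUE)) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(bad))
      cc_stop(paste0(col, " must be non-negative"), "cetacond_schema_error")
  }
  chk_levels <- list(sex = c("male", "female"),
                     cod_class = c("acute", "chronic"),
                     age_class = c("calf", "juvenile", "adult"),
                     season = c("breeding", "nonbreeding"))
  for (col in names(chk_levels)) {
    v <- records[[col]]
    bad <- !is.na(v) & !(v %in% chk_levels[[col]])
    if (any(bad))
      cc_stop(paste0("invalid ", col, " value(s): ",
                     paste(unique(v[bad]), collapse = ", ")),
              "cetacond_schema_error")
  }
  if (check_consistency) {
    auto <- assign_age_class(records$length_cm, cutoffs)
    bad <- !is.na(records$age_class) & !is.na(records$length_cm) &
      records$age_class != auto
    if (any(bad))
      cc_stop(paste0("age_class inconsistent with length cutoffs in ",
                     sum(bad), " row(s)"), "cetacond_schema_error")
  }
  invisible(records)
}

#' Read a morphometrics CSV
#'
#' Expects the exact header
#' `id,sex,date,cod_class,age_class,season,mass_kg,length_cm,girth_cm,`
#' `blubber_dorsal_mm,blubber_lateral_mm,blubber_ventral_mm` with ISO-8601
#' dates. Blank `age_class`/`season` entries are auto-assigned from the
#' cutoffs; rows whose date fails to parse while `season` is blank are
#' rejected (dropped with a warning), since the season cannot be recovered.
#'
#' @param path CSV file path.
#' @param cutoffs See [morph_cutoffs()].
#' @return A validated data frame of morphometric records. The number of
#'   rejected rows is attached as attribute `"n_rejected"`.
#' @export
read_morphometrics <- function(path, cutoffs = morph_cutoffs()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), MORPH_COLUMNS))
    cc_stop(paste0("unexpected columns.\n  expected: ",
                   paste(MORPH_COLUMNS, collapse = ","), "\n  found:    ",
                   paste(names(raw), collapse = ",")),
            "cetacond_schema_error")
  for (col in c("mass_kg", "length_cm", "girth_cm",
                "blubber_dorsal_mm", "blubber_lateral_mm",
                "blubber_ventral_mm"))
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  for (col in c("sex", "cod_class", "age_class", "season"))
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA_character_
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- is.na(date) & is.na(raw$season)
  if (any(bad_date)) {
    cc_warn(paste0(sum(bad_date), " row(s) rejected: unparseable date with ",
                   "no season label"), "cetacond_row_rejected")
    raw <- raw[!bad_date, , drop = FALSE]
    date <- date[!bad_date]
  }
  raw$date <- date
  fill <- is.na(raw$age_class)
  raw$age_class[fill] <- assign_age_class(raw$length_cm[fill], cutoffs)
  fill <- is.na(raw$season)
  raw$season[fill] <- assign_season(raw$date[fill], cutoffs)
  out <- validate_morphometrics(raw, cutoffs)
  attr(out, "n_rejected") <- sum(bad_date)
  out
}

#' Write a morphometrics CSV
#'
#' @param records Morphometric record table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morphometrics <- function(records, path) {
  out <- records[, MORPH_COLUMNS]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
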