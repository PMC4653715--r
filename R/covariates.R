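#' Fixed feeding-category label sets
#'
#' Six feeding preferences and seven feeding modes, the groupings used for
#' Lake Tanganyika cichlids.
#' @name feeding_levels
#' @export
FEEDING_PREFERENCES <- c("microinvertebrates/algae", "zooplankton",
                         "benthic invertebrates", "piscivore", "scales",
                         "generalist")

#' @rdname feeding_levels
#' @export
FEEDING_MODES <- c("ram", "sandpicking", "rockpicking", "scales",
                   "algaepicking", "suction", "benthic invertebrate picking")

.cov_numeric <- c("d13C", "d15N", "grnDa", "grnVa", "mean_rl", "GLTL", "ER")

#' Read a species-level covariate table
#'
#' Reads a CSV keyed by `species_code` with the seven ecological covariates
#' (stable isotopes d13C and d15N in per mil, gill-raker counts `grnDa` and
#' `grnVa`, mean gill-raker length `mean_rl` in mm, standardised gut length
#' `GLTL`, elongation ratio `ER`) and the categorical `feeding_preference`
#' (6 levels) and `feeding_mode` (7 levels) columns.
#'
#' Missing cells are kept as `NA` and flagged in the `"missing"` attribute;
#' species with a missing value for some variable are excluded pairwise by
#' the downstream analysis that uses that variable, never dropped here.
#'
#' @param path CSV path with a header row.
#' @return A data frame of class `covariate_table` keyed by `species_code`,
#'   with factor feeding columns at the fixed level sets.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  covariate_table(df)
}

#' Construct and validate a covariate table
#'
#' @param df Data frame with a `species_code` column; see [read_covariates()].
#' @return Validated `covariate_table`.
#' @export
covariate_table <- function(df) {
  if (!"species_code" %in% names(df)) stop("missing species_code column")
  if (anyDuplicated(df$species_code))
    stop("duplicate species_code rows")
  for (cl in intersect(.cov_numeric, names(df))) {
    raw <- df[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(v))
    if (length(bad))
      stop("non-numeric value in column ", cl, ": '", raw[bad[1L]], "'")
    v[!is.na(raw) & raw == ""] <- NA_real_
    df[[cl]] <- v
  }
  chk_range <- function(cl, ok, what) {
    v <- df[[cl]]
    if (!is.null(v) && any(!is.na(v) & !ok(v)))
      stop("column ", cl, " violates ", what)
  }
  chk_range("ER",   function(v) v > 0,  "ER > 0")
  chk_range("GLTL", function(v) v > 0,  "GLTL > 0")
  chk_range("grnDa", function(v) v >= 0, "count >= 0")
  chk_range("grnVa", function(v) v >= 0, "count >= 0")
  chk_cat <- function(cl, levels) {
    v <- df[[cl]]
    if (is.null(v)) return()
    v <- as.character(v)
    v[v == ""] <- NA_character_
    bad <- setdiff(unique(v[!is.na(v)]), levels)
    if (length(bad))
      stop("unknown ", cl, " label: '", bad[1L], "'")
    df[[cl]] <<- factor(v, levels = levels)
  }
  chk_cat("feeding_preference", FEEDING_PREFERENCES)
  chk_cat("feeding_mode", FEEDING_MODES)
  miss <- which(is.na(df[setdiff(names(df), "species_code")]), arr.ind = TRUE)
  attr(df, "missing") <- miss
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Write a covariate table to CSV
#'
#' @param tab A `covariate_table` (or plain data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}
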