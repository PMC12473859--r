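#' Body-composition column dictionary
#'
#' The documented column set for bioimpedance (InBody-style) indicator
#' tables: one row per participant, demographics plus 21 indicators.
#' Masses are kg, water volumes litres, PBF and TBW_FFM percent, BMI and
#' SMI kg/m^2, ECW_TBW a dimensionless ratio, VFA cm^2, BMR kcal. The
#' `control` columns (BFM_control, FFM_control) are recommended-change
#' quantities and may legitimately be negative.
#'
#' @return data.frame with columns `column`, `unit`, `kind`
#'   (`demographic`, `water`, `muscle`, `fat`, `ratio`, `control`,
#'   `other`) and `required`.
#' @export
bodyCompColumns <- function() .BODY_DICT

.BODY_DICT <- local({
  d <- function(column, unit, kind, required = FALSE)
    data.frame(column = column, unit = unit, kind = kind,
               required = required, stringsAsFactors = FALSE)
  rbind(
    d("participant_id", "", "demographic", TRUE),
    d("sex", "male/female", "demographic", TRUE),
    d("age", "years", "demographic", TRUE),
    d("height", "cm", "demographic", TRUE),
    d("weight", "kg", "demographic", TRUE),
    d("ICW", "L", "water"), d("ECW", "L", "water"), d("TBW", "L", "water"),
    d("PM", "kg", "muscle"), d("MM", "kg", "other"),
    d("FAT", "kg", "fat"), d("SLM", "kg", "muscle"),
    d("FFM", "kg", "muscle"), d("SMM", "kg", "muscle"),
    d("DLM", "kg", "muscle"), d("PBF", "%", "fat"),
    d("BMI", "kg/m2", "other"), d("ECW_TBW", "ratio", "ratio"),
    d("BFM_control", "kg", "control"), d("FFM_control", "kg", "control"),
    d("BCM", "kg", "muscle"), d("BMC", "kg", "other"),
    d("VFA", "cm2", "fat"), d("BMR", "kcal", "other"),
    d("TBW_FFM", "%", "ratio"), d("SMI", "kg/m2", "muscle"))
})

.BODY_ALIASES <- c("ECW/TBW" = "ECW_TBW", "TBW/FFM" = "TBW_FFM",
                   "DLMM" = "DLM", "BFM Control" = "BFM_control",
                   "FFM Control" = "FFM_control", "BFM" = "FAT",
                   "id" = "participant_id", "gender" = "sex")

#' Read a body-composition indicator table
#'
#' Reads a CSV with the columns of [bodyCompColumns()] (common aliases
#' such as `ECW/TBW` or `BFM Control` are renamed on read; unknown extra
#' columns are carried through untouched), coerces indicator columns to
#' numeric, and runs the consistency checks of [validateBodyComp()].
#'
#' @param path CSV path.
#' @param strict If `TRUE`, consistency violations are errors instead of
#'   warnings.
#' @return data.frame of validated records, with the validation table
#'   attached as attribute `"validation"`.
#' @export
readBodyComp <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  hit <- names(df) %in% names(.BODY_ALIASES)
  names(df)[hit] <- .BODY_ALIASES[names(df)[hit]]
  dict <- bodyCompColumns()
  missing <- setdiff(dict$column[dict$required], names(df))
  if (length(missing))
    stop("body-composition table ", path, " is missing mandatory ",
         "column(s): ", paste(missing, collapse = ", "))
  numcols <- setdiff(intersect(dict$column, names(df)),
                     c("participant_id", "sex"))
  for (col in numcols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' in row ", bad[1],
             ", column ", col)
      v <- vn
    }
    df[[col]] <- v
  }
  df$sex <- tolower(as.character(df$sex))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' (row ",
         which(!df$sex %in% c("male", "female"))[1], ")")
  df$participant_id <- as.character(df$participant_id)
  attr(df, "validation") <- validateBodyComp(df, strict = strict)
  df
}

#' Write a body-composition table
#'
#' @param df data.frame of records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeBodyComp <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Consistency checks on body-composition records
#'
#' Per record, checks the physical and definitional identities a
#' bioimpedance table must satisfy:
#' non-negative masses/volumes (control columns exempt), `PBF` in
#' \[0, 100\], `ECW_TBW` in (0, 1), the water-sum identity
#' `ICW + ECW = TBW` within `tolWater` (0.05 L), the ratio identity
#' `ECW / TBW = ECW_TBW` within `tolRatio` (0.001) and the BMI identity
#' `weight / (height/100)^2 = BMI` within `tolBMI` (0.3 kg/m^2).
#' Tolerances absorb the 1-3 decimal rounding typical of printed tables.
#' `SMI` is deliberately **not** recomputed from `SMM` and height: device
#' reports use appendicular muscle mass as the SMI numerator, so the
#' stored value takes precedence.
#'
#' @param df data.frame of records.
#' @param strict Violations become errors instead of warnings.
#' @param tolWater,tolRatio,tolBMI Numeric tolerances.
#' @return data.frame of violations (columns `participant_id`, `check`,
#'   `detail`); zero rows when all records pass.
#' @export
validateBodyComp <- function(df, strict = FALSE, tolWater = 0.05,
                             tolRatio = 0.001, tolBMI = 0.3) {
  dict <- bodyCompColumns()
  bad <- list()
  note <- function(id, check, detail)
    data.frame(participant_id = id, check = check, detail = detail,
               stringsAsFactors = FALSE)
  nonneg <- dict$column[dict$kind %in% c("water", "muscle", "fat",
                                         "other") |
                        dict$column %in% c("height", "weight", "age")]
  for (col in intersect(nonneg, names(df))) {
    i <- which(is.finite(df[[col]]) & df[[col]] < 0)
    for (j in i)
      bad[[length(bad) + 1L]] <- note(df$participant_id[j], "non_negative",
        sprintf("%s = %g", col, df[[col]][j]))
  }
  if ("PBF" %in% names(df)) {
    i <- which(is.finite(df$PBF) & (df$PBF < 0 | df$PBF > 100))
    for (j in i)
      bad[[length(bad) + 1L]] <- note(df$participant_id[j], "pbf_range",
        sprintf("PBF = %g", df$PBF[j]))
  }
  if ("ECW_TBW" %in% names(df)) {
    i <- which(is.finite(df$ECW_TBW) &
               (df$ECW_TBW <= 0 | df$ECW_TBW >= 1))
    for (j in i)
      bad[[length(bad) + 1L]] <- note(df$participant_id[j],
        "ecw_tbw_range", sprintf("ECW_TBW = %g", df$ECW_TBW[j]))
  }
  if (all(c("ICW", "ECW", "TBW") %in% names(df))) {
    dev <- abs(df$ICW + df$ECW - df$TBW)
    for (j in which(is.finite(dev) & dev > tolWater))
      bad[[length(bad) + 1L]] <- note(df$participant_id[j], "water_sum",
        sprintf("|ICW + ECW - TBW| = %.4g L", dev[j]))
  }
  if (all(c("ECW", "TBW", "ECW_TBW") %in% names(df))) {
    dev <- abs(df$ECW / df$TBW - df$ECW_TBW)
    for (j in which(is.finite(dev) & dev > tolRatio))
      bad[[length(bad) + 1L]] <- note(df$participant_id[j], "ecw_tbw",
        sprintf("|ECW/TBW - ECW_TBW| = %.4g", dev[j]))
  }
  if (all(c("weight", "height", "BMI") %in% names(df))) {
    dev <- abs(df$weight / (df$height / 100)^2 - df$BMI)
    for (j in which(is.finite(dev) & dev > tolBMI))
      bad[[length(bad) + 1L]] <- note(df$participant_id[j], "bmi",
        sprintf("|weight/height^2 - BMI| = %.4g kg/m2", dev[j]))
  }
  out <- if (length(bad)) do.call(rbind, bad)
         else data.frame(participant_id = character(0),
                         check = character(0), detail = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(out)) {
    msg <- sprintf("%d consistency violation(s), e.g. %s [%s]: %s",
                   nrow(out), out$participant_id[1], out$check[1],
                   out$detail[1])
    if (strict) stop(msg) else warning(msg)
  }
  out
}

#' Sarcopenia-risk screen from the skeletal muscle index
#'
#' Flags participants whose SMI falls below the AWGS 2019 diagnostic
#' cutoffs: strictly below 7.0 kg/m^2 for males, strictly below
#' 5.7 kg/m^2 for females (values equal to the cutoff are not at risk).
#' Missing SMI yields `"unknown"`.
#'
#' @param sex Character vector, `"male"`/`"female"`.
#' @param smi Numeric SMI values, kg/m^2.
#' @param cutoffMale,cutoffFemale Diagnostic cutoffs (kg/m^2).
#' @return Character vector `"at_risk"`/`"not_at_risk"`/`"unknown"`.
#' @examples
#' flagSarcopeniaRisk(c("male", "female"), c(6.9, 5.7))
#' @export
flagSarcopeniaRisk <- function(sex, smi, cutoffMale = 7.0,
                               cutoffFemale = 5.7) {
  sex <- tolower(as.character(sex))
  stopifnot(all(sex %in% c("male", "female")), length(sex) == length(smi))
  cut <- ifelse(sex == "male", cutoffMale, cutoffFemale)
  out <- ifelse(smi < cut, "at_risk", "not_at_risk")
  out[is.na(smi)] <- "unknown"
  out
}

#' Descriptive statistics of the indicator columns
#'
#' Per indicator: mean, sample standard deviation (n - 1), min and max,
#' in the indicator's own units. Indicators absent from the table are
#' skipped; a single record yields sd 0 with a warning.
#'
#' @param df data.frame of body-composition records.
#' @param indicators Character vector of columns to summarise; default
#'   all indicator columns of [bodyCompColumns()] present in `df`.
#' @return data.frame with columns `indicator`, `mean`, `std`, `min`,
#'   `max`, `n`.
#' @export
describeIndicators <- function(df, indicators = NULL) {
  stopifnot(nrow(df) >= 1L)
  dict <- bodyCompColumns()
  if (is.null(indicators))
    indicators <- intersect(
      dict$column[!dict$column %in% c("participant_id", "sex")],
      names(df))
  rows <- lapply(indicators, function(col) {
    v <- df[[col]]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("indicator ", col, " is entirely missing; skipped")
      return(NULL)
    }
    s <- if (length(v) > 1L) stats::sd(v) else {
      warning("indicator ", col, " has a single value; std reported as 0")
      0
    }
    data.frame(indicator = col, mean = mean(v), std = s, min = min(v),
               max = max(v), n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
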