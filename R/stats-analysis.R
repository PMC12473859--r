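#' Shapiro-Wilk normality screen
#'
#' Screens each variable for normality ahead of Pearson correlation:
#' one row per variable with mean, sample SD, bias-corrected skewness and
#' excess kurtosis, the Shapiro-Wilk W statistic and p-value, and
#' `conforms = (p > 0.05)`. Variables with fewer than 3 complete values
#' are skipped with a warning; constant variables are flagged degenerate
#' (`conforms = NA`).
#'
#' @param df data.frame holding the variables.
#' @param variables Character vector of column names; default all numeric
#'   columns.
#' @param alpha Significance level of the screen (default 0.05).
#' @return data.frame with columns `variable`, `n`, `mean`, `sd`,
#'   `skewness`, `kurtosis`, `W`, `p`, `conforms`.
#' @export
shapiroScreen <- function(df, variables = NULL, alpha = 0.05) {
  if (is.null(variables))
    variables <- names(df)[vapply(df, is.numeric, logical(1))]
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    x <- x[is.finite(x)]
    if (length(x) < 3L) {
      warning("variable ", v, ": fewer than 3 values, skipped")
      return(NULL)
    }
    if (length(x) > 5000L) {
      warning("variable ", v, ": more than 5000 values, skipped")
      return(NULL)
    }
    base <- data.frame(variable = v, n = length(x), mean = mean(x),
                       sd = stats::sd(x), skewness = .skewness(x),
                       kurtosis = .kurtosis(x), stringsAsFactors = FALSE)
    if (stats::sd(x) == 0) {
      warning("variable ", v, " is constant; normality test degenerate")
      return(cbind(base, W = NA_real_, p = NA_real_, conforms = NA))
    }
    sw <- stats::shapiro.test(x)
    cbind(base, W = unname(sw$statistic), p = sw$p.value,
          conforms = sw$p.value > alpha)
  })
  do.call(rbind, rows)
}

.completePairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

.corCell <- function(x, y, method, xname, yname,
                     onDegenerate = c("error", "na")) {
  onDegenerate <- match.arg(onDegenerate)
  cp <- .completePairs(x, y)
  degenerate <- if (cp$n < 3L)
    sprintf("correlation of %s and %s needs >= 3 complete pairs (got %d)",
            xname, yname, cp$n)
  else if (stats::sd(cp$x) == 0 || stats::sd(cp$y) == 0)
    paste0("undefined correlation: zero variance in ",
           if (stats::sd(cp$x) == 0) xname else yname)
  else NULL
  if (!is.null(degenerate)) {
    if (onDegenerate == "error") stop(degenerate)
    warning(degenerate)
    return(data.frame(x = xname, y = yname, method = method,
                      r = NA_real_, n = cp$n, p = NA_real_,
                      marker = NA_character_, stringsAsFactors = FALSE))
  }
  if (method == "spearman") {
    cp$x <- rank(cp$x)
    cp$y <- rank(cp$y)
  }
  r <- stats::cor(cp$x, cp$y)
  p <- .corPValue(r, cp$n)
  data.frame(x = xname, y = yname, method = method, r = r, n = cp$n,
             p = p, marker = significanceMarker(p),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with significance marker
#'
#' Pearson product-moment correlation of two paired vectors on pairwise
#' complete observations, with the two-sided p-value from the exact
#' t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom (H0: no correlation, H1: r != 0) and the star marker of
#' [significanceMarker()].
#'
#' @param x,y Paired numeric vectors.
#' @param xname,yname Variable names recorded in the cell.
#' @return One-row data.frame: `x`, `y`, `method`, `r`, `n`, `p`,
#'   `marker`.
#' @export
pearsonCell <- function(x, y, xname = deparse(substitute(x)),
                        yname = deparse(substitute(y))) {
  .corCell(x, y, "pearson", xname, yname)
}

#' Spearman rank correlation with significance marker
#'
#' Pearson correlation of the average ranks (ties shared), with the same
#' t-transform p-value as [pearsonCell()] applied to the rank
#' correlation.
#'
#' @inheritParams pearsonCell
#' @return One-row data.frame as in [pearsonCell()].
#' @export
spearmanCell <- function(x, y, xname = deparse(substitute(x)),
                         yname = deparse(substitute(y))) {
  .corCell(x, y, "spearman", xname, yname)
}

.DYNAMIC_VARS <- c("mean_directional_shift", "mean_displacement",
                   "test2_1_score", "test2_2_score", "test2_score")

#' Correlation matrix between movement metrics and indicators
#'
#' Builds the grid of correlation cells between the dynamic movement
#' variables (mean directional shift, mean displacement and the three
#' walk scores) and every body-composition indicator, joined on
#' `participant_id`. Cells use pairwise-complete observations and record
#' their own n. No multiplicity correction is applied by default (the
#' battery is exploratory); `adjust = "BH"` applies Benjamini-Hochberg to
#' the p-values and re-derives the markers. Degenerate cells (zero
#' variance or fewer than 3 complete pairs) are returned as `NA` with a
#' warning instead of aborting the grid.
#'
#' @param features Per-participant feature table ([featureTable()]).
#' @param indicators Body-composition table ([readBodyComp()]).
#' @param scores Walk-score table ([scoreWalk()]), optional.
#' @param method `"pearson"` or `"spearman"`.
#' @param dynamicVars Dynamic variable names to use (default all five
#'   that are present).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of cells (long format), one row per
#'   (dynamic, indicator) pair.
#' @export
correlationMatrix <- function(features, indicators, scores = NULL,
                              method = c("pearson", "spearman"),
                              dynamicVars = NULL, adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  merged <- merge(features, indicators, by = "participant_id")
  if (!is.null(scores))
    merged <- merge(merged, scores, by = "participant_id")
  if (nrow(merged) < 3L) {
    un <- union(setdiff(features$participant_id,
                        indicators$participant_id),
                setdiff(indicators$participant_id,
                        features$participant_id))
    stop("join on participant_id yields ", nrow(merged),
         " rows (< 3); unmatched ids: ", paste(un, collapse = ", "))
  }
  if (is.null(dynamicVars))
    dynamicVars <- intersect(.DYNAMIC_VARS, names(merged))
  dict <- bodyCompColumns()
  indVars <- intersect(setdiff(dict$column,
                               c("participant_id", "sex")),
                       names(merged))
  cells <- list()
  for (dv in dynamicVars)
    for (iv in indVars)
      cells[[length(cells) + 1L]] <-
        .corCell(merged[[iv]], merged[[dv]], method, iv, dv,
                 onDegenerate = "na")
  out <- do.call(rbind, cells)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$marker <- significanceMarker(out$p_adjusted)
  }
  out
}

#' Render a correlation grid in report form
#'
#' Formats a long cell table as a wide indicator-by-movement-metric table
#' whose entries read `r marker(p)`, e.g. `0.561 **(0.019)` -- the layout
#' used in the package's reports.
#'
#' @param cells Long data.frame from [correlationMatrix()].
#' @param digits Decimal places for r and p.
#' @return data.frame, one row per indicator, one column per dynamic
#'   variable.
#' @export
formatCorrelationTable <- function(cells, digits = 3) {
  fmt <- sprintf("%%.%df %%s(%%.%df)", digits, digits)
  cells$cell <- sprintf(fmt, cells$r, cells$marker, cells$p)
  wide <- stats::reshape(
    cells[, c("x", "y", "cell")], idvar = "x", timevar = "y",
    direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  names(wide)[1] <- "variable"
  rownames(wide) <- NULL
  wide
}

#' Simple linear regression of the directional shift on one indicator
#'
#' Ordinary least squares of `y` on a single indicator `x`: intercept,
#' slope, slope t-statistic on `n - 2` degrees of freedom, two-sided
#' p-value and star marker. For any dataset the slope t equals the
#' t implied by the Pearson correlation of the same pair (an algebraic
#' identity). An exact linear relationship is reported with `t = Inf`
#' and a perfect-fit warning.
#'
#' @param y Response vector (the mean directional shift).
#' @param x Single predictor vector.
#' @param xname Name recorded for the predictor.
#' @return One-row data.frame: `variable`, `intercept`, `slope`,
#'   `t_slope`, `p`, `marker`, `n`.
#' @export
simpleOLS <- function(y, x, xname = deparse(substitute(x))) {
  cp <- .completePairs(x, y)
  if (cp$n < 3L)
    stop("regression on ", xname, " needs >= 3 complete pairs")
  if (stats::sd(cp$x) == 0)
    stop("zero variance in predictor ", xname)
  fit <- stats::lm(cp$y ~ cp$x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12 * sum((cp$y - mean(cp$y))^2) || rss == 0) {
    warning("perfect fit for predictor ", xname)
    t <- sign(co[2]) * Inf
    p <- 0
  } else {
    sm <- summary(fit)$coefficients
    t <- sm[2, "t value"]
    p <- sm[2, "Pr(>|t|)"]
  }
  data.frame(variable = xname, intercept = unname(co[1]),
             slope = unname(co[2]), t_slope = unname(t), p = unname(p),
             marker = significanceMarker(p), n = cp$n,
             stringsAsFactors = FALSE)
}

#' Per-indicator simple regressions
#'
#' Runs [simpleOLS()] of one response column against every indicator
#' column, mirroring a per-indicator regression report.
#'
#' @param df Merged data.frame holding response and indicators.
#' @param yvar Response column name (default `mean_directional_shift`).
#' @param xvars Predictor columns; default every indicator of
#'   [bodyCompColumns()] present, plus `age`, `height`, `weight`.
#' @return data.frame, one row per predictor.
#' @export
regressionTable <- function(df, yvar = "mean_directional_shift",
                            xvars = NULL) {
  if (is.null(xvars)) {
    dict <- bodyCompColumns()
    xvars <- intersect(setdiff(dict$column, c("participant_id", "sex")),
                       names(df))
  }
  out <- do.call(rbind, lapply(xvars, function(v)
    simpleOLS(df[[yvar]], df[[v]], xname = v)))
  rownames(out) <- NULL
  out
}

#' Sex-stratified correlation analysis
#'
#' Recomputes the correlation grid within each stratum of a grouping
#' column (sex by default) and summarises the response distribution per
#' stratum with a five-number summary (boxplot statistics of the mean
#' directional shift). Strata with fewer than 3 complete rows are skipped
#' with a warning; strata below `lowN` rows are flagged `low_n = TRUE`,
#' mirroring the caution required for small, imbalanced subgroups.
#'
#' @param features,indicators,scores As in [correlationMatrix()].
#' @param stratum Stratifying column in `indicators` (default `"sex"`).
#' @param method `"pearson"` or `"spearman"`.
#' @param lowN Sample size under which a stratum is flagged low-n
#'   (default 10).
#' @return Named list per stratum, each with elements `cells`,
#'   `summary` (min/q1/median/q3/max of the mean directional shift),
#'   `n` and `low_n`.
#' @export
stratifiedAnalysis <- function(features, indicators, scores = NULL,
                               stratum = "sex",
                               method = c("pearson", "spearman"),
                               lowN = 10L) {
  method <- match.arg(method)
  if (!stratum %in% names(indicators))
    stop("unknown stratum column: ", stratum)
  levels <- unique(indicators[[stratum]])
  if (stratum == "sex" && !all(levels %in% c("male", "female")))
    stop("unknown stratum labels: ",
         paste(setdiff(levels, c("male", "female")), collapse = ", "))
  out <- list()
  for (lv in levels) {
    ind <- indicators[indicators[[stratum]] == lv, , drop = FALSE]
    joined <- merge(features, ind, by = "participant_id")
    if (nrow(joined) < 3L) {
      warning("stratum ", lv, ": only ", nrow(joined),
              " complete rows, skipped")
      next
    }
    lowFlag <- nrow(joined) < lowN
    if (lowFlag)
      warning("stratum ", lv, ": small sample (n = ", nrow(joined),
              "), interpret with caution")
    cells <- correlationMatrix(features, ind, scores, method = method)
    mds <- joined$mean_directional_shift
    q <- linearQuantile(mds, c(0, 0.25, 0.5, 0.75, 1))
    out[[as.character(lv)]] <- list(
      cells = cells,
      summary = data.frame(stratum = lv, min = q[1], q1 = q[2],
                           median = q[3], q3 = q[4], max = q[5],
                           stringsAsFactors = FALSE),
      n = nrow(joined), low_n = lowFlag)
  }
  out
}
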