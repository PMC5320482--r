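#' Construct or fit a calibration curve
#'
#' `calibration_curve()` wraps already-known regression parameters (e.g. a
#' published slope/intercept/R-squared); `fit_calibration()` fits an
#' unweighted ordinary least-squares line to signal vs. concentration.
#'
#' @param analyte,matrix,dilution Identifying labels; `matrix = "methanol"`
#'   denotes the pure-solvent curve, `dilution` is `"ND"` (no dilution) or
#'   `"D10"` (10-fold).
#' @param slope,intercept,r_squared Regression parameters (signal per
#'   ug/L, signal, and coefficient of determination).
#' @param levels Calibration concentrations in ug/L (strictly increasing).
#' @return A `"cv_calibration"` object. `fit_calibration()` additionally
#'   carries `residual_sd`, `n`, `x_mean`, `s_xx` for uncertainty
#'   propagation, and a `usable` flag (FALSE for a zero slope).
#' @export
calibration_curve <- function(slope, intercept = 0, r_squared = NA_real_,
                              analyte = NA_character_, matrix = NA_character_,
                              dilution = NA_character_, levels = NULL) {
  if (!is.null(levels) && is.unsorted(levels, strictly = TRUE)) {
    stop("calibration levels must be strictly increasing", call. = FALSE)
  }
  structure(list(analyte = analyte, matrix = matrix, dilution = dilution,
                 slope = slope, intercept = intercept, r_squared = r_squared,
                 levels = levels, usable = slope != 0),
            class = "cv_calibration")
}

#' @rdname calibration_curve
#' @param signals Instrument responses, one per level.
#' @export
fit_calibration <- function(levels, signals, analyte = NA_character_,
                            matrix = NA_character_, dilution = NA_character_) {
  if (length(levels) < 5L) {
    stop("calibration needs at least 5 levels, got ", length(levels),
         call. = FALSE)
  }
  if (length(signals) != length(levels)) {
    stop("levels and signals differ in length", call. = FALSE)
  }
  o <- order(levels)
  levels <- levels[o]
  signals <- signals[o]
  fit <- stats::lm(signals ~ levels)
  b <- unname(stats::coef(fit))
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning is expected
  if (stats::var(signals) == 0) {
    # a flat signal is a zero slope, not the numerical noise lm returns
    b <- c(signals[1], 0)
  }
  r2 <- if (stats::var(signals) == 0) 0 else sm$r.squared
  cc <- calibration_curve(slope = b[2], intercept = b[1], r_squared = r2,
                          analyte = analyte, matrix = matrix,
                          dilution = dilution, levels = levels)
  cc$residual_sd <- sm$sigma
  cc$n <- length(levels)
  cc$x_mean <- mean(levels)
  cc$s_xx <- sum((levels - mean(levels))^2)
  if (!cc$usable) warning("zero calibration slope: curve unusable", call. = FALSE)
  cc
}

#' Matrix effect from calibration slopes
#'
#' \deqn{ME(\%) = (slope_{matrix} / slope_{solvent} - 1) \times 100}
#' Positive values are signal enhancement, negative values suppression.
#' `me_display` rounds half-away-from-zero to the nearest integer for
#' reporting; full precision is retained in `me_percent`.
#'
#' @param curve_matrix,curve_solvent `"cv_calibration"` objects for the
#'   matrix-matched and pure-solvent curves.
#' @return A `"cv_matrix_effect"` list: `me_percent`, `me_display`,
#'   `category`, `direction`.
#' @export
matrix_effect <- function(curve_matrix, curve_solvent) {
  stopifnot(inherits(curve_matrix, "cv_calibration"),
            inherits(curve_solvent, "cv_calibration"))
  if (curve_solvent$slope == 0) {
    stop("solvent calibration slope is zero", call. = FALSE)
  }
  me <- (curve_matrix$slope / curve_solvent$slope - 1) * 100
  structure(list(
    analyte = curve_matrix$analyte, matrix = curve_matrix$matrix,
    dilution = curve_matrix$dilution,
    me_percent = me, me_display = round_half_away(me),
    category = classify_me(me),
    direction = if (me < 0) "suppression" else if (me > 0) "enhancement"
                else "neutral"
  ), class = "cv_matrix_effect")
}

#' Classify a matrix effect
#'
#' No matrix effect between -20 and +20 % inclusive (comparable to
#' repeatability); strong strictly below -50 or above +50 %; medium
#' otherwise.
#'
#' @param me_percent Matrix effect in percent.
#' @return `"none"`, `"medium"` or `"strong"` (vectorized).
#' @export
classify_me <- function(me_percent) {
  ifelse(me_percent >= -20 & me_percent <= 20, "none",
         ifelse(me_percent < -50 | me_percent > 50, "strong", "medium"))
}

#' Improvement of matrix effects after dilution
#'
#' Compares per-analyte matrix effects before (`ND`) and after 10-fold
#' dilution (`D10`) within one matrix. Two summary metrics are available:
#' `"abs_decrease"` (default) — the percentage of analytes whose |ME|
#' decreased after dilution; `"strong_resolved"` — the percentage of
#' analytes with a strong ND matrix effect that became non-strong.
#'
#' @param me_nd,me_d10 Named numeric vectors of ME % (names = analytes).
#' @param metric `"abs_decrease"` or `"strong_resolved"`.
#' @return Improvement percentage (0--100); `NA` for `"strong_resolved"`
#'   when no ND effect is strong.
#' @export
dilution_improvement <- function(me_nd, me_d10,
                                 metric = c("abs_decrease", "strong_resolved")) {
  metric <- match.arg(metric)
  if (!setequal(names(me_nd), names(me_d10))) {
    stop("ND and D10 analyte sets differ", call. = FALSE)
  }
  me_d10 <- me_d10[names(me_nd)]
  if (metric == "abs_decrease") {
    100 * mean(abs(me_d10) < abs(me_nd))
  } else {
    strong <- classify_me(me_nd) == "strong"
    if (!any(strong)) return(NA_real_)
    100 * mean(classify_me(me_d10[strong]) != "strong")
  }
}

#' Summarize spiked-recovery replicates
#'
#' Computes the mean recovery, the intra-day RSD (first day's replicates)
#' and the inter-day RSD (all replicates across days) for one analyte,
#' matrix and spike level. RSD = 100 * sample SD / mean.
#'
#' @param replicates Data frame with columns `day` and `recovery_pct` (one
#'   row per replicate), or a numeric vector for a single day.
#' @param n_days,n_reps Expected structure (default 3 days x 5 replicates);
#'   deviations raise an error naming the deficit.
#' @param analyte,matrix,level Identifying labels carried through.
#' @return A `"cv_recovery"` list: `mean_recovery`, `rsd_intra`,
#'   `rsd_inter`, `n_intra`, `n_total` plus labels.
#' @export
recovery_summary <- function(replicates, n_days = 3L, n_reps = 5L,
                             analyte = NA_character_, matrix = NA_character_,
                             level = NA_character_) {
  if (is.numeric(replicates)) {
    replicates <- data.frame(day = 1L, recovery_pct = replicates)
    n_days <- 1L
  }
  stopifnot(all(c("day", "recovery_pct") %in% names(replicates)))
  days <- sort(unique(replicates$day))
  if (length(days) != n_days) {
    stop("expected ", n_days, " days, found ", length(days), call. = FALSE)
  }
  counts <- table(replicates$day)
  if (any(counts != n_reps)) {
    bad <- names(counts)[counts != n_reps]
    stop("expected ", n_reps, " replicates per day; day(s) ",
         paste(bad, collapse = ", "), " deviate", call. = FALSE)
  }
  r <- replicates$recovery_pct
  r1 <- replicates$recovery_pct[replicates$day == days[1L]]
  structure(list(
    analyte = analyte, matrix = matrix, level = level,
    mean_recovery = mean(r),
    rsd_intra = 100 * stats::sd(r1) / mean(r1),
    rsd_inter = 100 * stats::sd(r) / mean(r),
    n_intra = length(r1), n_total = length(r)
  ), class = "cv_recovery")
}

#' Validation-based limit of quantification
#'
#' The LOQ is the lowest candidate spike level whose validation results
#' pass: mean recovery within 70--120 % inclusive and every reported RSD
#' strictly below 20 %.
#'
#' @param results Data frame with columns `level` (ug/kg, the candidate
#'   spike levels), `mean_recovery`, and one or more RSD columns (any
#'   column whose name starts with `"rsd"`).
#' @param recovery_range Inclusive acceptance range for mean recovery.
#' @param rsd_max Strict upper bound for RSDs.
#' @return List with `loq` (numeric, `NA` if no level passes), `passed`
#'   (logical per level) and the decision table.
#' @export
check_loq <- function(results, recovery_range = c(70, 120), rsd_max = 20) {
  stopifnot(all(c("level", "mean_recovery") %in% names(results)))
  rsd_cols <- grep("^rsd", names(results), value = TRUE)
  if (length(rsd_cols) == 0L) stop("no RSD columns found", call. = FALSE)
  o <- order(results$level)
  results <- results[o, , drop = FALSE]
  rec_ok <- results$mean_recovery >= recovery_range[1] &
    results$mean_recovery <= recovery_range[2]
  rsd_ok <- apply(results[rsd_cols] < rsd_max, 1L, all)
  passed <- rec_ok & rsd_ok
  loq <- if (any(passed)) results$level[which(passed)[1L]] else NA_real_
  if (is.na(loq)) {
    warning("no candidate level passes: LOQ undefined", call. = FALSE)
  }
  results$passed <- passed
  list(loq = loq, passed = passed, table = results)
}

#' Identification points for MS/MS confirmation
#'
#' Confirmation currency of Decision 2002/657/EC: 1.0 point per precursor
#' ion and 1.5 per product ion, with >= 4 points required for confirmation.
#' One precursor with two products earns exactly 4.0.
#'
#' @param n_precursor,n_product Ion counts (>= 0).
#' @return List with `points` and logical `confirmed`.
#' @export
identification_points <- function(n_precursor, n_product) {
  stopifnot(n_precursor >= 0, n_product >= 0)
  pts <- 1.0 * n_precursor + 1.5 * n_product
  list(points = pts, confirmed = pts >= 4)
}

#' Aggregate a residue survey
#'
#' A sample is positive when at least one analyte is quantified at or above
#' its LOQ; censored records (`NA` concentration, i.e. below the detection
#' limit) never count. Ratios are displayed rounded to integer percent.
#'
#' @param records Data frame with columns `sample_id`, `commodity`,
#'   `analyte`, `conc_ugkg` (`NA` = censored). Blank samples may appear as
#'   rows with `NA` analyte.
#' @param commodity_totals Named vector: number of samples surveyed per
#'   commodity (required; records alone cannot reveal blank sample counts).
#' @param loq Named vector of LOQs (ug/kg) per analyte.
#' @param mrl Optional data frame `analyte`, `commodity`, `mrl_ugkg` for
#'   exceedance checks.
#' @return A `"cv_survey"` list: `per_commodity` (counts, positives,
#'   ratio_pct), `n_samples`, `n_positive`, `positive_pct` (integer
#'   percent) and `positive_pct_raw`, `max_concentration` (value, analyte,
#'   commodity; `NULL` if no quantified residue), `exceedances`.
#' @export
survey_summary <- function(records, commodity_totals, loq, mrl = NULL) {
  stopifnot(all(c("sample_id", "commodity", "analyte", "conc_ugkg")
                %in% names(records)))
  unknown <- setdiff(unique(records$commodity), names(commodity_totals))
  if (length(unknown) > 0L) {
    stop("unknown commodity in records: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  det <- records[!is.na(records$conc_ugkg) & !is.na(records$analyte), ,
                 drop = FALSE]
  if (nrow(det) > 0L) {
    unk_a <- setdiff(unique(det$analyte), names(loq))
    if (length(unk_a) > 0L) {
      stop("no LOQ supplied for analyte(s): ", paste(unk_a, collapse = ", "),
           call. = FALSE)
    }
    det$positive <- det$conc_ugkg >= loq[det$analyte]
  }
  pos_samples <- if (nrow(det) > 0L) {
    unique(det$sample_id[det$positive])
  } else character(0)
  pos_by_comm <- vapply(names(commodity_totals), function(cm) {
    ids <- unique(records$sample_id[records$commodity == cm])
    sum(ids %in% pos_samples)
  }, integer(1))
  n_samples <- sum(commodity_totals)
  n_positive <- sum(pos_by_comm)
  per_comm <- data.frame(
    commodity = names(commodity_totals),
    n = as.integer(commodity_totals),
    positives = as.integer(pos_by_comm),
    ratio_pct = as.integer(round_half_away(100 * pos_by_comm /
                                             as.integer(commodity_totals))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  max_conc <- NULL
  if (nrow(det) > 0L) {
    i <- which.max(det$conc_ugkg)
    max_conc <- list(value = det$conc_ugkg[i], analyte = det$analyte[i],
                     commodity = det$commodity[i])
  }
  exceed <- NULL
  if (!is.null(mrl) && nrow(det) > 0L) {
    m <- merge(det, mrl, by = c("analyte", "commodity"))
    exceed <- m[!is.na(m$mrl_ugkg) & m$conc_ugkg > m$mrl_ugkg, ,
                drop = FALSE]
  }
  structure(list(
    per_commodity = per_comm,
    n_samples = n_samples,
    n_positive = n_positive,
    positive_pct = as.integer(round_half_away(100 * n_positive / n_samples)),
    positive_pct_raw = 100 * n_positive / n_samples,
    max_concentration = max_conc,
    exceedances = exceed
  ), class = "cv_survey")
}

#' @export
print.cv_survey <- function(x, ...) {
  cat(sprintf("Survey: %d/%d samples positive (%d%%)\n",
              x$n_positive, x$n_samples, x$positive_pct))
  if (!is.null(x$max_concentration)) {
    cat(sprintf("  max residue: %.1f ug/kg (%s, %s)\n",
                x$max_concentration$value, x$max_concentration$analyte,
                x$max_concentration$commodity))
  }
  invisible(x)
}
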