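#' Default synthetic truth for the five-pesticide workflow
#'
#' Builds a fully specified latent "truth" from which every pipeline input
#' can be simulated: per-analyte quadratic recovery surfaces in coded
#' units over the three optimization factors (toluene %, HCl %, GCB mg),
#' linear screening effects over all five factors (adding PSA and C18 as
#' true nulls), matrix-dependent calibration-slope distortion that 10-fold
#' dilution shrinks toward 1, within/between-day recovery variance
#' components, and low-prevalence log-normal contamination surveys.
#'
#' The surfaces encode the qualitative structure the workflow is designed
#' to recover: a strong negative GCB effect for three of the five analytes
#' (weakly positive for the other two), positive HCl and toluene effects
#' with concave curvature so the optimum is interior in toluene and HCl but
#' sits at the low GCB boundary (0 mg). A small seeded jitter
#' differentiates analytes without moving the optimum structure.
#'
#' @param seed Integer seed; the same seed always returns the same truth.
#' @return A `"cv_truth"` list: `analytes`, `factors` (five
#'   [doe_factor()]s), `surface` (per-analyte named coefficient vectors on
#'   the 3-factor quadratic basis), `screening_effects` (per-analyte linear
#'   coefficients for all 5 factors), `noise_sd`, `clip`, calibration
#'   (`true_slope`, `me_factor` per matrix, `dilution_shrink`,
#'   `calibration_cv`), recovery (`recovery_mean`, `sd_within`,
#'   `sd_between`), survey (`prevalence`, `lnorm_meanlog`, `lnorm_sdlog`,
#'   `loq`), and `seed`.
#' @export
make_default_truth <- function(seed = 1L) {
  analytes <- c("2,4-D", "carbendazim", "thiabendazole", "iprodione",
                "prochloraz")
  factors <- list(
    doe_factor("toluene_pct", 0, 100, "X1"),
    doe_factor("hcl_pct", 0, 0.5, "X2"),
    doe_factor("psa_mg", 0, 50, "X3"),
    doe_factor("c18_mg", 0, 20, "X4"),
    doe_factor("gcb_mg", 0, 20, "X5")
  )
  names(factors) <- vapply(factors, `[[`, "", "name")
  # GCB hurts recovery for three analytes; weak positive for 2,4-D and
  # thiabendazole (adsorption of planar analytes drives the asymmetry).
  gcb_lin <- c(0.8, -5, 0.8, -5, -5)
  jit <- with_seed(child_seed(seed, "truth"), {
    list(b0 = stats::runif(5, -2, 2), coefjit = stats::runif(5, -0.3, 0.3))
  })
  surface <- lapply(seq_along(analytes), function(i) {
    c(`(Intercept)` = 92 + jit$b0[i],
      toluene_pct = 2 + jit$coefjit[i],
      hcl_pct = 3 + jit$coefjit[i],
      gcb_mg = gcb_lin[i],
      `toluene_pct^2` = -8,
      `hcl_pct^2` = -6,
      `gcb_mg^2` = 0,
      `toluene_pct:hcl_pct` = 0.5,
      `toluene_pct:gcb_mg` = 0,
      `hcl_pct:gcb_mg` = 0)
  })
  names(surface) <- analytes
  screening_effects <- lapply(seq_along(analytes), function(i) {
    c(toluene_pct = 2 + jit$coefjit[i], hcl_pct = 3 + jit$coefjit[i],
      psa_mg = 0, c18_mg = 0, gcb_mg = gcb_lin[i])
  })
  names(screening_effects) <- analytes
  matrices <- c("citrus", "apple", "mango", "lychee", "tomato", "cucumber",
                "green pepper", "eggplant")
  me_factor <- matrix(
    c(1.60, 1.10, 1.43, 0.60, 0.79, 1.23, 0.68, 0.58,
      1.52, 1.34, 1.30, 0.73, 1.22, 1.51, 1.28, 1.38,
      1.60, 1.03, 0.86, 0.49, 1.17, 1.10, 0.73, 0.73,
      0.66, 0.82, 0.59, 0.46, 0.57, 1.28, 0.83, 0.46,
      1.28, 0.63, 1.35, 0.55, 1.29, 1.28, 1.38, 0.60),
    nrow = 8, dimnames = list(matrices, analytes))
  commodities <- c(citrus = 20L, apple = 10L, mango = 10L, lychee = 20L,
                   tomato = 5L, cucumber = 5L, `green pepper` = 10L,
                   eggplant = 5L)
  structure(list(
    analytes = analytes,
    factors = factors,
    surface = surface,
    screening_effects = screening_effects,
    noise_sd = 1.0,
    clip = c(0, 110),
    true_slope = c(`2,4-D` = 2000, carbendazim = 180000,
                   thiabendazole = 120000, iprodione = 260,
                   prochloraz = 14500),
    me_factor = me_factor,
    dilution_shrink = 0.6,
    calibration_cv = 0.02,
    calibration_levels = c(0.1, 1, 5, 10, 50, 100, 200),
    recovery_mean = 90,
    sd_within = 4,
    sd_between = 3,
    prevalence = 0.12,
    lnorm_meanlog = 2.0,
    lnorm_sdlog = 0.6,
    loq = c(`2,4-D` = 1.0, carbendazim = 1.0, thiabendazole = 1.0,
            iprodione = 1.5, prochloraz = 1.0),
    commodity_counts = commodities,
    seed = as.integer(seed)
  ), class = "cv_truth")
}

# Evaluate a truth surface at coded points of a (possibly partial) design.
# Missing factors are held at their coded center (0).
eval_surface <- function(truth, analyte, coded) {
  beta <- truth$surface[[analyte]]
  nm <- colnames(coded)
  full <- c("toluene_pct", "hcl_pct", "gcb_mg")
  pts <- matrix(0, nrow = nrow(coded), ncol = 3,
                dimnames = list(NULL, full))
  for (j in nm) if (j %in% full) pts[, j] <- coded[, j]
  drop(quad_basis(pts) %*% beta[colnames(quad_basis(pts))])
}

#' Simulate design-of-experiments responses
#'
#' For screening designs the latent response is linear in all five factors
#' (the `screening_effects` coefficients plus the surface intercept); for
#' optimization designs it is the quadratic recovery surface. Gaussian
#' noise with `truth$noise_sd` is added and responses are clipped to
#' `truth$clip` (recoveries cannot be negative nor far above 100 %).
#'
#' @param design A `"cv_design"` whose factor names appear in the truth.
#' @param truth A `"cv_truth"`.
#' @param seed Integer seed.
#' @param noise_sd Override for the response noise SD (default from truth).
#' @return Data frame `run_id`, `analyte`, `response` (long format), one
#'   row per run per analyte.
#' @export
simulate_doe <- function(design, truth, seed = truth$seed,
                         noise_sd = truth$noise_sd) {
  stopifnot(inherits(design, "cv_design"), inherits(truth, "cv_truth"))
  nm <- colnames(design$coded)
  if (!all(nm %in% names(truth$factors))) {
    stop("design factors not in truth: ",
         paste(setdiff(nm, names(truth$factors)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(design$coded)
  out <- vector("list", length(truth$analytes))
  for (i in seq_along(truth$analytes)) {
    a <- truth$analytes[i]
    mu <- if (identical(design$design_type, "plackett_burman")) {
      beta <- truth$screening_effects[[a]]
      truth$surface[[a]][["(Intercept)"]] +
        drop(design$coded %*% beta[nm])
    } else {
      eval_surface(truth, a, design$coded)
    }
    eps <- with_seed(child_seed(seed, "doe", i), stats::rnorm(n, 0, noise_sd))
    y <- pmin(pmax(mu + eps, truth$clip[1]), truth$clip[2])
    out[[i]] <- data.frame(run_id = seq_len(n), analyte = a, response = y,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a calibration table
#'
#' Signal = true slope x matrix-effect factor x concentration x (1 + eps),
#' eps ~ N(0, CV^2). For the pure solvent (`matrix = "methanol"`) the
#' matrix-effect factor is 1. Ten-fold dilution shrinks the distortion
#' toward 1 by `truth$dilution_shrink` (0.6 = 60 % of the deviation
#' removed), so |ME(D10)| < |ME(ND)| whenever the factor is non-unit.
#'
#' @param truth A `"cv_truth"`.
#' @param analyte,matrix Labels; `matrix = "methanol"` for solvent.
#' @param dilution `"ND"` or `"D10"`.
#' @param seed Integer seed.
#' @return Data frame `analyte`, `matrix`, `dilution`, `level_ugL`,
#'   `signal`.
#' @export
simulate_calibration <- function(truth, analyte, matrix, dilution = "ND",
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "cv_truth"), analyte %in% truth$analytes)
  f <- if (identical(matrix, "methanol")) 1 else {
    if (!matrix %in% rownames(truth$me_factor)) {
      stop("unknown matrix: ", matrix, call. = FALSE)
    }
    f0 <- truth$me_factor[matrix, analyte]
    if (identical(dilution, "D10")) 1 + (f0 - 1) * (1 - truth$dilution_shrink)
    else f0
  }
  lv <- truth$calibration_levels
  eps <- with_seed(child_seed(seed, paste("cal", analyte, matrix, dilution)),
                   stats::rnorm(length(lv), 0, truth$calibration_cv))
  data.frame(analyte = analyte, matrix = matrix, dilution = dilution,
             level_ugL = lv,
             signal = truth$true_slope[[analyte]] * f * lv * (1 + eps),
             stringsAsFactors = FALSE)
}

#' Simulate spiked-recovery replicates
#'
#' Recovery = truth mean + day effect N(0, sd_between^2) + replicate noise
#' N(0, sd_within^2), the classic one-way variance-components layout behind
#' intra-day (n = `n_reps`) and inter-day (n = `n_days * n_reps`) RSDs.
#'
#' @param truth A `"cv_truth"`.
#' @param analyte,matrix,level Labels carried through.
#' @param n_days,n_reps Replication structure (default 3 x 5).
#' @param seed Integer seed.
#' @return Data frame `analyte`, `matrix`, `level_label`, `day`, `rep`,
#'   `recovery_pct`.
#' @export
simulate_recovery <- function(truth, analyte, matrix, level = "LOQ",
                              n_days = 3L, n_reps = 5L, seed = truth$seed) {
  stopifnot(inherits(truth, "cv_truth"))
  r <- with_seed(child_seed(seed, paste("rec", analyte, matrix, level)), {
    day_eff <- stats::rnorm(n_days, 0, truth$sd_between)
    truth$recovery_mean + rep(day_eff, each = n_reps) +
      stats::rnorm(n_days * n_reps, 0, truth$sd_within)
  })
  data.frame(analyte = analyte, matrix = matrix, level_label = level,
             day = rep(seq_len(n_days), each = n_reps),
             rep = rep(seq_len(n_reps), times = n_days),
             recovery_pct = r, stringsAsFactors = FALSE)
}

#' Simulate a contamination survey
#'
#' Each sample is contaminated with probability `truth$prevalence`; a
#' contaminated sample receives one analyte (uniformly chosen) at a
#' log-normal concentration. Values below that analyte's LOQ are emitted
#' as censored (`NA`), as a real monitoring table would report them.
#'
#' @param truth A `"cv_truth"`.
#' @param commodity_counts Named integer vector of samples per commodity
#'   (default `truth$commodity_counts`).
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `commodity`, `analyte`, `conc_ugkg`
#'   (one row per sample; `NA` analyte/concentration for blanks).
#' @export
simulate_survey <- function(truth, commodity_counts = truth$commodity_counts,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "cv_truth"), all(commodity_counts >= 0))
  n <- sum(commodity_counts)
  commodity <- rep(names(commodity_counts), times = commodity_counts)
  with_seed(child_seed(seed, "survey"), {
    contaminated <- stats::runif(n) < truth$prevalence
    analyte <- ifelse(contaminated,
                      sample(truth$analytes, n, replace = TRUE), NA)
    conc <- ifelse(contaminated,
                   stats::rlnorm(n, truth$lnorm_meanlog, truth$lnorm_sdlog),
                   NA_real_)
    censored <- !is.na(conc) & conc < truth$loq[analyte]
    conc[censored] <- NA_real_
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               commodity = commodity, analyte = analyte, conc_ugkg = conc,
               stringsAsFactors = FALSE)
  })
}
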