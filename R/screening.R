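#' Plackett--Burman main effects
#'
#' The main effect of a two-level factor is the mean response at its high
#' level minus the mean at its low level, computed over the non-center runs
#' only. Center points do not enter the contrast; they estimate pure error.
#'
#' @param design A `"cv_design"` from [pb_design()].
#' @param responses Numeric response vector aligned with the design rows
#'   (including center rows).
#' @return Named numeric vector of effects, one per factor.
#' @export
main_effects <- function(design, responses) {
  stopifnot(inherits(design, "cv_design"))
  if (length(responses) != nrow(design$coded)) {
    stop("responses (", length(responses), ") not aligned with design rows (",
         nrow(design$coded), ")", call. = FALSE)
  }
  if (anyNA(responses)) stop("missing response values", call. = FALSE)
  keep <- design$point_type != "center"
  x <- design$coded[keep, , drop = FALSE]
  y <- responses[keep]
  eff <- vapply(seq_len(ncol(x)), function(j) {
    mean(y[x[, j] > 0]) - mean(y[x[, j] < 0])
  }, numeric(1))
  names(eff) <- colnames(x)
  eff
}

#' Pure error from center-point replicates
#'
#' @param center_responses Responses of the replicated center runs (>= 2).
#' @return List with `s_pe` (sample SD) and `df_pe` (replicates - 1).
#' @examples
#' pure_error(c(88, 90, 92))  # s_pe = 2, df_pe = 2
#' @export
pure_error <- function(center_responses) {
  n <- length(center_responses)
  if (n < 2L) {
    stop("pure error needs at least 2 center replicates, got ", n,
         call. = FALSE)
  }
  list(s_pe = stats::sd(center_responses), df_pe = n - 1L)
}

#' t-test of main effects against pure error
#'
#' Each effect is tested at confidence level `1 - alpha` (two-sided) using
#' the center-point pure-error SD as the error term:
#' \eqn{SE = s_{pe}\sqrt{1/n_+ + 1/n_-}}, \eqn{t = effect/SE}, with
#' `df_pe` degrees of freedom. With a degenerate `s_pe = 0` the t-values and
#' p-values are undefined (`NA`) and the table is flagged.
#'
#' @param effects Named effect vector from [main_effects()].
#' @param s_pe,df_pe Pure-error SD and degrees of freedom.
#' @param n_plus,n_minus Runs at the high / low level per factor (6 and 6
#'   for the 12-run design).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A data frame of class `"cv_effect_table"` with columns `factor`,
#'   `effect`, `standard_error`, `t_value`, `p_value`, `significant`,
#'   `sign`; attributes `s_pe`, `df_pe`, `t_critical`, `alpha`, `degenerate`.
#' @export
test_effects <- function(effects, s_pe, df_pe, n_plus = 6L, n_minus = 6L,
                         alpha = 0.05) {
  stopifnot(s_pe >= 0, df_pe >= 1)
  degenerate <- s_pe == 0
  se <- s_pe * sqrt(1 / n_plus + 1 / n_minus)
  t_crit <- stats::qt(1 - alpha / 2, df = df_pe)
  if (degenerate) {
    warning("pure-error SD is zero: significance undefined", call. = FALSE)
    tv <- rep(NA_real_, length(effects))
    pv <- rep(NA_real_, length(effects))
    sig <- rep(NA, length(effects))
  } else {
    tv <- effects / se
    pv <- 2 * stats::pt(-abs(tv), df = df_pe)
    sig <- abs(tv) > t_crit
  }
  out <- data.frame(factor = names(effects), effect = unname(effects),
                    standard_error = se, t_value = tv, p_value = pv,
                    significant = sig,
                    sign = ifelse(effects >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  attr(out, "s_pe") <- s_pe
  attr(out, "df_pe") <- df_pe
  attr(out, "t_critical") <- t_crit
  attr(out, "alpha") <- alpha
  attr(out, "degenerate") <- degenerate
  class(out) <- c("cv_effect_table", "data.frame")
  out
}

#' Screen a Plackett--Burman experiment
#'
#' Convenience wrapper: main effects, pure error from the design's center
#' rows, and the pure-error t-test, as displayed in a standardized Pareto
#' chart (bars proportional to |t|, vertical line at the critical t).
#'
#' @inheritParams main_effects
#' @param alpha Two-sided significance level.
#' @return A `"cv_effect_table"` (see [test_effects()]).
#' @export
screen_effects <- function(design, responses, alpha = 0.05) {
  eff <- main_effects(design, responses)
  keep <- design$point_type != "center"
  n_plus <- colSums(design$coded[keep, , drop = FALSE] > 0)
  pe <- pure_error(responses[design$point_type == "center"])
  test_effects(eff, pe$s_pe, pe$df_pe,
               n_plus = n_plus, n_minus = sum(keep) - n_plus, alpha = alpha)
}

#' Rank factors as in a standardized Pareto chart
#'
#' Orders factors by decreasing |t|; ties keep the input order. The
#' threshold column repeats the critical t so the 95 % line can be drawn.
#'
#' @param table A `"cv_effect_table"`.
#' @return The table sorted by |t| with a `threshold` column and a `rank`
#'   column.
#' @export
pareto_rank <- function(table) {
  stopifnot(inherits(table, "cv_effect_table"))
  o <- order(-abs(table$t_value), seq_len(nrow(table)))  # ties keep input order
  out <- table[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$threshold <- attr(table, "t_critical")
  rownames(out) <- NULL
  out
}
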