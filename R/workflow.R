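#' Run the screening-to-optimum workflow end to end
#'
#' Reproduces the full chemometric development sequence on simulated (or
#' supplied) data: a 12-run Plackett--Burman screen with 3 center points
#' over all five factors, selection of the factors significant for at
#' least `min_analytes` of the analytes, a rotatable central composite
#' design over the selected factors, per-analyte second-order fits with
#' lack-of-fit ANOVA, and Derringer desirability optimization over the
#' coded cube.
#'
#' @param truth A `"cv_truth"` from [make_default_truth()].
#' @param seed Integer seed controlling every simulated response.
#' @param alpha Significance level for the screening t-tests.
#' @param min_analytes A factor is carried into optimization when it is
#'   significant for at least this many analytes (default: a majority).
#' @param n_center_pb,n_center_ccd Center replicates for the two designs.
#' @return A `"cv_workflow"` list: `pb_design`, `screening` (per-analyte
#'   effect tables), `selected` (factor names), `ccd_design`, `models`
#'   (per-analyte `"cv_quad_model"`), `optimum`, `profiles`, `seed`.
#' @export
run_workflow <- function(truth = make_default_truth(seed), seed = 1L,
                         alpha = 0.05, min_analytes = NULL,
                         n_center_pb = 3L, n_center_ccd = 6L) {
  stopifnot(inherits(truth, "cv_truth"))
  if (is.null(min_analytes)) min_analytes <- ceiling(length(truth$analytes) / 2)

  pb <- pb_design(truth$factors, n_center = n_center_pb)
  pb <- randomize_run_order(pb, child_seed(seed, "pb_order"))
  pb_resp <- simulate_doe(pb, truth, seed = child_seed(seed, "pb_resp"))
  screening <- lapply(truth$analytes, function(a) {
    screen_effects(pb, pb_resp$response[pb_resp$analyte == a], alpha = alpha)
  })
  names(screening) <- truth$analytes

  sig_count <- Reduce(`+`, lapply(screening, function(tb) {
    stats::setNames(as.integer(tb$significant), tb$factor)
  }))
  selected <- names(sig_count)[sig_count >= min_analytes]
  if (length(selected) < 2L) {
    # Optimization needs at least two factors; fall back to the two
    # largest pooled |t| if screening was too conservative.
    pooled <- Reduce(`+`, lapply(screening, function(tb) {
      stats::setNames(abs(tb$t_value), tb$factor)
    }))
    selected <- names(sort(pooled, decreasing = TRUE))[1:2]
  }
  selected <- names(truth$factors)[names(truth$factors) %in% selected]

  ccd <- ccd_design(truth$factors[selected], n_center = n_center_ccd)
  ccd <- randomize_run_order(ccd, child_seed(seed, "ccd_order"))
  ccd_resp <- simulate_doe(ccd, truth, seed = child_seed(seed, "ccd_resp"))
  models <- lapply(truth$analytes, function(a) {
    fit_quadratic(ccd, ccd_resp$response[ccd_resp$analyte == a])
  })
  names(models) <- truth$analytes

  optimum <- optimize_desirability(models)
  profiles <- desirability_profiles(optimum)

  structure(list(pb_design = pb, pb_responses = pb_resp,
                 screening = screening, selected = selected,
                 ccd_design = ccd, ccd_responses = ccd_resp,
                 models = models, optimum = optimum, profiles = profiles,
                 truth = truth, seed = as.integer(seed)),
            class = "cv_workflow")
}

#' @export
print.cv_workflow <- function(x, ...) {
  cat("Chemometric workflow\n")
  cat("  selected factors:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  optimum D = %.3f at %s\n", x$optimum$D,
              paste(sprintf("%s = %.2f", names(x$optimum$coded),
                            x$optimum$coded), collapse = ", ")))
  invisible(x)
}

fmt_row <- function(...) paste0("| ", paste(..., sep = " | "), " |")

#' Build a human-readable markdown report
#'
#' Assembles whatever artifacts are supplied into a deterministic markdown
#' summary: screening effects, response-surface fits and the desirability
#' optimum (from a `"cv_workflow"`), matrix-effect and recovery tables,
#' uncertainty budgets, and a survey section. Missing artifacts are
#' skipped with a notice line. Identical inputs yield byte-identical
#' output.
#'
#' @param workflow Optional `"cv_workflow"`.
#' @param matrix_effects Optional list of `"cv_matrix_effect"` objects.
#' @param recoveries Optional list of `"cv_recovery"` objects.
#' @param budgets Optional list of `"cv_uncertainty_budget"` objects.
#' @param survey Optional `"cv_survey"`.
#' @return Character vector of markdown lines (invisibly printable via
#'   `cat(report, sep = "\n")`).
#' @export
build_report <- function(workflow = NULL, matrix_effects = NULL,
                         recoveries = NULL, budgets = NULL, survey = NULL) {
  out <- c("# Method development and validation report", "")
  if (!is.null(workflow)) {
    out <- c(out, "## Screening (Plackett-Burman)", "",
             fmt_row("analyte", "factor", "effect", "t", "p", "significant"),
             fmt_row("---", "---", "---", "---", "---", "---"))
    for (a in names(workflow$screening)) {
      tb <- workflow$screening[[a]]
      for (i in seq_len(nrow(tb))) {
        out <- c(out, fmt_row(a, tb$factor[i], sprintf("%.3f", tb$effect[i]),
                              sprintf("%.2f", tb$t_value[i]),
                              sprintf("%.4f", tb$p_value[i]),
                              ifelse(tb$significant[i], "yes", "no")))
      }
    }
    out <- c(out, "",
             paste0("Selected factors: ",
                    paste(workflow$selected, collapse = ", ")),
             "", "## Response-surface fits", "",
             fmt_row("analyte", "R^2", "LOF p"),
             fmt_row("---", "---", "---"))
    for (a in names(workflow$models)) {
      m <- workflow$models[[a]]
      out <- c(out, fmt_row(a, sprintf("%.4f", m$r_squared),
                            sprintf("%.4f", m$anova$p_lof)))
    }
    op <- workflow$optimum
    out <- c(out, "", "## Desirability optimum", "",
             paste0("Overall D = ", sprintf("%.4f", op$D)),
             paste0("Coded settings: ",
                    paste(sprintf("%s = %.3f", names(op$coded), op$coded),
                          collapse = ", ")),
             paste0("Natural settings: ",
                    paste(sprintf("%s = %.4g", names(op$natural), op$natural),
                          collapse = ", ")), "")
  } else {
    out <- c(out, "_No workflow artifact supplied; section skipped._", "")
  }
  if (!is.null(matrix_effects)) {
    out <- c(out, "## Matrix effects", "",
             "Legend: none |ME| <= 20%; strong |ME| > 50%; medium otherwise.",
             "",
             fmt_row("analyte", "matrix", "dilution", "ME (%)", "category"),
             fmt_row("---", "---", "---", "---", "---"))
    for (me in matrix_effects) {
      out <- c(out, fmt_row(me$analyte, me$matrix, me$dilution,
                            sprintf("%+d", as.integer(me$me_display)),
                            me$category))
    }
    out <- c(out, "")
  }
  if (!is.null(recoveries)) {
    out <- c(out, "## Recovery and precision", "",
             fmt_row("analyte", "matrix", "level", "mean recovery (%)",
                     "RSD intra (%)", "RSD inter (%)"),
             fmt_row("---", "---", "---", "---", "---", "---"))
    for (r in recoveries) {
      out <- c(out, fmt_row(r$analyte, r$matrix, r$level,
                            sprintf("%.1f", r$mean_recovery),
                            sprintf("%.1f", r$rsd_intra),
                            sprintf("%.1f", r$rsd_inter)))
    }
    out <- c(out, "")
  }
  if (!is.null(budgets)) {
    out <- c(out, "## Measurement uncertainty (bottom-up)", "",
             fmt_row("analyte", "U1", "U2", "U3", "U4", "U_c", "U_exp (%)"),
             fmt_row("---", "---", "---", "---", "---", "---", "---"))
    for (b in budgets) {
      out <- c(out, fmt_row(b$analyte, sprintf("%.4f", b$u1),
                            sprintf("%.4f", b$u2), sprintf("%.4f", b$u3),
                            sprintf("%.4f", b$u4),
                            sprintf("%.4f", round_half_away(b$u_c, 4)),
                            sprintf("%.1f", b$u_exp_percent)))
    }
    out <- c(out, "")
  }
  if (!is.null(survey)) {
    out <- c(out, "## Residue survey", "",
             fmt_row("commodity", "samples", "positives", "ratio (%)"),
             fmt_row("---", "---", "---", "---"))
    pc <- survey$per_commodity
    for (i in seq_len(nrow(pc))) {
      out <- c(out, fmt_row(pc$commodity[i], pc$n[i], pc$positives[i],
                            pc$ratio_pct[i]))
    }
    out <- c(out, "",
             sprintf("Overall: %d of %d samples positive (%d%%).",
                     survey$n_positive, survey$n_samples,
                     survey$positive_pct))
    if (survey$n_positive == 0L) {
      out <- c(out, "No positive samples were found.")
    } else if (!is.null(survey$max_concentration)) {
      mc <- survey$max_concentration
      out <- c(out, sprintf("Highest residue: %.1f ug/kg (%s in %s).",
                            mc$value, mc$analyte, mc$commodity))
    }
    out <- c(out, "")
  }
  out
}
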