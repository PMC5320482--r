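#' Larger-is-better Derringer desirability specification
#'
#' Maps a response onto \[0, 1\]: 0 at or below the lower anchor `L`, 1 at
#' or above the target `T`, and \eqn{((y-L)/(T-L))^s} in between. With
#' `scaling = "auto_range"` the anchors are taken from the span of a
#' model's predictions over the optimization region, so the best
#' achievable point in the region attains a desirability of 1.
#'
#' @param L,T Lower anchor and target (response units), `L < T`. May be
#'   `NA` under `scaling = "auto_range"`, in which case they are filled in
#'   from the model at optimization time.
#' @param s Shape exponent (> 0); 1 is linear.
#' @param scaling `"auto_range"` (default) or `"fixed"`.
#' @return A `"cv_desirability"` spec.
#' @export
desirability_spec <- function(L = NA_real_, T = NA_real_, s = 1,
                              scaling = c("auto_range", "fixed")) {
  scaling <- match.arg(scaling)
  if (s <= 0) stop("exponent s must be > 0", call. = FALSE)
  if (scaling == "fixed") {
    if (is.na(L) || is.na(T)) stop("fixed scaling needs L and T", call. = FALSE)
    if (!(L < T)) stop("need L < T", call. = FALSE)
  } else if (!is.na(L) && !is.na(T) && !(L < T)) {
    stop("need L < T", call. = FALSE)
  }
  structure(list(goal = "maximize", L = L, T = T, s = s, scaling = scaling),
            class = "cv_desirability")
}

#' Partial desirability of a single response value
#'
#' @param y Numeric response value(s).
#' @param spec A [desirability_spec()] with resolved anchors.
#' @return Desirability in \[0, 1\], same length as `y`.
#' @examples
#' partial_desirability(85, desirability_spec(70, 100, scaling = "fixed")) # 0.5
#' @export
partial_desirability <- function(y, spec) {
  stopifnot(inherits(spec, "cv_desirability"))
  if (is.na(spec$L) || is.na(spec$T)) {
    stop("desirability anchors unresolved; supply L and T or optimize with ",
         "auto_range scaling", call. = FALSE)
  }
  u <- (y - spec$L) / (spec$T - spec$L)
  pmin(pmax(u, 0), 1)^spec$s
}

#' Overall desirability (geometric mean)
#'
#' \eqn{D = (\prod d_i)^{1/n}}. Any single zero partial desirability
#' annihilates the product; D always lies between the smallest and largest
#' partials.
#'
#' @param d Numeric vector of partial desirabilities in \[0, 1\].
#' @return Overall desirability D.
#' @export
overall_desirability <- function(d) {
  if (length(d) < 1L) stop("need at least one response", call. = FALSE)
  if (any(d < 0 | d > 1)) {
    stop("partial desirabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

# Resolve auto_range anchors for each model over the region via a dense grid.
resolve_specs <- function(models, specs, lower, upper, grid_n = 21L) {
  f <- models[[1]]$n_factors
  s <- lapply(seq_len(f), function(j) seq(lower[j], upper[j], length.out = grid_n))
  pts <- as.matrix(do.call(expand.grid, s))
  lapply(seq_along(models), function(i) {
    sp <- specs[[i]]
    if (sp$scaling == "auto_range" && (is.na(sp$L) || is.na(sp$T))) {
      pr <- predict(models[[i]], pts)
      sp$L <- min(pr)
      sp$T <- max(pr)
      if (sp$T <= sp$L) sp$T <- sp$L + 1e-9   # flat surface guard
    }
    sp
  })
}

#' Maximize overall desirability over the coded region
#'
#' Evaluates D on a dense multistart grid (default `21^f` points) over the
#' coded box, then refines the best point with bound-constrained
#' quasi-Newton iterations. Ties on the grid break toward the smallest
#' coded norm, then the lowest factor index lexicographically.
#'
#' @param models List of `"cv_quad_model"` fits, one per response, sharing
#'   the same factors.
#' @param specs One [desirability_spec()] per model (a single spec is
#'   recycled).
#' @param lower,upper Coded bounds of the optimization region (defaults
#'   -1 and +1 per factor; extend to the star radius if desired).
#' @param grid_n Multistart grid resolution per axis.
#' @return A `"cv_optimum"` list: `coded`, `natural`, `predictions`,
#'   `partial_d`, `D`, resolved `specs`, and a `diagnostic` naming the
#'   response that annihilates D if D = 0.
#' @export
optimize_desirability <- function(models, specs = desirability_spec(),
                                  lower = NULL, upper = NULL, grid_n = 21L) {
  if (inherits(models, "cv_quad_model")) models <- list(models)
  if (inherits(specs, "cv_desirability")) {
    specs <- rep(list(specs), length(models))
  }
  stopifnot(length(specs) == length(models))
  f <- models[[1]]$n_factors
  nm <- colnames(models[[1]]$design_coded)
  for (m in models) {
    if (m$n_factors != f || !identical(colnames(m$design_coded), nm)) {
      stop("all models must share the same design factors", call. = FALSE)
    }
  }
  if (is.null(lower)) lower <- rep(-1, f)
  if (is.null(upper)) upper <- rep(1, f)
  specs <- resolve_specs(models, specs, lower, upper)

  d_at <- function(pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
    dmat <- vapply(seq_along(models), function(i) {
      partial_desirability(predict(models[[i]], pts), specs[[i]])
    }, numeric(nrow(pts)))
    if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
    apply(dmat, 1L, function(r) if (any(r == 0)) 0 else exp(mean(log(r))))
  }

  s <- lapply(seq_len(f), function(j) seq(lower[j], upper[j], length.out = grid_n))
  grid <- as.matrix(do.call(expand.grid, s))
  Dg <- d_at(grid)
  best <- max(Dg)
  cand <- which(Dg >= best - 1e-12)
  if (length(cand) > 1L) {
    nrm <- rowSums(grid[cand, , drop = FALSE]^2)
    cand <- cand[order(nrm, apply(grid[cand, , drop = FALSE], 1L, paste,
                                  collapse = ","))]
  }
  x0 <- grid[cand[1L], ]

  ref <- stats::optim(x0, function(z) -d_at(z), method = "L-BFGS-B",
                      lower = lower, upper = upper)
  x_star <- if (-ref$value >= best) ref$par else x0
  preds <- vapply(models, function(m) predict(m, matrix(x_star, 1L)), numeric(1))
  dvec <- vapply(seq_along(models), function(i) {
    partial_desirability(preds[i], specs[[i]])
  }, numeric(1))
  D <- overall_desirability(dvec)
  diagnostic <- NULL
  if (D == 0) {
    diagnostic <- paste0("overall desirability is 0 over the region; ",
                         "response(s) at zero partial desirability: ",
                         paste(which(dvec == 0), collapse = ", "))
    warning(diagnostic, call. = FALSE)
  }
  natural <- vapply(seq_len(f), function(j) {
    suppressWarnings(to_natural(x_star[j], models[[1]]$factors[[j]]))
  }, numeric(1))
  names(x_star) <- nm
  names(natural) <- nm
  structure(list(coded = x_star, natural = natural, predictions = preds,
                 partial_d = dvec, D = D, specs = specs,
                 lower = lower, upper = upper, models = models,
                 diagnostic = diagnostic),
            class = "cv_optimum")
}

#' @export
print.cv_optimum <- function(x, ...) {
  cat(sprintf("Desirability optimum: D = %.4f\n", x$D))
  cat("  coded settings:  ",
      paste(sprintf("%s = %.3f", names(x$coded), x$coded), collapse = ", "),
      "\n")
  cat("  natural settings:",
      paste(sprintf("%s = %.4g", names(x$natural), x$natural), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-factor desirability profiles through the optimum
#'
#' For each factor, sweeps that factor across the region while holding the
#' others at the optimum, recording each response's prediction and partial
#' desirability plus the overall D trace — the numeric content of a
#' prediction/desirability profile display.
#'
#' @param optimum A `"cv_optimum"` from [optimize_desirability()].
#' @param n_points Points per trace.
#' @return Named list of data frames (one per factor) with the swept coded
#'   value, `pred_<i>` and `d_<i>` per response, and `D`.
#' @export
desirability_profiles <- function(optimum, n_points = 41L) {
  stopifnot(inherits(optimum, "cv_optimum"))
  models <- optimum$models
  specs <- optimum$specs
  f <- length(optimum$coded)
  nm <- names(optimum$coded)
  out <- vector("list", f)
  names(out) <- nm
  for (j in seq_len(f)) {
    sweep <- seq(optimum$lower[j], optimum$upper[j], length.out = n_points)
    pts <- matrix(rep(optimum$coded, each = n_points), nrow = n_points)
    pts[, j] <- sweep
    df <- data.frame(value = sweep)
    names(df) <- nm[j]
    dmat <- matrix(NA_real_, n_points, length(models))
    for (i in seq_along(models)) {
      pr <- predict(models[[i]], pts)
      di <- partial_desirability(pr, specs[[i]])
      df[[paste0("pred_", i)]] <- pr
      df[[paste0("d_", i)]] <- di
      dmat[, i] <- di
    }
    df$D <- apply(dmat, 1L, function(r) if (any(r == 0)) 0 else exp(mean(log(r))))
    out[[j]] <- df
  }
  out
}
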