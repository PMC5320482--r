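#' Fit a full second-order response-surface model
#'
#' Ordinary least squares on the complete quadratic basis in coded units:
#' intercept, the `f` linear terms, the `f` pure quadratics and the
#' `f(f-1)/2` two-way interactions (10 terms for three factors). Fitting in
#' coded units keeps the basis well conditioned and the coefficients
#' directly comparable; natural-unit coefficients are a reporting
#' transformation only.
#'
#' @param design A `"cv_design"` (typically from [ccd_design()]).
#' @param responses Numeric responses aligned with the design rows.
#' @return A `"cv_quad_model"` list: `coef` (named vector), `coef_table`
#'   (coefficient, se, t, p), `r_squared`, `sigma`, `fitted`, `residuals`,
#'   `anova` (model / residual / lack-of-fit / pure-error decomposition),
#'   `factors`, `terms`.
#' @export
fit_quadratic <- function(design, responses) {
  stopifnot(inherits(design, "cv_design"))
  x <- design$coded
  if (length(responses) != nrow(x)) {
    stop("responses not aligned with design rows", call. = FALSE)
  }
  f <- ncol(x)
  X <- quad_basis(x)
  p <- ncol(X)
  if (nrow(unique(x)) < p) {
    stop("singular design: ", nrow(unique(x)), " distinct points cannot ",
         "support the ", p, "-term quadratic basis", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: collinear terms ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, responses)
  beta <- fit$coefficients
  fitted <- drop(X %*% beta)
  resid <- responses - fitted
  n <- length(responses)
  df_res <- n - p
  ss_res <- sum(resid^2)
  ybar <- mean(responses)
  ss_tot <- sum((responses - ybar)^2)
  ss_mod <- ss_tot - ss_res
  r2 <- if (ss_tot == 0) {
    warning("zero-variance response: R^2 defined as 0", call. = FALSE)
    0
  } else 1 - ss_res / ss_tot
  sigma2 <- if (df_res > 0) ss_res / df_res else NA_real_
  XtXinv <- solve(crossprod(X))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tv <- beta / se
  pv <- 2 * stats::pt(-abs(tv), df = df_res)
  coef_table <- data.frame(term = colnames(X), coefficient = unname(beta),
                           se = unname(se), t_value = unname(tv),
                           p_value = unname(pv), stringsAsFactors = FALSE)
  an <- list(
    ss_model = ss_mod, df_model = p - 1L,
    ss_residual = ss_res, df_residual = df_res,
    f_model = if (df_res > 0 && sigma2 > 0)
      (ss_mod / (p - 1L)) / sigma2 else NA_real_,
    p_model = if (df_res > 0 && sigma2 > 0)
      stats::pf((ss_mod / (p - 1L)) / sigma2, p - 1L, df_res,
                lower.tail = FALSE) else NA_real_
  )
  model <- structure(list(
    coef = beta, coef_table = coef_table, r_squared = r2,
    sigma = sqrt(sigma2), fitted = fitted, residuals = resid,
    anova = an, factors = design$factors, n_factors = f,
    design_coded = x, responses = responses
  ), class = "cv_quad_model")
  anova_lof(model, design, responses)
}

# Full quadratic basis matrix in coded units; term naming x1, x1^2, x1:x2.
quad_basis <- function(x) {
  f <- ncol(x)
  nm <- colnames(x) %||% paste0("x", seq_len(f))
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  for (j in seq_len(f)) cols[[nm[j]]] <- x[, j]
  for (j in seq_len(f)) cols[[paste0(nm[j], "^2")]] <- x[, j]^2
  if (f >= 2) {
    for (i in seq_len(f - 1)) for (j in (i + 1):f) {
      cols[[paste0(nm[i], ":", nm[j])]] <- x[, i] * x[, j]
    }
  }
  do.call(cbind, cols)
}

#' Lack-of-fit ANOVA for a response-surface model
#'
#' Partitions the residual sum of squares into pure error (pooled within
#' replicated design points) and lack of fit, and tests
#' \eqn{F = (SS_{lof}/df_{lof}) / (SS_{pe}/df_{pe})}. A non-significant
#' lack of fit (p > 0.05) supports the quadratic model.
#'
#' @param model A `"cv_quad_model"`.
#' @param design,responses The design and responses the model was fit to.
#' @return The model with an extended `anova` element (`ss_pe`, `df_pe`,
#'   `ss_lof`, `df_lof`, `f_lof`, `p_lof`, `lof_available`).
#' @export
anova_lof <- function(model, design, responses) {
  stopifnot(inherits(model, "cv_quad_model"))
  x <- design$coded
  key <- apply(x, 1L, paste, collapse = "\r")
  groups <- split(responses, key)
  reps <- groups[lengths(groups) > 1L]
  an <- model$anova
  if (length(reps) == 0L) {
    warning("no replicated design points: lack-of-fit test unavailable",
            call. = FALSE)
    an$lof_available <- FALSE
    an[c("ss_pe", "df_pe", "ss_lof", "df_lof", "f_lof", "p_lof")] <- NA_real_
  } else {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1L)
    ss_lof <- max(an$ss_residual - ss_pe, 0)
    df_lof <- an$df_residual - df_pe
    an$lof_available <- df_lof > 0L
    an$ss_pe <- ss_pe
    an$df_pe <- df_pe
    an$ss_lof <- ss_lof
    an$df_lof <- df_lof
    if (an$lof_available && ss_pe > 0) {
      an$f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
      an$p_lof <- stats::pf(an$f_lof, df_lof, df_pe, lower.tail = FALSE)
    } else {
      an$f_lof <- NA_real_
      an$p_lof <- NA_real_
    }
  }
  model$anova <- an
  model
}

#' @export
print.cv_quad_model <- function(x, ...) {
  cat(sprintf("Second-order model in %d factors: R^2 = %.4f\n",
              x$n_factors, x$r_squared))
  if (isTRUE(x$anova$lof_available)) {
    cat(sprintf("  lack of fit: F(%d, %d) = %.3f, p = %.4f\n",
                x$anova$df_lof, x$anova$df_pe, x$anova$f_lof, x$anova$p_lof))
  }
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' @param object A `"cv_quad_model"`.
#' @param newdata Matrix (or vector for a single point) of coded
#'   coordinates, one column per factor.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.cv_quad_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$n_factors) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$n_factors, call. = FALSE)
  }
  colnames(newdata) <- colnames(object$design_coded)
  unname(drop(quad_basis(newdata) %*% object$coef))
}

#' Numeric response-surface grid for a pair of factors
#'
#' Evaluates the model over an `grid_n` x `grid_n` lattice spanning the
#' coded region for two chosen axes, holding the remaining factors fixed —
#' the numeric content of a 3-D surface plot.
#'
#' @param model A `"cv_quad_model"`.
#' @param axes Integer or character vector of length 2: which factors vary.
#' @param fixed Coded values for the remaining factors (default 0).
#' @param grid_n Points per axis (default 21).
#' @param limits Coded range spanned by each axis (default `c(-1, 1)`).
#' @return Long-format data frame with the two axis coordinates and
#'   `prediction`; also carries the prediction matrix as attribute
#'   `"matrix"`.
#' @export
surface_grid <- function(model, axes, fixed = NULL, grid_n = 21L,
                         limits = c(-1, 1)) {
  stopifnot(inherits(model, "cv_quad_model"), length(axes) == 2L)
  nm <- colnames(model$design_coded)
  if (is.character(axes)) axes <- match(axes, nm)
  if (anyNA(axes)) stop("unknown axis name", call. = FALSE)
  f <- model$n_factors
  others <- setdiff(seq_len(f), axes)
  if (is.null(fixed)) fixed <- rep(0, length(others))
  s <- seq(limits[1], limits[2], length.out = grid_n)
  g <- expand.grid(a = s, b = s)
  pts <- matrix(0, nrow = nrow(g), ncol = f)
  pts[, axes[1]] <- g$a
  pts[, axes[2]] <- g$b
  for (k in seq_along(others)) pts[, others[k]] <- fixed[k]
  pred <- predict(model, pts)
  out <- data.frame(g$a, g$b, prediction = pred)
  names(out)[1:2] <- nm[axes]
  attr(out, "matrix") <- matrix(pred, nrow = grid_n, ncol = grid_n)
  out
}
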