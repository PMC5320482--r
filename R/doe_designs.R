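#' Define an experimental factor
#'
#' A factor is a continuous variable studied between a low and a high
#' natural level, e.g. toluene percentage of the extraction solvent
#' (0--100 % v/v) or the mass of a dispersive cleanup sorbent (mg).
#' Coded units map the range linearly onto \[-1, +1\].
#'
#' @param name Factor name, unique within a design.
#' @param low Low natural level (coded -1).
#' @param high High natural level (coded +1); must exceed `low`.
#' @param symbol Optional short symbol such as `"X1"`.
#' @return An object of class `"cv_factor"`.
#' @examples
#' doe_factor("toluene_pct", 0, 100, "X1")
#' @export
doe_factor <- function(name, low, high, symbol = name) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low < high)) {
    stop("factor '", name, "': low level must be strictly below high level",
         call. = FALSE)
  }
  structure(list(name = name, low = low, high = high, symbol = symbol),
            class = "cv_factor")
}

#' @export
print.cv_factor <- function(x, ...) {
  cat(sprintf("Factor %s (%s): [%g, %g]\n", x$name, x$symbol, x$low, x$high))
  invisible(x)
}

# Standard cyclic generator row of the 12-run Plackett-Burman design.
.pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

.pb12_matrix <- function() {
  g <- .pb12_generator
  m <- matrix(0, nrow = 12L, ncol = 11L)
  for (i in 1:11) {
    # row i is the generator cyclically shifted right by i - 1
    m[i, ] <- g[((seq_len(11L) - i) %% 11L) + 1L]
  }
  m[12L, ] <- -1
  m
}

.new_design <- function(factors, coded, point_type, seed = NA_integer_) {
  names(factors) <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(names(factors))) {
    stop("factor names must be unique within a design", call. = FALSE)
  }
  colnames(coded) <- names(factors)
  structure(list(
    factors = factors,
    coded = coded,
    point_type = point_type,
    run_order = seq_len(nrow(coded)),
    seed = seed
  ), class = "cv_design")
}

#' Generate a 12-run Plackett--Burman screening design
#'
#' Builds the standard 12-run two-level orthogonal screening design from
#' the cyclic generator row (+ + - + + + - - - + -) with a final all-minus
#' row, keeps the first `length(factors)` columns, and appends `n_center`
#' all-zero center-point rows used to estimate pure error.
#'
#' @param factors List of [doe_factor()] objects (2 to 11 of them).
#' @param n_center Number of center-point replicates (>= 0).
#' @return A `"cv_design"` object with a `coded` run-by-factor matrix and a
#'   `point_type` vector (`"factorial"` / `"center"`).
#' @examples
#' f <- list(doe_factor("toluene_pct", 0, 100), doe_factor("hcl_pct", 0, 0.5),
#'           doe_factor("psa_mg", 0, 50), doe_factor("c18_mg", 0, 20),
#'           doe_factor("gcb_mg", 0, 20))
#' d <- pb_design(f, n_center = 3)
#' nrow(d$coded)  # 15 runs
#' @export
pb_design <- function(factors, n_center = 3L) {
  k <- length(factors)
  if (k < 2L || k > 11L) {
    stop("Plackett-Burman 12-run design supports 2 to 11 factors, got ", k,
         call. = FALSE)
  }
  if (n_center < 0L) stop("n_center must be >= 0", call. = FALSE)
  full <- .pb12_matrix()
  coded <- full[, seq_len(k), drop = FALSE]
  if (n_center > 0L) {
    coded <- rbind(coded, matrix(0, nrow = n_center, ncol = k))
  }
  pt <- c(rep("factorial", 12L), rep("center", n_center))
  d <- .new_design(factors, coded, pt)
  d$design_type <- "plackett_burman"
  d
}

#' Generate a central composite design
#'
#' A CCD joins a \eqn{2^f} two-level factorial block, \eqn{2f} axial
#' ("star") points at distance \eqn{\pm\alpha} on each axis, and replicated
#' center points. With the rotatable choice \eqn{\alpha = (2^f)^{1/4}} the
#' prediction variance of the fitted quadratic depends only on the distance
#' from the design center.
#'
#' @param factors List of [doe_factor()] objects (2 to 6).
#' @param alpha_mode `"rotatable"` (default), `"face_centered"` (alpha = 1),
#'   or `"custom"`.
#' @param alpha Axial distance when `alpha_mode = "custom"`.
#' @param n_center Center replicates; at least 1 (pure error needs
#'   replication, and the default 6 gives the classic 20-run design for
#'   three factors).
#' @return A `"cv_design"` object; `point_type` marks rows as `"factorial"`,
#'   `"star"` or `"center"`.
#' @examples
#' f <- list(doe_factor("toluene_pct", 0, 100), doe_factor("hcl_pct", 0, 0.5),
#'           doe_factor("gcb_mg", 0, 20))
#' d <- ccd_design(f)
#' attr(d, "alpha")        # 1.68179 for f = 3
#' table(d$point_type)
#' @export
ccd_design <- function(factors, alpha_mode = c("rotatable", "face_centered", "custom"),
                       alpha = NULL, n_center = 6L) {
  alpha_mode <- match.arg(alpha_mode)
  f <- length(factors)
  if (f < 2L || f > 6L) {
    stop("central composite design supports 2 to 6 factors, got ", f,
         call. = FALSE)
  }
  if (n_center < 1L) {
    stop("n_center must be >= 1: pure error requires center replication",
         call. = FALSE)
  }
  a <- switch(alpha_mode,
    rotatable = (2^f)^(1 / 4),
    face_centered = 1,
    custom = {
      if (is.null(alpha) || !is.numeric(alpha) || alpha <= 0) {
        stop("alpha_mode = 'custom' needs a positive alpha", call. = FALSE)
      }
      alpha
    })
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), f)))
  star <- matrix(0, nrow = 2L * f, ncol = f)
  for (j in seq_len(f)) {
    star[2L * j - 1L, j] <- -a
    star[2L * j, j] <- a
  }
  center <- matrix(0, nrow = n_center, ncol = f)
  coded <- rbind(fact, star, center)
  pt <- c(rep("factorial", nrow(fact)), rep("star", nrow(star)),
          rep("center", n_center))
  d <- .new_design(factors, coded, pt)
  d$design_type <- "central_composite"
  attr(d, "alpha") <- a
  d
}

#' @export
print.cv_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors (%s)\n",
              x$design_type, nrow(x$coded), ncol(x$coded),
              paste(sprintf("%d %s", table(x$point_type)[unique(x$point_type)],
                            unique(x$point_type)), collapse = ", ")))
  invisible(x)
}

#' Convert between natural and coded factor units
#'
#' Coded units place the center of the factor range at 0 and the half-range
#' at 1, so the low and high levels sit at -1 and +1. Star points may code
#' beyond \[-1, +1\] and hence map to natural values outside the stated
#' range; [to_natural()] clamps at physical zero (with a warning) when
#' `clamp_zero = TRUE`, which matters for sorbent masses that cannot go
#' negative.
#'
#' @param value Numeric vector in natural (resp. coded) units.
#' @param factor A [doe_factor()].
#' @param clamp_zero Clamp negative natural values to 0 (default TRUE).
#' @return Numeric vector of the same length.
#' @examples
#' tol <- doe_factor("toluene_pct", 0, 100)
#' to_coded(50, tol)   # 0
#' to_natural(1, tol)  # 100
#' @export
to_coded <- function(value, factor) {
  mid <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  (value - mid) / half
}

#' @rdname to_coded
#' @export
to_natural <- function(value, factor, clamp_zero = TRUE) {
  mid <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  nat <- mid + value * half
  if (clamp_zero && any(nat < 0)) {
    warning("natural value(s) below physical zero for factor '",
            factor$name, "' clamped to 0", call. = FALSE)
    nat[nat < 0] <- 0
  }
  nat
}

#' Randomize the run order of a design
#'
#' Stores a seeded permutation in `run_order`; the coded matrix itself is
#' left untouched so effects and model fits are unchanged by randomization.
#'
#' @param design A `"cv_design"`.
#' @param seed Integer seed; the same seed always yields the same order.
#' @return The design with a permuted `run_order` and recorded `seed`.
#' @export
randomize_run_order <- function(design, seed) {
  stopifnot(inherits(design, "cv_design"))
  n <- nrow(design$coded)
  design$run_order <- with_seed(seed, sample.int(n))
  design$seed <- as.integer(seed)
  design
}

#' Export / import a design as a data frame
#'
#' The CSV dialect carries `run_id`, `point_type`, one coded column per
#' factor (`<name>_coded`), one natural-unit column per factor, and
#' `run_order`.
#'
#' @param design A `"cv_design"`.
#' @return `design_table()`: a data frame; `write_design()` writes it as
#'   UTF-8 CSV and returns the path invisibly.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "cv_design"))
  coded <- design$coded
  nat <- coded
  for (j in seq_along(design$factors)) {
    nat[, j] <- suppressWarnings(to_natural(coded[, j], design$factors[[j]]))
  }
  out <- data.frame(run_id = seq_len(nrow(coded)),
                    point_type = design$point_type,
                    stringsAsFactors = FALSE)
  cn <- colnames(coded)
  for (j in seq_along(cn)) out[[paste0(cn[j], "_coded")]] <- coded[, j]
  for (j in seq_along(cn)) out[[cn[j]]] <- nat[, j]
  out$run_order <- design$run_order
  out
}

#' @rdname design_table
#' @param path File path for the CSV.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design_table(design), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
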