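# Shared fixtures: the five screening factors and the three optimization
# factors used throughout the tests, built in code.

factors5 <- function() {
  list(
    doe_factor("toluene_pct", 0, 100, "X1"),
    doe_factor("hcl_pct", 0, 0.5, "X2"),
    doe_factor("psa_mg", 0, 50, "X3"),
    doe_factor("c18_mg", 0, 20, "X4"),
    doe_factor("gcb_mg", 0, 20, "X5")
  )
}

factors3 <- function() factors5()[c(1, 2, 5)]

# Evaluate a named quadratic coefficient vector on coded points (oracle-side
# surface evaluation, independent of the model object).
eval_quad <- function(beta, x) {
  f <- ncol(x)
  y <- rep(beta[1], nrow(x))
  for (j in seq_len(f)) y <- y + beta[1 + j] * x[, j] + beta[1 + f + j] * x[, j]^2
  k <- 1 + 2 * f
  if (f >= 2) {
    for (i in seq_len(f - 1)) for (j in (i + 1):f) {
      k <- k + 1
      y <- y + beta[k] * x[, i] * x[, j]
    }
  }
  y
}
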