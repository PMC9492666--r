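# Independent oracles used to cross-check the implementation.

# Brute-force least-squares oracle for the median-effect linearization:
# coarse grid over (log10 Dm, m) followed by Nelder-Mead polish of the
# transformed-coordinate SSE. Shares no code with fit_median_effect().
oracle_median_effect <- function(dose, fa, fa_bounds = c(0.005, 0.995)) {
  keep <- fa > fa_bounds[1] & fa < fa_bounds[2]
  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  sse <- function(p) sum((y - (p[2] * x - p[2] * p[1]))^2)  # p = (log10 Dm, m)
  grid <- expand.grid(logDm = seq(-3, 3, by = 0.1), m = seq(0.1, 6, by = 0.1))
  vals <- mapply(function(a, b) sse(c(a, b)), grid$logDm, grid$m)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
  list(Dm = 10^opt$par[1], m = opt$par[2], sse = opt$value)
}

# transformed-coordinate SSE of any (Dm, m) pair against a series
me_sse <- function(Dm, m, dose, fa, fa_bounds = c(0.005, 0.995)) {
  keep <- fa > fa_bounds[1] & fa < fa_bounds[2]
  x <- log10(dose[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  sum((y - (m * x - m * log10(Dm)))^2)
}

# Bisection oracle for the Loewe-additive total dose at effect level fa for
# a fixed-ratio mixture of two median-effect agents: solves
# r1*D/Dx1(fa) + r2*D/Dx2(fa) = 1 for D by geometric bisection.
oracle_loewe_dose <- function(params_a, params_b, ratio, fa,
                              lo = 1e-9, hi = 1e9) {
  Dx <- function(p) p$Dm * (fa / (1 - fa))^(1 / p$m)
  g <- function(D) ratio[1] * D / Dx(params_a) + ratio[2] * D / Dx(params_b) - 1
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# closed-form ground-truth TGI for exponential growth
true_tgi <- function(g_control, g_treated, horizon) {
  100 * (exp(g_control * horizon) - exp(g_treated * horizon)) /
    (exp(g_control * horizon) - 1)
}
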