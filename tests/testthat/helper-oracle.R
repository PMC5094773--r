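# Numerical-integration oracle for the generator's first-visit CL mean.
# Non-cerclage subgroups sample CL_A from a plain truncated normal; cerclage
# subgroups additionally condition on at least one *observed* visit below
# the insertion threshold, which shifts the marginal. This computes
# E[CL_A | event] by quadrature over (CL_A, f_AB, f_BC) and the missingness
# patterns, independent of the sampling code.
oracle_forced_cl_a_mean <- function(p, bounds = c(5, 60), thr = 25,
                                    n_a = 3000, n_f = 800) {
  ptn <- function(q, mu, sd, lo, hi) {
    (stats::pnorm(pmin(pmax(q, lo), hi), mu, sd) - stats::pnorm(lo, mu, sd)) /
      (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd))
  }
  dtn <- function(x, mu, sd, lo, hi) {
    stats::dnorm(x, mu, sd) / (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd))
  }
  clip <- function(x) pmin(pmax(x, bounds[1]), bounds[2])

  a_grid <- seq(bounds[1], bounds[2], length.out = n_a)
  f_grid <- seq(-50, 95, length.out = n_f)
  wf <- dtn(f_grid, p$mu_pct_ab, p$sd_pct_ab, -50, 95)
  wf <- wf / sum(wf)

  cl_b <- clip(outer(a_grid, 1 - f_grid / 100))        # n_a x n_f
  # P(CL_C >= thr | cl_b): needs f_BC <= 100 (1 - thr / cl_b)
  pc <- ptn(100 * (1 - thr / cl_b), p$mu_pct_bc, p$sd_pct_bc, -50, 95)
  q_c <- as.vector(pc %*% wf)                          # P(C long)
  q_bc <- as.vector((pc * (cl_b >= thr)) %*% wf)       # P(B and C long)
  q_b <- ptn(100 * (1 - thr / a_grid), p$mu_pct_ab, p$sd_pct_ab, -50, 95)

  oa <- 1 - p$p_missing_a
  ob <- 1 - p$p_missing_b
  oc <- 1 - p$p_missing_c
  a_long <- as.numeric(a_grid >= thr)
  no_event <- 0
  for (sa in 0:1) for (sb in 0:1) for (sc in 0:1) {
    if (sa + sb + sc == 0) next   # all-missing patterns are redrawn
    w <- (if (sa) oa else 1 - oa) * (if (sb) ob else 1 - ob) *
      (if (sc) oc else 1 - oc)
    bc <- if (sb && sc) q_bc else if (sb) q_b else if (sc) q_c else 1
    no_event <- no_event + w * (if (sa) a_long else 1) * bc
  }
  no_event <- no_event / (1 - (1 - oa) * (1 - ob) * (1 - oc))
  p_event <- 1 - no_event

  da <- dtn(a_grid, p$mu_cl_a, p$sd_cl_a, bounds[1], bounds[2])
  sum(a_grid * da * p_event) / sum(da * p_event)
}
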