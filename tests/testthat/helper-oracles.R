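# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force one-set-of-sites equilibrium per injection: solve the mass
# balance (X_t - MX)(n*M_t - MX) = Kd * MX numerically instead of via the
# closed-form quadratic, then apply the definitional heat bookkeeping.
oracle_itc_heats <- function(protocol, kd_nM, dh_kcal, n,
                             dilution_correction = TRUE) {
  v0 <- protocol$cell_volume_ml
  kd_uM <- kd_nM / 1000
  f_step <- 1 - protocol$injection_ul / 1000 / v0
  m <- protocol$cell_uM * cumprod(f_step)
  x <- numeric(length(f_step))
  xi <- 0
  for (i in seq_along(f_step)) {
    xi <- xi * f_step[i] + protocol$syringe_uM * (1 - f_step[i])
    x[i] <- xi
  }
  q_cum <- vapply(seq_along(m), function(i) {
    sites <- n * m[i]
    upper <- min(x[i], sites)
    if (upper <= 0) return(0)
    g <- function(mx) (x[i] - mx) * (sites - mx) - kd_uM * mx
    mx <- uniroot(g, c(0, upper), tol = 1e-14)$root
    theta <- mx / sites
    n * theta * m[i] * dh_kcal * v0
  }, numeric(1))
  q_prev <- c(0, head(q_cum, -1))
  dq <- q_cum - q_prev
  if (dilution_correction) {
    dq <- dq + (protocol$injection_ul / 1000 / v0) * (q_cum + q_prev) / 2
  }
  dq
}

# Pixel-count oracle: which pixel centres satisfy the ellipse inequality.
oracle_ellipse_pixels <- function(nr, nc, cx, cy, a, b, angle = 0) {
  count <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      dx <- cc - cx; dy <- r - cy
      u <- dx * cos(angle) + dy * sin(angle)
      v <- -dx * sin(angle) + dy * cos(angle)
      if ((u / a)^2 + (v / b)^2 <= 1) count <- count + 1L
    }
  }
  count
}

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
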