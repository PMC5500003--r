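#' Hill equation for fraction of RNA bound
#'
#' Evaluates \eqn{y = 1 / (1 + (K_d / x)^n)}: the fraction of trace RNA
#' bound at free protein concentration `x`, with dissociation constant
#' `kd` and Hill coefficient `n` (cooperativity for `n > 1`). Strictly
#' increasing in `x`; equals 0.5 exactly at `x = kd`.
#'
#' @param x Protein concentration, nM (> 0; vectorised).
#' @param kd Dissociation constant, nM (> 0).
#' @param n Hill coefficient (> 0).
#' @return Fraction bound in (0, 1).
#' @examples
#' hill_fraction(460, kd = 460, n = 2.8) # exactly 0.5
#' @export
hill_fraction <- function(x, kd, n) {
  if (any(x <= 0)) rlang::abort("`x` must be > 0.")
  if (kd <= 0 || n <= 0) rlang::abort("`kd` and `n` must be > 0.")
  1 / (1 + (kd / x)^n)
}

validate_titration <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("conc_nM", "fraction_bound") %in% names(data)))
  x <- data$conc_nM
  y <- data$fraction_bound
  if (length(x) < 4) rlang::abort("A titration needs at least 4 points to fit.")
  if (any(x <= 0)) rlang::abort("Concentrations must be strictly positive.")
  if (is.unsorted(x, strictly = TRUE)) {
    rlang::abort("Concentrations must be strictly increasing.")
  }
  if (any(y < 0 | y > 1)) rlang::abort("Fractions bound must lie in [0, 1].")
  invisible(data)
}

#' Fit a gel-shift titration to the Hill equation
#'
#' Nonlinear least squares of [hill_fraction()] to a fraction-bound
#' titration (bounded Levenberg-Marquardt via [minpack.lm::nlsLM()]).
#' Starting values are `kd` at the concentration whose fraction bound is
#' nearest 0.5 and `n = 1`. Standard errors come from the Jacobian at
#' the optimum; a seeded residual bootstrap is available instead.
#' Degenerate inputs (flat curves, all-0/all-1 fractions) are refused or
#' returned with `converged = FALSE` rather than silently reported.
#'
#' @param data Data frame with columns `conc_nM` (strictly increasing
#'   and positive, at least 4 points) and `fraction_bound` (in `[0, 1]`).
#' @param init Optional named list/vector with starting `kd` and `n`.
#' @param lower,upper Box constraints for `c(kd, n)`, nM and
#'   dimensionless.
#' @param bootstrap If `TRUE`, standard errors by resampling residuals.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#'
#' @return An object of class `hill_fit` with [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods. Key fields: `kd`, `n`, `kd_se`,
#'   `n_se`, `converged`.
#' @examples
#' curve <- sim_binding_curve(kd = 460, n = 2.8, noise_sd = 0, seed = 1)
#' fit <- fit_hill(curve)
#' glance(fit)
#' @export
fit_hill <- function(data, init = NULL, lower = c(kd = 1, n = 0.2),
                     upper = c(kd = 1e5, n = 8), bootstrap = FALSE,
                     n_boot = 500, seed = NULL) {
  validate_titration(data)
  x <- data$conc_nM
  y <- data$fraction_bound
  if (all(y == 0) || all(y == 1)) {
    rlang::abort("Titration carries no binding information (all fractions 0 or 1).")
  }
  identifiable <- diff(range(y)) > 1e-3
  if (is.null(init)) {
    init <- list(kd = x[which.min(abs(y - 0.5))], n = 1)
  }
  init$kd <- min(max(init$kd, lower[["kd"]]), upper[["kd"]])
  init$n <- min(max(init$n, lower[["n"]]), upper[["n"]])
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + (kd / x)^n),
      data = df, start = init,
      lower = unname(lower[c("kd", "n")]),
      upper = unname(upper[c("kd", "n")]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- structure(
      list(kd = init$kd, n = init$n, kd_se = NA_real_, n_se = NA_real_,
           converged = FALSE, data = tibble::as_tibble(data),
           fitted = rep(NA_real_, length(y)), rss = NA_real_),
      class = "hill_fit"
    )
    return(out)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  converged <- identifiable && isTRUE(fit$convInfo$isConv)
  # parameters pinned to a box edge mean the optimizer left the region of
  # trust; report them but flag
  at_edge <- any(abs(est - lower[c("kd", "n")]) < 1e-8) ||
    any(abs(est - upper[c("kd", "n")]) < 1e-8)
  if (at_edge) converged <- FALSE
  if (bootstrap) {
    if (!is.null(seed)) set.seed(seed)
    res <- y - fitted(fit)
    boot <- replicate(n_boot, {
      yb <- pmin(pmax(fitted(fit) + sample(res, replace = TRUE), 0), 1)
      fb <- tryCatch(
        coef(minpack.lm::nlsLM(
          yb ~ 1 / (1 + (kd / x)^n),
          data = data.frame(x = x, yb = yb),
          start = as.list(est),
          lower = unname(lower[c("kd", "n")]),
          upper = unname(upper[c("kd", "n")])
        )),
        error = function(e) c(kd = NA_real_, n = NA_real_)
      )
      fb
    })
    se <- apply(boot, 1, sd, na.rm = TRUE)
  }
  structure(
    list(kd = unname(est[["kd"]]), n = unname(est[["n"]]),
         kd_se = unname(se[[1]]), n_se = unname(se[[2]]),
         converged = converged, data = tibble::as_tibble(data),
         fitted = as.numeric(fitted(fit)),
         rss = sum((y - fitted(fit))^2)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> Kd = %.3g +/- %.2g nM, n = %.3g +/- %.2g (%s)\n",
    x$kd, x$kd_se, x$n, x$n_se,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "n"),
    estimate = c(x$kd, x$n),
    std.error = c(x$kd_se, x$n_se)
  )
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$kd, kd_se = x$kd_se, n = x$n, n_se = x$n_se,
    rss = x$rss, nobs = nrow(x$data), converged = x$converged
  )
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble::tibble(
    conc_nM = exp(seq(log(min(object$data$conc_nM)),
                      log(max(object$data$conc_nM)), length.out = 200))
  )
  grid$fraction_bound <- hill_fraction(grid$conc_nM, object$kd, object$n)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_nM, y = .data$fraction_bound)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (nM)", y = "fraction RNA bound") +
    ggplot2::theme_minimal()
}

#' Stoichiometric saturation binding curves
#'
#' Theoretical fraction of protein bound at a protein:RNA molar ratio
#' `r` when each RNA binds `m` proteins. In the default tight-binding
#' (stoichiometric) limit the fraction is `min(1, m / r)`: all protein
#' is bound while RNA sites remain, then the bound fraction falls as
#' `m / r`. Supplying a finite per-site `kd_nM` (with the absolute RNA
#' concentration `rna_nM`) switches to the per-site mass-balance
#' quadratic for `m` independent sites.
#'
#' @param r Protein:RNA molar ratio (> 0; vectorised).
#' @param m Stoichiometry, integer 1-6.
#' @param kd_nM Optional per-site dissociation constant, nM; `NULL` for
#'   the tight-binding limit.
#' @param rna_nM Total RNA concentration (nM) used by the finite-affinity
#'   variant; default 2600 (the 2.6 uM of the stoichiometric gel shifts).
#' @return Fraction of protein bound, in `[0, 1]`.
#' @examples
#' saturation_bound_fraction(4, m = 2) # 0.5
#' @export
saturation_bound_fraction <- function(r, m, kd_nM = NULL, rna_nM = 2600) {
  if (any(r <= 0)) rlang::abort("`r` must be > 0.")
  if (length(m) != 1 || !m %in% 1:6) rlang::abort("`m` must be an integer in 1..6.")
  if (is.null(kd_nM)) {
    return(pmin(1, m / r))
  }
  stopifnot(kd_nM > 0, rna_nM > 0)
  p0 <- r * rna_nM
  s0 <- m * rna_nM
  b <- p0 + s0 + kd_nM
  bound <- (b - sqrt(b^2 - 4 * p0 * s0)) / 2
  pmin(1, pmax(0, bound / p0))
}

#' Family of saturation curves over stoichiometries
#'
#' Evaluates [saturation_bound_fraction()] for each stoichiometry on a
#' shared molar-ratio grid, as plotted against stoichiometric gel-shift
#' data.
#'
#' @param m Stoichiometries (subset of 1..6).
#' @param r Molar-ratio grid (> 0).
#' @inheritParams saturation_bound_fraction
#' @return A tibble with columns `m`, `ratio`, `fraction_bound`.
#' @examples
#' saturation_curves()
#' @export
saturation_curves <- function(m = 1:6, r = seq(0.25, 16, by = 0.25),
                              kd_nM = NULL, rna_nM = 2600) {
  purrr::map(m, function(mi) {
    tibble::tibble(
      m = mi, ratio = r,
      fraction_bound = saturation_bound_fraction(r, mi, kd_nM, rna_nM)
    )
  }) %>% dplyr::bind_rows()
}

#' Read a titration table from CSV
#'
#' @param path CSV with columns `conc_nM`, `fraction_bound`.
#' @return A validated tibble.
#' @export
read_titration <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_titration(data)
  tibble::as_tibble(data)
}
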