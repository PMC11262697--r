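# Dose-response and time-course regression fits for the junction-number
# analyses. Nonlinear fits use Levenberg-Marquardt (minpack.lm) with
# data-driven starting values and a multi-start fallback.

.fit_metrics <- function(y, fitted, n_par) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  n <- length(y)
  adj <- if (n - n_par - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - n_par - 1) else NA_real_
  list(r_squared = r2, adj_r_squared = adj)
}

.nls_multistart <- function(formula, data, starts_list, ...) {
  best <- NULL
  errs <- character()
  for (st in starts_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500), ...),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    stop("nonlinear fit did not converge from any start: ",
         paste(unique(errs), collapse = "; "))
  }
  best
}

#' Saturating-exponential dose-response fit
#'
#' Fits `f(P) = a - b * exp(-c * P)`, the asymptotic form of the junction
#' number against a single dose-like parameter (used both for the
#' VEGF-parameter and for the binding-site sweeps).
#'
#' @param x parameter values.
#' @param y response (junction numbers).
#' @return list with `coefficients` (`a`, `b`, `c`), `r_squared`,
#'   `adj_r_squared`, `fitted`, and the `nls` fit object.
#' @export
fit_saturating_exp <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 3)
  a0 <- max(y) + 0.05 * abs(max(y))
  b0 <- max(a0 - min(y), .Machine$double.eps)
  # crude rate guess from the x-scale, plus log-linear refinement
  c0s <- 1 / pmax(abs(mean(x)), abs(diff(range(x))), .Machine$double.xmin)
  pos <- which(a0 - y > 0)
  if (length(pos) >= 2) {
    lf <- lm(log(a0 - y[pos]) ~ x[pos])
    if (is.finite(coef(lf)[2]) && coef(lf)[2] < 0) c0s <- c(-coef(lf)[2], c0s)
  }
  starts <- lapply(c0s, function(cc) list(a = a0, b = b0, c = cc))
  starts <- c(starts, lapply(c0s, function(cc) list(a = max(y), b = b0, c = cc * 5)))
  d <- data.frame(x = x, y = y)
  fit <- .nls_multistart(y ~ a - b * exp(-c * x), d, starts)
  co <- coef(fit)
  m <- .fit_metrics(y, fitted(fit), 3)
  list(coefficients = co, r_squared = m$r_squared,
       adj_r_squared = m$adj_r_squared, fitted = fitted(fit), fit = fit)
}

#' Linear dose-response fit
#'
#' Fits `f(x) = a1 + b1 * x` (junction number against traction strength).
#'
#' @param x parameter values.
#' @param y response.
#' @return list with `coefficients` (`a1`, `b1`), `r_squared`,
#'   `adj_r_squared`, `fitted`, and the `lm` fit object.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 2)
  fit <- lm(y ~ x)
  co <- setNames(coef(fit), c("a1", "b1"))
  m <- .fit_metrics(y, fitted(fit), 1)
  list(coefficients = co, r_squared = m$r_squared,
       adj_r_squared = m$adj_r_squared, fitted = fitted(fit), fit = fit)
}

#' Logistic dose-response fit
#'
#' Fits `f(x) = a3 + b3 / (1 + exp(-c3 * x + d3))` (junction number against
#' the initial gel thickness).
#'
#' @param x parameter values.
#' @param y response.
#' @return list with `coefficients` (`a3`, `b3`, `c3`, `d3`), `r_squared`,
#'   `adj_r_squared`, `fitted`, and the `nls` fit object.
#' @export
fit_logistic <- function(x, y) {
  stopifnot(length(x) == length(y), length(y) >= 4)
  b0 <- max(diff(range(y)), .Machine$double.eps)
  a0 <- min(y)
  xm <- median(x)
  c0s <- c(4 / max(diff(range(x)), .Machine$double.xmin), 1 / max(abs(xm), 1))
  starts <- unlist(lapply(c0s, function(cc) {
    list(list(a3 = a0, b3 = b0, c3 = cc, d3 = cc * xm),
         list(a3 = a0 - b0 / 2, b3 = 2 * b0, c3 = cc, d3 = cc * xm))
  }), recursive = FALSE)
  d <- data.frame(x = x, y = y)
  fit <- .nls_multistart(y ~ a3 + b3 / (1 + exp(-c3 * x + d3)), d, starts)
  m <- .fit_metrics(y, fitted(fit), 4)
  list(coefficients = coef(fit), r_squared = m$r_squared,
       adj_r_squared = m$adj_r_squared, fitted = fitted(fit), fit = fit)
}

#' Two-factor junction-time regression
#'
#' Fits the joint model of the junction-number time course under multipliers
#' of the four migration-related parameters:
#' `f = A (1 - exp(-B mu_m - C mu_h - D c0 - E kr)) *`
#' `(1 - exp(-F mu_m^G mu_h^H c0^I kr^J t))`,
#' where `kr = k_on / k_off`. The first factor is the plateau junction
#' number, the second the development rate.
#'
#' @param data data.frame with columns `mu_m`, `mu_h`, `c0`, `kr`, `t`
#'   (seconds) and `junctions`.
#' @return list with `coefficients` (`A` ... `J`), `r_squared`,
#'   `adj_r_squared`, `fitted`, and the `nls` fit object.
#' @export
fit_junction_time <- function(data) {
  need <- c("mu_m", "mu_h", "c0", "kr", "t", "junctions")
  stopifnot(all(need %in% names(data)), nrow(data) >= 10)
  y <- data$junctions
  # fit on median-rescaled predictors (the raw parameter scales span 25
  # orders of magnitude, which cripples the optimizer), then map the
  # coefficients back to physical units
  med <- list(mu_m = median(data$mu_m), mu_h = median(data$mu_h),
              c0 = median(data$c0), kr = median(data$kr), t = median(data$t))
  d <- data.frame(mu_m = data$mu_m / med$mu_m, mu_h = data$mu_h / med$mu_h,
                  c0 = data$c0 / med$c0, kr = data$kr / med$kr,
                  t = data$t / med$t, junctions = y)
  A0 <- max(y) * 1.05
  starts <- list()
  for (lin in c(0.3, 1, 3)) {
    for (ex in c(0.4, 0.8, 1.4)) {
      starts <- c(starts, list(list(A = A0, B = lin, C = lin, D = lin, E = lin,
                                    F = 1, G = ex, H = ex / 2, I = ex * 1.5,
                                    J = ex / 2)))
    }
  }
  fit <- .nls_multistart(
    junctions ~ A * (1 - exp(-B * mu_m - C * mu_h - D * c0 - E * kr)) *
      (1 - exp(-F * mu_m^G * mu_h^H * c0^I * kr^J * t)),
    d, starts)
  co <- coef(fit)
  co_phys <- co
  co_phys["B"] <- co["B"] / med$mu_m
  co_phys["C"] <- co["C"] / med$mu_h
  co_phys["D"] <- co["D"] / med$c0
  co_phys["E"] <- co["E"] / med$kr
  co_phys["F"] <- co["F"] / (med$mu_m^co["G"] * med$mu_h^co["H"] *
                             med$c0^co["I"] * med$kr^co["J"] * med$t)
  m <- .fit_metrics(y, fitted(fit), 10)
  list(coefficients = co_phys, r_squared = m$r_squared,
       adj_r_squared = m$adj_r_squared, fitted = as.vector(fitted(fit)),
       fit = fit)
}

#' Regression dispatcher
#'
#' Routes a sweep table to the matching functional form: `"saturating_exp"`
#' (`a - b e^{-cx}`), `"linear"` (`a1 + b1 x`), `"logistic"`
#' (`a3 + b3/(1 + e^{-c3 x + d3})`) or `"junction_time"` (the two-factor
#' time-course model).
#'
#' @param data for the single-dose forms, a data.frame with columns `x` and
#'   `y`; for `"junction_time"` the table described in
#'   [fit_junction_time()].
#' @param form functional form name.
#' @return the fit list of the matching `fit_*` function.
#' @export
fit_regressions <- function(data, form = c("saturating_exp", "linear",
                                           "logistic", "junction_time")) {
  form <- match.arg(form)
  switch(form,
         saturating_exp = fit_saturating_exp(data$x, data$y),
         linear = fit_linear(data$x, data$y),
         logistic = fit_logistic(data$x, data$y),
         junction_time = fit_junction_time(data))
}

#' Compare factorial conditions against a reference by t-tests
#'
#' Two-sample Student's t-test of every metric at every time point against
#' the reference condition, with the usual star convention (`*` p < 0.05,
#' `**` p < 0.01, `ns` otherwise). No multiple-testing correction is applied
#' (raw per-comparison tests, as is conventional for these endpoint plots);
#' degenerate comparisons (zero variance in both groups) are reported as
#' such.
#'
#' @param metric_tables named list of data.frames (one per condition), each
#'   with columns `time_mcs`, `metric`, `value` and one row per replicate.
#' @param reference name of the reference condition in `metric_tables`.
#' @return data.frame with `condition`, `metric`, `time_mcs`, `p_value`,
#'   `stars`, `degenerate`.
#' @export
compare_conditions <- function(metric_tables, reference) {
  stopifnot(reference %in% names(metric_tables))
  ref <- metric_tables[[reference]]
  out <- NULL
  for (cond in setdiff(names(metric_tables), reference)) {
    tab <- metric_tables[[cond]]
    keys <- unique(tab[, c("time_mcs", "metric")])
    for (k in seq_len(nrow(keys))) {
      a <- ref$value[ref$time_mcs == keys$time_mcs[k] & ref$metric == keys$metric[k]]
      b <- tab$value[tab$time_mcs == keys$time_mcs[k] & tab$metric == keys$metric[k]]
      if (length(a) < 2 || length(b) < 2) next
      degenerate <- sd(a) == 0 && sd(b) == 0
      p <- if (degenerate) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        t.test(a, b)$p.value
      }
      stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
      out <- rbind(out, data.frame(condition = cond, metric = keys$metric[k],
                                   time_mcs = keys$time_mcs[k], p_value = p,
                                   stars = stars, degenerate = degenerate))
    }
  }
  out
}
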