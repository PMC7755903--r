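# Enzymatic-inhibition and SPR curve fitting.

#' Reaction velocity from a chromogenic timecourse
#'
#' Slope of the least-squares line over the configured linear window of an
#' absorbance-versus-time trace (e.g. p-nitroaniline release at 405 nm).
#' Traces with pronounced curvature in the window are flagged.
#'
#' @param time,signal Numeric vectors.
#' @param window Two-element time window; defaults to the full trace.
#' @param curvature_tol Flag threshold: magnitude of the quadratic
#'   component across the window relative to the signal range.
#'
#' @return List with `rate` (signal units per time unit), `se`,
#'   `flagged` and `r_squared`.
#' @export
velocity <- function(time, signal, window = range(time),
                     curvature_tol = 0.1) {
  keep <- time >= window[1] & time <= window[2]
  t <- time[keep]
  y <- signal[keep]
  if (length(t) < 3L) stop("need >= 3 points in the linear window")
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  smry <- suppressWarnings(summary(fit))  # exact lines trip a perfect-fit warning
  se <- smry$coefficients[2, 2]
  flagged <- FALSE
  rng <- diff(range(y))
  if (length(t) >= 4L && rng > 0) {
    q <- stats::lm(y ~ t + I(t^2))
    curv <- abs(unname(stats::coef(q)[3])) * diff(range(t))^2
    if (curv > curvature_tol * rng) flagged <- TRUE
  }
  list(rate = slope, se = se, flagged = flagged,
       r_squared = smry$r.squared)
}

aicc <- function(rss, n, k) {
  # k = number of mean-model parameters; +1 for the error variance
  kk <- k + 1
  n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1e-9)
}

#' Four-parameter logistic (4PL) inhibition fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + (x / IC50)^h)` by
#' Levenberg-Marquardt least squares with data-driven starts.  At
#' `x = IC50` the response is the midpoint `(top + bottom) / 2`.
#'
#' @param conc Concentrations (same units as the reported IC50; zeros
#'   allowed and evaluate to `top`).
#' @param response Responses (e.g. percent activity).
#'
#' @return A `dose_response_fit` list: `top`, `bottom`, `ic50`, `h`,
#'   `model = "4pl"`, `rss`, `aicc`, `fitted`, `residuals`, `converged`.
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 5L) stop("need >= 5 concentrations")
  if (any(conc < 0)) stop("negative concentrations")
  top0 <- max(response)
  bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  pos <- conc[conc > 0]
  lic0 <- log10(pos[which.min(abs(response[conc > 0] - mid))])
  d <- data.frame(x = conc, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + ifelse(x > 0, (x / 10^lic)^h, 0)),
      data = d,
      start = list(top = top0, bottom = bot0, lic = lic0, h = 1),
      lower = c(-Inf, -Inf, log10(min(pos)) - 3, 0.1),
      upper = c(Inf, Inf, log10(max(pos)) + 3, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          h = NA_real_, model = "4pl", rss = NA_real_,
                          aicc = Inf, fitted = rep(NA_real_, length(conc)),
                          residuals = rep(NA_real_, length(conc)),
                          converged = FALSE),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rss <- sum(res^2)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ic50 = 10^unname(cf["lic"]), h = unname(cf["h"]),
                 model = "4pl", rss = rss,
                 aicc = aicc(rss, length(conc), 4L),
                 fitted = stats::fitted(fit), residuals = res,
                 converged = TRUE),
            class = "dose_response_fit")
}

#' Bell-shaped (hook-effect) inhibition fit
#'
#' Product-of-logistics model for inhibition curves whose effect reverses
#' at supersaturating antibody (bivalent engagement outcompeted by
#' monovalent binding):
#' `y = top - (top - bottom) * [x^h1 / (x^h1 + IC50^h1)] *
#'  [EC50_2^h2 / (x^h2 + EC50_2^h2)]`.
#' The reported `ic50` is the falling-phase midpoint.
#'
#' @param conc,response As in [fit_4pl()].
#' @return A `dose_response_fit` with additional `ec50_2`, `h2` and
#'   `model = "bell"`.
#' @export
fit_bell <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 6L) stop("need >= 6 concentrations for the bell model")
  if (any(conc < 0)) stop("negative concentrations")
  top0 <- max(response)
  bot0 <- min(response)
  pos <- sort(unique(conc[conc > 0]))
  imin <- which.min(vapply(pos, function(cc) {
    mean(response[conc == cc])
  }, numeric(1)))
  lic0 <- log10(sqrt(pos[1] * pos[imin]))
  lec0 <- log10(sqrt(pos[imin] * pos[length(pos)]))
  d <- data.frame(x = conc, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ top - (top - bottom) *
        ifelse(x > 0, x^h1 / (x^h1 + (10^lic)^h1), 0) *
        (10^lec)^h2 / (ifelse(x > 0, x^h2, 0) + (10^lec)^h2),
      data = d,
      start = list(top = top0, bottom = bot0, lic = lic0, h1 = 1,
                   lec = lec0, h2 = 1),
      lower = c(-Inf, -Inf, log10(pos[1]) - 3, 0.1, log10(pos[1]) - 3, 0.1),
      upper = c(Inf, Inf, log10(pos[length(pos)]) + 3, 10,
                log10(pos[length(pos)]) + 3, 10),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          h = NA_real_, ec50_2 = NA_real_, h2 = NA_real_,
                          model = "bell", rss = NA_real_, aicc = Inf,
                          fitted = rep(NA_real_, length(conc)),
                          residuals = rep(NA_real_, length(conc)),
                          converged = FALSE),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rss <- sum(res^2)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ic50 = 10^unname(cf["lic"]), h = unname(cf["h1"]),
                 ec50_2 = 10^unname(cf["lec"]), h2 = unname(cf["h2"]),
                 model = "bell", rss = rss,
                 aicc = aicc(rss, length(conc), 6L),
                 fitted = stats::fitted(fit), residuals = res,
                 converged = TRUE),
            class = "dose_response_fit")
}

#' Fit an inhibition curve, selecting 4PL vs bell by corrected AIC
#'
#' @param conc,response As in [fit_4pl()].
#' @return The preferred `dose_response_fit`, with attributes
#'   `alternatives` (both fits) and `delta_aicc` (bell minus 4PL).
#' @export
fit_inhibition <- function(conc, response) {
  f4 <- fit_4pl(conc, response)
  fb <- tryCatch(fit_bell(conc, response), error = function(e) NULL)
  if (is.null(fb) || !fb$converged || !is.finite(fb$aicc)) return(f4)
  best <- if (fb$aicc < f4$aicc) fb else f4
  attr(best, "alternatives") <- list(`4pl` = f4, bell = fb)
  attr(best, "delta_aicc") <- fb$aicc - f4$aicc
  best
}

#' Global 1:1 Langmuir fit of an SPR concentration series
#'
#' Simultaneous fit of association and dissociation phases across all
#' analyte concentrations:
#' association `R(t) = R_eq(C) (1 - exp(-(kon C + koff) t))` with
#' `R_eq = Rmax C / (C + KD)`, dissociation decaying exponentially with
#' `koff` from the response at the end of association.  `KD = koff / kon`
#' by construction.
#'
#' @param sensorgrams data.frame with columns `time`, `response`, `conc`
#'   (>= 3 distinct concentrations).
#' @param t_dissoc Time at which dissociation begins (association start is
#'   t = 0).
#'
#' @return A `kinetic_fit` list: `kon` (M^-1 s^-1), `koff` (s^-1),
#'   `KD` (M), `Rmax`, `rss`, `converged`.
#' @export
fit_langmuir <- function(sensorgrams, t_dissoc) {
  stopifnot(all(c("time", "response", "conc") %in% names(sensorgrams)))
  concs <- sort(unique(sensorgrams$conc))
  if (length(concs) < 3L) stop("need >= 3 analyte concentrations")
  if (stats::sd(sensorgrams$response) < 1e-9) stop("flat sensorgrams")
  d <- sensorgrams
  model_R <- function(lkon, lkoff, Rmax, time, conc) {
    kon <- 10^lkon
    koff <- 10^lkoff
    KD <- koff / kon
    Req <- Rmax * conc / (conc + KD)
    kobs <- kon * conc + koff
    Rend <- Req * (1 - exp(-kobs * t_dissoc))
    ifelse(time <= t_dissoc,
           Req * (1 - exp(-kobs * time)),
           Rend * exp(-koff * (time - t_dissoc)))
  }
  Rmax0 <- max(d$response)
  fit <- minpack.lm::nlsLM(
    response ~ model_R(lkon, lkoff, Rmax, time, conc),
    data = d,
    start = list(lkon = 5, lkoff = -2.5, Rmax = Rmax0),
    lower = c(0, -7, 1e-6), upper = c(10, 1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  kon <- 10^unname(cf["lkon"])
  koff <- 10^unname(cf["lkoff"])
  structure(list(kon = kon, koff = koff, KD = koff / kon,
                 Rmax = unname(cf["Rmax"]), rss = sum(stats::resid(fit)^2),
                 t_dissoc = t_dissoc, converged = TRUE),
            class = "kinetic_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s fit: top %.3g, bottom %.3g, IC50 %.3g, h %.2f (RSS %.3g)\n",
              x$model, x$top, x$bottom, x$ic50, x$h, x$rss))
  if (identical(x$model, "bell")) {
    cat(sprintf("  hook: EC50_2 %.3g, h2 %.2f\n", x$ec50_2, x$h2))
  }
  invisible(x)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 Langmuir: kon %.3g M^-1 s^-1, koff %.3g s^-1, KD %.3g M, Rmax %.3g\n",
              x$kon, x$koff, x$KD, x$Rmax))
  invisible(x)
}
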