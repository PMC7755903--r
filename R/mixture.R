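# n-population binomial mixture fitting of deuterated envelopes with
# nested F-test model selection.
#
# The forward model is the natural envelope convolved with
# sum_j w_j Binomial(N_ex, p_j); fitting minimises the residual sum of
# squares between that model and the observed envelope.  Population counts
# are compared by the standard nested-model F-test on residual sums of
# squares.

# Convolution design matrix: column k holds the natural envelope shifted
# by k-1 bins, padded to n_bins rows.  model = M %*% shift(w, p).
conv_matrix <- function(natural, N_ex, n_bins) {
  M <- matrix(0, nrow = n_bins, ncol = N_ex + 1L)
  nat <- as.numeric(natural)
  for (k in 0:N_ex) {
    idx <- seq_along(nat) + k
    keep <- idx <= n_bins
    M[idx[keep], k + 1L] <- nat[keep]
  }
  M
}

mixture_rss <- function(obs, M, w, p, N_ex) {
  model <- as.numeric(M %*% mixture_shift(w, p, N_ex))
  sum((obs - model)^2)
}

# Stick-breaking map from box-constrained v in [0,1]^(n-1) to weights.
stick_weights <- function(v) {
  n <- length(v) + 1L
  w <- numeric(n)
  rem <- 1
  for (j in seq_len(n - 1L)) {
    w[j] <- rem * v[j]
    rem <- rem - w[j]
  }
  w[n] <- rem
  w
}

#' Fit an n-population binomial mixture to an observed envelope
#'
#' Least-squares estimation of weights and incorporation probabilities.
#' The single-population fit uses a coarse grid followed by golden-section
#' refinement; multi-population fits run box-constrained local
#' optimisation (`nlminb`) from a deterministic set of starting points.
#'
#' @param observed Observed (deuterated) envelope, numeric, sums to 1.
#' @param natural Natural envelope of the same peptide.
#' @param N_ex Number of exchangeable amides.
#' @param n_pop Number of populations to fit.
#' @param n_starts Maximum number of multi-start points for `n_pop >= 2`.
#'
#' @return A `mixture_model` list with `n_pop`, `w`, `p` (sorted by `p`),
#'   `N_ex`, `rss`, `df` (bins minus the `2 n_pop - 1` free parameters),
#'   `converged`, and the fitted envelope.
#' @export
fit_mixture <- function(observed, natural, N_ex, n_pop = 1L, n_starts = 16L) {
  observed <- as.numeric(observed)
  natural <- as.numeric(natural)
  stopifnot(n_pop >= 1L, N_ex >= 1L)
  n_bins <- max(length(observed), length(natural) + N_ex)
  obs <- pad_to(observed, n_bins)
  df <- n_bins - (2L * n_pop - 1L)
  if (df <= 0L) stop("n_pop too large for the number of envelope bins")
  M <- conv_matrix(natural, N_ex, n_bins)

  if (n_pop == 1L) {
    f <- function(p) mixture_rss(obs, M, 1, p, N_ex)
    grid <- seq(0, 1, by = 0.025)
    vals <- vapply(grid, f, numeric(1))
    i0 <- which.min(vals)
    lo <- grid[max(1L, i0 - 1L)]
    hi <- grid[min(length(grid), i0 + 1L)]
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
    # guard against a flat boundary optimum missed by the bracket
    if (f(grid[i0]) < opt$objective) opt <- list(minimum = grid[i0], objective = vals[i0])
    w_hat <- 1; p_hat <- opt$minimum; rss <- opt$objective; conv <- TRUE
  } else {
    obj <- function(theta) {
      p <- theta[seq_len(n_pop)]
      w <- stick_weights(theta[n_pop + seq_len(n_pop - 1L)])
      mixture_rss(obs, M, w, p, N_ex)
    }
    # deterministic starts: sorted combinations of a coarse p grid plus a
    # split of the single-population optimum
    p1 <- fit_mixture(observed, natural, N_ex, 1L)$p
    pgrid <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    combos <- utils::combn(pgrid, n_pop, simplify = FALSE)
    starts <- lapply(combos, function(ps) c(ps, rep(0.5, n_pop - 1L)))
    split_p <- sort(pmin(1, pmax(0, p1 * seq(0.5, 1.5, length.out = n_pop))))
    starts <- c(list(c(split_p, rep(0.5, n_pop - 1L))), starts)
    if (length(starts) > n_starts) starts <- starts[seq_len(n_starts)]
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      fit <- stats::nlminb(s, obj,
                           lower = rep(0, 2L * n_pop - 1L),
                           upper = rep(1, 2L * n_pop - 1L),
                           control = list(iter.max = 400, abs.tol = 0))
      if (is.null(best) || fit$objective < best$objective) best <- fit
      if (fit$convergence == 0) conv <- TRUE
    }
    p_hat <- best$par[seq_len(n_pop)]
    w_hat <- stick_weights(best$par[n_pop + seq_len(n_pop - 1L)])
    ord <- order(p_hat)
    p_hat <- p_hat[ord]
    w_hat <- w_hat[ord]
    rss <- best$objective
  }

  fitted <- as.numeric(M %*% mixture_shift(w_hat, p_hat, N_ex))
  structure(list(n_pop = as.integer(n_pop), w = w_hat, p = p_hat,
                 N_ex = as.integer(N_ex), rss = rss, df = df,
                 converged = conv, fitted = fitted, observed = obs),
            class = "mixture_model")
}

#' Select the number of deuteration populations by nested F-test
#'
#' Iteratively compares the n-population fit against n+1 populations with
#' `F = ((RSS_n - RSS_{n+1}) / (df_n - df_{n+1})) / (RSS_{n+1} / df_{n+1})`
#' and accepts the larger model only when the F-test p-value falls below
#' `alpha`.  A perfect larger fit (RSS of zero) is accepted outright.
#'
#' @param observed,natural,N_ex See [fit_mixture()].
#' @param alpha Significance level of the F-test.
#' @param n_max Largest population count considered.
#' @param ... Passed to [fit_mixture()].
#'
#' @return The selected `mixture_model`.
#' @export
select_populations <- function(observed, natural, N_ex, alpha = 0.05,
                               n_max = 3L, ...) {
  stopifnot(alpha > 0, alpha < 1, n_max >= 1L)
  cur <- fit_mixture(observed, natural, N_ex, 1L, ...)
  if (n_max == 1L) return(cur)
  for (n in 2:n_max) {
    if (cur$rss <= .Machine$double.eps) return(cur)  # already a perfect fit
    cand <- fit_mixture(observed, natural, N_ex, n, ...)
    if (cand$rss <= .Machine$double.eps) return(cand)
    ddf <- cur$df - cand$df
    gain <- cur$rss - cand$rss
    if (gain <= 0) return(cur)
    Fstat <- (gain / ddf) / (cand$rss / cand$df)
    pval <- stats::pf(Fstat, ddf, cand$df, lower.tail = FALSE)
    if (pval < alpha) cur <- cand else return(cur)
  }
  cur
}

#' Deuterium uptake implied by a mixture fit
#'
#' @param model A `mixture_model`.
#' @return Uptake in Da: `N_ex * sum(w * p)`.
#' @export
uptake_from_fit <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  model$N_ex * sum(model$w * model$p)
}

#' Correct observed uptake for back-exchange
#'
#' Divides the observed uptake by the fractional deuterium recovery
#' (roughly 0.85 for a cold quench/LC workup), capping at the number of
#' exchangeable sites with a warning when that is supplied.
#'
#' @param D_obs Observed uptake, Da.
#' @param r Fractional recovery in `(0, 1]`.
#' @param N_ex Optional cap (exchangeable amide count).
#' @return Corrected uptake, Da.
#' @export
correct_back_exchange <- function(D_obs, r = 0.85, N_ex = NULL) {
  if (!is.numeric(r) || r <= 0 || r > 1) stop("recovery r must be in (0, 1]")
  D <- D_obs / r
  if (!is.null(N_ex) && any(D > N_ex)) {
    warning("corrected uptake exceeds N_ex; capped")
    D <- pmin(D, N_ex)
  }
  D
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("binomial mixture: %d population(s), N_ex = %d, RSS = %.3g (df %d)\n",
              x$n_pop, x$N_ex, x$rss, x$df))
  for (j in seq_len(x$n_pop)) {
    cat(sprintf("  pop %d: w = %.3f, p = %.4f\n", j, x$w[j], x$p[j]))
  }
  invisible(x)
}
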