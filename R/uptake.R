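# Peptide-level deuterium uptake analysis: the duplicate-range
# differential-protection criterion, intrinsic exchange rates, empirical
# protection factors and residue-level consolidation.

#' Differential deuterium-uptake map
#'
#' For each peptide and labeling time, compares mean uptake between the
#' unbound (apo) and Fab-bound (holo) states.  A peptide is significant
#' when, at any timepoint, the absolute mean difference exceeds the sum of
#' the duplicate ranges of both states.  Direction is positive when the
#' bound state exchanges more slowly (protection).
#'
#' @param uptake Long-format data.frame with columns `peptide_id`,
#'   `start`, `end`, `state`, `time_min`, `replicate`, `D`.
#' @param state_apo,state_holo State labels to compare.
#'
#' @return A list of class `differential_map` with `per_timepoint`
#'   (peptide x time table of means, ranges, `delta`, `significant`) and
#'   `per_peptide` (peptide-level `significant` flag and `direction`).
#' @export
differential_map <- function(uptake, state_apo = "apo", state_holo = "holo") {
  needed <- c("peptide_id", "start", "end", "state", "time_min", "replicate", "D")
  missing_cols <- setdiff(needed, names(uptake))
  if (length(missing_cols)) {
    stop("uptake table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  apo <- uptake[uptake$state == state_apo, ]
  holo <- uptake[uptake$state == state_holo, ]
  if (!nrow(apo) || !nrow(holo)) stop("both states must be present")
  common <- intersect(unique(apo$peptide_id), unique(holo$peptide_id))
  unmatched <- setdiff(union(unique(apo$peptide_id), unique(holo$peptide_id)), common)
  if (length(unmatched)) {
    warning("skipping peptides present in only one state: ",
            paste(unmatched, collapse = ", "))
  }
  rows <- list()
  for (pep in common) {
    a <- apo[apo$peptide_id == pep, ]
    h <- holo[holo$peptide_id == pep, ]
    times <- intersect(unique(a$time_min), unique(h$time_min))
    for (t in sort(times)) {
      da <- a$D[a$time_min == t]
      dh <- h$D[h$time_min == t]
      if (length(da) < 2L || length(dh) < 2L) {
        stop("peptide ", pep, " t=", t, ": need >= 2 replicates per state")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pep, start = a$start[1], end = a$end[1], time_min = t,
        mean_apo = mean(da), mean_holo = mean(dh),
        range_apo = diff(range(da)), range_holo = diff(range(dh)),
        stringsAsFactors = FALSE)
    }
  }
  tp <- do.call(rbind, rows)
  tp$delta <- abs(tp$mean_apo - tp$mean_holo)
  tp$direction <- sign(tp$mean_apo - tp$mean_holo)
  tp$significant <- tp$delta > tp$range_apo + tp$range_holo

  per_pep <- do.call(rbind, lapply(split(tp, tp$peptide_id), function(d) {
    sig <- any(d$significant)
    dir <- if (sig) d$direction[which.max(d$delta * d$significant)] else 0
    data.frame(peptide_id = d$peptide_id[1], start = d$start[1],
               end = d$end[1], significant = sig, direction = dir,
               max_delta = max(d$delta), stringsAsFactors = FALSE)
  }))
  rownames(per_pep) <- NULL
  structure(list(per_timepoint = tp, per_peptide = per_pep,
                 states = c(apo = state_apo, holo = state_holo)),
            class = "differential_map")
}

# ---------------------------------------------------------------------------
# Intrinsic (unstructured-chain) amide exchange rates.
#
# Reference poly-DL-alanine rate constants in D2O with nearest-neighbor
# side-chain corrections, pD dependence (first order in D+ and OD-) and
# Arrhenius temperature corrections, following the standard published
# reference compilation used throughout the HX field.

# log10 nearest-neighbor factors; columns: acid when the residue is left
# of the amide (AL), acid right (AR), base left (BL), base right (BR).
NN_FACTORS <- matrix(c(
   0.00,  0.00,  0.00,  0.00,  # A
  -0.54, -0.46,  0.62,  0.55,  # C
   0.90,  0.58, -0.30, -0.18,  # D (deprotonated)
  -0.90,  0.31, -0.51, -0.15,  # E (deprotonated)
  -0.52, -0.43, -0.24,  0.06,  # F
  -0.22,  0.22,  0.27,  0.17,  # G
  -0.80, -0.51,  0.80,  0.83,  # H
  -0.91, -0.59, -0.73, -0.23,  # I
  -0.56, -0.29, -0.04,  0.12,  # K
  -0.57, -0.13, -0.58, -0.21,  # L
  -0.64, -0.28, -0.01,  0.11,  # M
  -0.58, -0.13,  0.49,  0.32,  # N
   0.00, -0.19,  0.00, -0.24,  # P (trans; no own amide)
  -0.47, -0.27,  0.06,  0.20,  # Q
  -0.59, -0.32,  0.08,  0.22,  # R
  -0.44, -0.39,  0.37,  0.30,  # S
  -0.79, -0.47, -0.07,  0.20,  # T
  -0.74, -0.30, -0.70, -0.14,  # V
  -0.40, -0.44, -0.41, -0.11,  # W
  -0.41, -0.37, -0.27,  0.05   # Y
), ncol = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("AL", "AR", "BL", "BR")))

HX_REF <- list(
  log_kA = 1.62,    # acid catalysis, M^-1 min^-1 at 20 C
  log_kB = 10.05,   # base catalysis, M^-1 min^-1 at 20 C
  log_kW = -1.5,    # water catalysis, min^-1 at 20 C
  pKD = 15.05,      # D2O autoionisation at 20 C
  Ea = c(A = 14, B = 17, W = 19),  # kcal/mol
  T_ref = 293.15
)

#' Intrinsic amide exchange rates of an unstructured chain
#'
#' Per-residue intrinsic rates `k_int` (min^-1) in D2O from the reference
#' poly-DL-alanine constants with nearest-neighbor side-chain corrections,
#' first-order pD dependence and Arrhenius temperature scaling.  The first
#' two residues and prolines carry no retained amide and receive `NA`.
#'
#' @param sequence One-letter amino-acid string.
#' @param pD Labeling pD (glass-electrode reading corrected), in `[0, 14]`.
#' @param temperature_C Labeling temperature in Celsius.
#'
#' @return data.frame with `position`, `residue`, `k_int` (min^-1).
#' @export
intrinsic_rates <- function(sequence, pD = 7.0, temperature_C = 20) {
  ch <- aa_chars(sequence)
  if (pD < 0 || pD > 14) stop("pD out of range")
  L <- length(ch)
  Tk <- temperature_C + 273.15
  Rgas <- 1.9858775e-3  # kcal/mol/K
  arr <- function(Ea) exp(-Ea / Rgas * (1 / Tk - 1 / HX_REF$T_ref))
  conc_D <- 10^(-pD)
  conc_OD <- 10^(pD - HX_REF$pKD)
  k_int <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i <= 2L || ch[i] == "P") next
    left <- ch[i - 1L]
    own <- ch[i]
    logA <- NN_FACTORS[own, "AL"] + NN_FACTORS[left, "AR"]
    logB <- NN_FACTORS[own, "BL"] + NN_FACTORS[left, "BR"]
    if (i == 3L) {           # succeeding the protonated N-terminus
      logA <- logA - 1.32
      logB <- logB + 1.62
    }
    if (i == L) {            # preceding the C-terminal carboxylate
      logA <- logA + 0.96
      logB <- logB - 1.80
    }
    kA <- 10^(HX_REF$log_kA + logA) * conc_D * arr(HX_REF$Ea["A"])
    kB <- 10^(HX_REF$log_kB + logB) * conc_OD * arr(HX_REF$Ea["B"])
    kW <- 10^(HX_REF$log_kW + logB) * arr(HX_REF$Ea["W"])
    k_int[i] <- kA + kB + kW
  }
  data.frame(position = seq_len(L), residue = ch, k_int = k_int,
             stringsAsFactors = FALSE)
}

#' Empirical protection factor for one peptide/state uptake curve
#'
#' Fits the single-protection-factor model
#' `D(t) = sum_i (1 - exp(-k_int_i * t / PF))` over the peptide's
#' exchange-competent amides by least squares on `log10(PF)`.  The
#' uncertainty is propagated from the replicate spread through the fit's
#' local sensitivity (Gauss-Newton curvature).
#'
#' @param records data.frame with columns `time_min`, `replicate`, `D` for
#'   one peptide and state (>= 3 distinct timepoints).
#' @param k_int Intrinsic rates (min^-1) of the peptide's amides; `NA`
#'   entries (prolines, N-terminal residues) are dropped.
#' @param pf_range Search range for the protection factor.
#' @param monotone_tol Allowed non-monotonicity of the mean uptake curve,
#'   as a multiple of the pooled replicate range, before flagging.
#'
#' @return A `protection_estimate` list with `PF`, `sigma_PF`, `log10_PF`,
#'   `rss` and a `flag` (`"ok"`, `"no_uptake"` sentinel at the upper search
#'   bound, or `"non_monotone"`).
#' @export
empirical_pf <- function(records, k_int, pf_range = c(1e-2, 1e8),
                         monotone_tol = 2) {
  stopifnot(all(c("time_min", "replicate", "D") %in% names(records)))
  k <- k_int[is.finite(k_int)]
  if (!length(k)) stop("no exchange-competent amides")
  times <- sort(unique(records$time_min))
  if (length(times) < 3L) stop("need >= 3 timepoints")
  means <- vapply(times, function(t) mean(records$D[records$time_min == t]),
                  numeric(1))
  ranges <- vapply(times, function(t) diff(range(records$D[records$time_min == t])),
                   numeric(1))
  pooled <- max(mean(ranges), 1e-6)
  flag <- "ok"
  if (any(diff(means) < -monotone_tol * pooled)) flag <- "non_monotone"

  model_D <- function(pf, t) sum(1 - exp(-k * t / pf))
  if (all(records$D < 0.02 * length(k))) {
    return(structure(list(PF = pf_range[2], sigma_PF = Inf,
                          log10_PF = log10(pf_range[2]), rss = NA_real_,
                          flag = "no_uptake"),
                     class = "protection_estimate"))
  }
  rss_fun <- function(lpf) {
    pred <- vapply(records$time_min, function(t) model_D(10^lpf, t), numeric(1))
    sum((records$D - pred)^2)
  }
  opt <- stats::optimize(rss_fun, log10(pf_range), tol = 1e-8)
  pf <- 10^opt$minimum
  # sensitivity of the mean curve to PF at the optimum
  J <- vapply(records$time_min, function(t) {
    sum(exp(-k * t / pf) * k * t / pf^2)
  }, numeric(1))
  s2 <- if (sum(ranges > 0)) mean((ranges[ranges > 0] / 2)^2) else
    opt$objective / max(1, nrow(records) - 1)
  sigma_PF <- if (sum(J^2) > 0) sqrt(s2 / sum(J^2)) else Inf
  structure(list(PF = pf, sigma_PF = sigma_PF, log10_PF = opt$minimum,
                 rss = opt$objective, flag = flag),
            class = "protection_estimate")
}

#' Consolidate peptide-level significance to a residue-level protected set
#'
#' A residue is protected when it is covered by at least one significant
#' peptide and is not exclusively explained by overlapping non-significant
#' peptides: the union of non-significant peptide spans is subtracted from
#' the union of significant spans.
#'
#' @param per_peptide data.frame with `start`, `end`, `significant`
#'   (e.g. the `per_peptide` component of [differential_map()]).
#' @return Sorted integer vector of protected residue positions.
#' @export
consolidate_residues <- function(per_peptide) {
  stopifnot(all(c("start", "end", "significant") %in% names(per_peptide)))
  if (any(per_peptide$end < per_peptide$start)) {
    stop("conflicting peptide coordinates: end < start")
  }
  span <- function(d) if (nrow(d)) unlist(Map(seq.int, d$start, d$end)) else integer(0)
  sig <- span(per_peptide[per_peptide$significant, , drop = FALSE])
  nonsig <- span(per_peptide[!per_peptide$significant, , drop = FALSE])
  sort(unique(setdiff(sig, nonsig)))
}

#' Annotate residue protection across two bound states
#'
#' @param set_a,set_b Protected residue sets (integer vectors) from two
#'   bound states, e.g. two antibody variants.
#' @param labels Character vector of length 2 naming the states.
#' @return data.frame with `residue` and `state`
#'   (`both` / `<labels[1]>-only` / `<labels[2]>-only`).
#' @export
annotate_states <- function(set_a, set_b, labels = c("v1", "v2")) {
  all_res <- sort(unique(c(set_a, set_b)))
  state <- ifelse(all_res %in% set_a & all_res %in% set_b, "both",
                  ifelse(all_res %in% set_a, paste0(labels[1], "-only"),
                         paste0(labels[2], "-only")))
  data.frame(residue = all_res, state = state, stringsAsFactors = FALSE)
}

#' @export
print.differential_map <- function(x, ...) {
  n_sig <- sum(x$per_peptide$significant)
  cat(sprintf("differential uptake map: %d peptides, %d significant (%s vs %s)\n",
              nrow(x$per_peptide), n_sig, x$states["apo"], x$states["holo"]))
  invisible(x)
}

#' @export
print.protection_estimate <- function(x, ...) {
  cat(sprintf("empirical PF = %.3g +/- %.2g [%s]\n", x$PF, x$sigma_PF, x$flag))
  invisible(x)
}
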