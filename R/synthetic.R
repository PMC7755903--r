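# Deterministic synthetic-data generators.
#
# Each generator takes an explicit seed (Mersenne-Twister via
# withr::with_seed, so the caller's RNG state is untouched), emulates the
# statistical structure the corresponding analysis assumes, and returns
# the ground truth alongside the data.

#' The upper-hinge variant panel with observed outcomes
#'
#' The fifteen hinge variants of the humanized anti-tryptase IgG:
#' sequence, constraint flag, isotype scaffold, the monomer-binding
#' affinity label (nM) and the observed inhibition outcome
#' (full / partial / none) used for concordance testing.
#'
#' @return data.frame with columns `name`, `upper_seq`, `constrained`,
#'   `scaffold`, `kd_nM`, `observed`.
#' @export
gen_variant_table <- function() {
  data.frame(
    name = c("IgG1.v1", "IgG1.v2", "IgG2", "IgG4",
             "G1+G", "G1+GG", "G1+GGS", "G1+(GGS)3",
             "G1-H", "G1-TH", "G1-KTH", "G1.G5", "G1.P5",
             "G1.C", "G1.CC"),
    upper_seq = c("EPKSCDKTHT", "EPKSCDKTHT", "ERKCCVE", "ESKYGPP",
                  "EPKSCDKTHGT", "EPKSCDKTHGGT", "EPKSCDKTHGGST",
                  "EPKSCDKTHGGSGGSGGST",
                  "EPKSCDKTT", "EPKSCDKT", "EPKSCDT",
                  "EPKSCGGGGG", "EPKSCPPPPP",
                  "EPKSCDKCHT", "EPKSCDKCCT"),
    constrained = c(FALSE, FALSE, TRUE, FALSE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, TRUE),
    scaffold = c("IgG1", "IgG1", "IgG2", "IgG4",
                 rep("IgG1", 11)),
    kd_nM = c(0.5, 0.6, 0.6, 0.7, 0.5, 0.4, 0.5, 0.5,
              0.6, 0.5, 0.5, 0.6, 0.4, 0.3, 0.4),
    observed = c("full", "full", "none", "full",
                 "full", "partial", "none", "none",
                 "full", "full", "none", "full", "full",
                 "none", "none"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic HDX dataset generator
#'
#' @param seed Integer RNG seed.
#' @param n_res Protein length when `protein_seq` is generated.
#' @param protein_seq Optional explicit protein sequence.
#' @param peptide_len,peptide_step Sliding-window peptide tiling.
#' @param times Labeling timepoint grid in minutes.
#' @param n_rep Replicates per (peptide, state, timepoint).
#' @param pf_apo Baseline protection factor of the unbound protein.
#' @param protection_ratio Fold increase of PF on the protected segment in
#'   the bound state.
#' @param protected Two-element residue range carrying extra protection.
#' @param sd_uptake Stochastic uptake noise, Da (i.i.d. per measurement).
#' @param rep_offset Systematic run offset of the second replicate, Da
#'   (shared across peptides and states, emulating day-to-day drift).
#' @param sd_intensity Absolute Gaussian noise on envelope intensities.
#' @param pD,temperature_C Labeling conditions.
#' @return A `hdx_config` list.
#' @export
hdx_config <- function(seed = 1L, n_res = 120L, protein_seq = NULL,
                       peptide_len = 10L, peptide_step = 3L,
                       times = c(0.5, 2.3, 10, 48, 218, 1000),
                       n_rep = 2L, pf_apo = 50, protection_ratio = 50,
                       protected = c(70L, 80L), sd_uptake = 0.01,
                       rep_offset = 0.05, sd_intensity = 0.003,
                       pD = 7.0, temperature_C = 20) {
  stopifnot(sd_uptake >= 0, rep_offset >= 0, sd_intensity >= 0,
            n_rep >= 2L, pf_apo >= 1, protection_ratio >= 1,
            length(protected) == 2L, protected[1] <= protected[2])
  structure(list(seed = as.integer(seed), n_res = as.integer(n_res),
                 protein_seq = protein_seq, peptide_len = as.integer(peptide_len),
                 peptide_step = as.integer(peptide_step), times = times,
                 n_rep = as.integer(n_rep), pf_apo = pf_apo,
                 protection_ratio = protection_ratio,
                 protected = as.integer(protected), sd_uptake = sd_uptake,
                 rep_offset = rep_offset, sd_intensity = sd_intensity,
                 pD = pD, temperature_C = temperature_C),
            class = "hdx_config")
}

# Deterministic synthetic protein sequence (proline-sparse).
gen_protein_seq <- function(n_res, seed) {
  pool <- setdiff(AA_CODES, "P")
  withr::with_seed(seed, {
    ch <- sample(pool, n_res, replace = TRUE)
    # sprinkle a few prolines away from the termini
    npro <- max(1L, n_res %/% 30L)
    pos <- sample(5:(n_res - 4), npro)
    ch[pos] <- "P"
    paste(ch, collapse = "")
  })
}

#' Generate a synthetic HDX-MS dataset with localised protection
#'
#' Simulates apo/holo deuterium-uptake tables and isotope-envelope spectra
#' for a peptic-peptide tiling of a synthetic protein.  Uptake follows the
#' intrinsic-rate/protection-factor model; the bound (holo) state carries
#' `protection_ratio`-fold higher PF on the protected segment.  Envelopes
#' come from the single-population binomial forward model plus Gaussian
#' intensity noise.  Duplicates combine a systematic run offset with
#' i.i.d. noise so the duplicate-range significance criterion is
#' informative.
#'
#' @param config A [hdx_config()].
#' @return List with `peptides` (id, sequence, start, end, N_ex),
#'   `uptake` (long table: peptide_id, sequence, start, end, state,
#'   time_min, replicate, D), `spectra` (peptide_id, state, time_min,
#'   replicate, bin, intensity), and `truth` (protein sequence, per-state
#'   PF per residue, protected amide positions, config).
#' @export
gen_hdx_dataset <- function(config = hdx_config()) {
  seq_full <- config$protein_seq
  if (is.null(seq_full)) seq_full <- gen_protein_seq(config$n_res, config$seed)
  n_res <- nchar(seq_full)
  if (config$protected[2] > n_res) stop("protected segment outside protein")
  rates <- intrinsic_rates(seq_full, config$pD, config$temperature_C)

  starts <- seq(1L, n_res - config$peptide_len + 1L, by = config$peptide_step)
  if (utils::tail(starts, 1) + config$peptide_len - 1L < n_res) {
    starts <- c(starts, n_res - config$peptide_len + 1L)
  }
  peptides <- data.frame(
    peptide_id = sprintf("pep%03d", seq_along(starts)),
    start = starts, end = starts + config$peptide_len - 1L,
    stringsAsFactors = FALSE)
  peptides$sequence <- substring(seq_full, peptides$start, peptides$end)
  peptides$N_ex <- vapply(peptides$sequence, exchangeable_sites, integer(1))
  peptides <- peptides[peptides$N_ex >= 1L, , drop = FALSE]

  pf_apo <- rep(config$pf_apo, n_res)
  pf_holo <- pf_apo
  prot_idx <- config$protected[1]:config$protected[2]
  pf_holo[prot_idx] <- pf_holo[prot_idx] * config$protection_ratio

  # exchange-competent amide positions per peptide (global coordinates)
  amides <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    local <- (p$start:p$end)
    ch <- strsplit(p$sequence, "")[[1]]
    keep <- seq_along(ch) > 2L & ch != "P"
    local[keep]
  })

  true_D <- function(pos, t, pf) {
    k <- rates$k_int[pos]
    sum(1 - exp(-k * t / pf[pos]))
  }

  withr::with_seed(config$seed + 1L, {
    up_rows <- list()
    sp_rows <- list()
    for (i in seq_len(nrow(peptides))) {
      p <- peptides[i, ]
      nat <- natural_envelope(p$sequence)
      pos <- amides[[i]]
      for (state in c("apo", "holo")) {
        pf <- if (state == "apo") pf_apo else pf_holo
        for (t in config$times) {
          D0 <- true_D(pos, t, pf)
          for (rep_i in seq_len(config$n_rep)) {
            off <- config$rep_offset * (rep_i - 1L)
            D <- D0 + off + stats::rnorm(1, 0, config$sd_uptake)
            D <- min(max(D, 0), p$N_ex)
            up_rows[[length(up_rows) + 1L]] <- data.frame(
              peptide_id = p$peptide_id, sequence = p$sequence,
              start = p$start, end = p$end, state = state, time_min = t,
              replicate = rep_i, D = D, stringsAsFactors = FALSE)
            env <- deuterated_envelope(nat, 1, D0 / p$N_ex, p$N_ex)
            # baseline-subtracted centroided intensities: additive Gaussian
            # noise, small negative excursions retained
            noisy <- as.numeric(env) +
              stats::rnorm(length(env), 0, config$sd_intensity)
            sp_rows[[length(sp_rows) + 1L]] <- data.frame(
              peptide_id = p$peptide_id, state = state, time_min = t,
              replicate = rep_i, bin = seq_along(noisy) - 1L,
              intensity = noisy, stringsAsFactors = FALSE)
          }
        }
      }
    }
    uptake <- do.call(rbind, up_rows)
    spectra <- do.call(rbind, sp_rows)
  })
  rownames(uptake) <- rownames(spectra) <- NULL
  protected_amides <- intersect(prot_idx, unlist(amides))
  list(peptides = peptides[, c("peptide_id", "sequence", "start", "end", "N_ex")],
       uptake = uptake, spectra = spectra,
       truth = list(protein_seq = seq_full, pf_apo = pf_apo,
                    pf_holo = pf_holo,
                    protected_segment = config$protected,
                    protected_amides = sort(protected_amides),
                    amides = amides, k_int = rates$k_int,
                    config = config))
}

#' Write a synthetic HDX dataset to CSV files
#'
#' @param dataset Result of [gen_hdx_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_hdx_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peptides = file.path(dir, "peptides.csv"),
             uptake = file.path(dir, "uptake.csv"),
             spectra = file.path(dir, "spectra.csv"))
  utils::write.csv(dataset$peptides, paths["peptides"], row.names = FALSE)
  utils::write.csv(dataset$uptake, paths["uptake"], row.names = FALSE)
  utils::write.csv(dataset$spectra, paths["spectra"], row.names = FALSE)
  invisible(paths)
}

#' Generate noisy isotope-envelope replicates from a known mixture
#'
#' Draws replicate observed envelopes from the binomial-mixture forward
#' model plus additive Gaussian intensity noise.  As with
#' baseline-subtracted centroided spectra, small negative excursions are
#' retained rather than clipped, keeping the noise model Gaussian.
#'
#' @param sequence Peptide sequence (defines the natural envelope).
#' @param w,p Mixture weights and incorporation probabilities.
#' @param N_ex Exchangeable amide count; defaults to
#'   [exchangeable_sites()] of the sequence.
#' @param sd Absolute intensity noise standard deviation.
#' @param n_rep Number of replicates.
#' @param seed Integer RNG seed.
#' @return List with `replicates` (list of numeric vectors), `natural`,
#'   and `truth`.
#' @export
gen_envelope_replicates <- function(sequence, w, p, N_ex = NULL,
                                    sd = 0.003, n_rep = 2L, seed = 1L) {
  if (is.null(N_ex)) N_ex <- exchangeable_sites(sequence)
  nat <- natural_envelope(sequence)
  env <- deuterated_envelope(nat, w, p, N_ex)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_rep), function(i) {
      as.numeric(env) + stats::rnorm(length(env), 0, sd)
    })
  })
  list(replicates = reps, natural = nat,
       truth = list(w = w, p = p, N_ex = N_ex, sd = sd))
}

#' Generate a toy tetramer-plus-Fab complex
#'
#' A purely geometric stand-in for the 4:4 ring architecture: four
#' protomer pseudo-chains (cubic atom clusters) on a planar ring, four
#' pseudo-Fab heavy/light chain pairs placed alternately above and below
#' the ring, each with one atom exactly 3.5 Angstrom from its protomer
#' (guaranteeing a 4 Angstrom contact), and designated anchor atoms
#' (residue 217, CA) on diagonal Fabs exactly `d` apart.
#'
#' @param d Diagonal anchor-anchor distance in Angstrom.
#' @param file Optional path; when given, the model is also written as a
#'   PDB file.
#' @param ring_radius Protomer-center ring radius (A).
#' @param anchor_height Height of the anchor atoms above/below the ring
#'   plane (A); makes adjacent anchor distances differ from diagonal ones.
#'
#' @return A `structure_model` with role annotation (`protomer`,
#'   `fab_heavy`, `fab_light`; Fab units `fab1`..`fab4`).
#' @export
gen_toy_complex <- function(d = 51, file = NULL, ring_radius = 24,
                            anchor_height = 12) {
  stopifnot(d > 0)
  cube <- function(center, spacing = 3, half = 1L) {
    g <- expand.grid(x = -half:half, y = -half:half, z = -half:half)
    sweep(as.matrix(g) * spacing, 2, center, "+")
  }
  rows <- list()
  add_atoms <- function(xyz, chain, resno0 = 1L, resid = "GLY",
                        elety = "CA", element = "C") {
    n <- nrow(xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno0 + seq_len(n) - 1L, resid = resid,
      elety = elety, element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  }
  ang <- c(0, 90, 180, 270) * pi / 180
  centers <- cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
  prot_chains <- c("A", "B", "C", "D")
  hc_chains <- c("E", "G", "I", "K")
  lc_chains <- c("F", "H", "J", "L")
  updown <- c(1, -1, 1, -1)
  # anchors: diagonal pairs (protomers 1,3 up; 2,4 down), exactly d apart
  anchors <- rbind(c(d / 2, 0, anchor_height),
                   c(0, d / 2, -anchor_height),
                   c(-d / 2, 0, anchor_height),
                   c(0, -d / 2, -anchor_height))
  for (k in 1:4) {
    ck <- centers[k, ]
    s <- updown[k]
    add_atoms(cube(ck), prot_chains[k])
    # heavy chain: small cube above/below plus a stem atom 3.5 A from the
    # protomer's apical atom at ck + (0,0,3s), plus the anchor CA (resno 217)
    hc_center <- ck + c(0, 0, s * 9.5)
    hc <- cube(hc_center, spacing = 3, half = 1L)
    stem <- matrix(ck + c(0, 0, s * 6.5), nrow = 1)
    add_atoms(rbind(hc, stem), hc_chains[k])
    rows[[length(rows) + 1L]] <- data.frame(
      chain = hc_chains[k], resno = 217L, resid = "PRO", elety = "CA",
      element = "C", x = anchors[k, 1], y = anchors[k, 2], z = anchors[k, 3],
      stringsAsFactors = FALSE)
    lc_center <- ck + c(0, 0, s * 9.5) + 8 * ck / sqrt(sum(ck^2))
    add_atoms(cube(lc_center, spacing = 3, half = 1L), lc_chains[k])
  }
  atoms <- do.call(rbind, rows)
  roles <- data.frame(
    chain = c(prot_chains, hc_chains, lc_chains),
    role = c(rep("protomer", 4), rep("fab_heavy", 4), rep("fab_light", 4)),
    unit = c(paste0("protomer", 1:4), paste0("fab", 1:4), paste0("fab", 1:4)),
    stringsAsFactors = FALSE)
  model <- structure_model(atoms, roles)
  if (!is.null(file)) {
    xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
    bio3d::write.pdb(file = file, xyz = xyz,
                     resno = atoms$resno, resid = atoms$resid,
                     chain = atoms$chain, elety = atoms$elety,
                     eleno = seq_len(nrow(atoms)))
  }
  model
}

#' Generate synthetic binding/inhibition curves with known truth
#'
#' @param kind `"4pl"`, `"bell"` or `"sensorgram"`.
#' @param truth Named list of true parameters; missing entries take
#'   defaults anchored on the assay scales (IC50 a few nM, KD ~0.5 nM).
#' @param seed Integer RNG seed.
#' @param noise Noise level: relative to the response span for dose
#'   response curves, absolute response units for sensorgrams.
#' @param n_conc Number of concentrations (dose-response kinds).
#' @param n_rep Replicate curves (dose-response kinds; the assay default
#'   of three mirrors triplicate independent experiments).
#'
#' @return List with `data` (data.frame) and `truth` (full parameter
#'   list).
#' @export
gen_curves <- function(kind = c("4pl", "bell", "sensorgram"),
                       truth = list(), seed = 1L, noise = 0.03,
                       n_conc = 10L, n_rep = 3L) {
  kind <- match.arg(kind)
  if (kind == "4pl") {
    tr <- utils::modifyList(
      list(top = 100, bottom = 5, ic50 = 4e-9, h = 1), truth)
    conc <- 10^seq(-11, -6.5, length.out = n_conc)
    mu <- tr$bottom + (tr$top - tr$bottom) / (1 + (conc / tr$ic50)^tr$h)
    data <- withr::with_seed(seed, {
      do.call(rbind, lapply(seq_len(n_rep), function(r) {
        data.frame(conc = conc, replicate = r,
                   response = mu + stats::rnorm(n_conc, 0, noise * (tr$top - tr$bottom)))
      }))
    })
    return(list(data = data, truth = tr))
  }
  if (kind == "bell") {
    tr <- utils::modifyList(
      list(top = 100, bottom = 10, ic50 = 2.5e-9, h1 = 1.5,
           ec50_2 = 2e-7, h2 = 1.5), truth)
    conc <- 10^seq(-11, -5.5, length.out = max(n_conc, 12L))
    occ <- conc^tr$h1 / (conc^tr$h1 + tr$ic50^tr$h1)
    esc <- tr$ec50_2^tr$h2 / (conc^tr$h2 + tr$ec50_2^tr$h2)
    mu <- tr$top - (tr$top - tr$bottom) * occ * esc
    data <- withr::with_seed(seed, {
      do.call(rbind, lapply(seq_len(n_rep), function(r) {
        data.frame(conc = conc, replicate = r,
                   response = mu + stats::rnorm(length(conc), 0,
                                                noise * (tr$top - tr$bottom)))
      }))
    })
    return(list(data = data, truth = tr))
  }
  # sensorgram: threefold dilution series, 3 min association / 10 min
  # dissociation
  tr <- utils::modifyList(
    list(kon = 2e6, koff = 1e-3, Rmax = 100, conc_top = 1e-7,
         n_conc = 6L, t_assoc = 180, t_total = 780, dt = 2), truth)
  concs <- tr$conc_top / 3^(0:(tr$n_conc - 1L))
  times <- seq(0, tr$t_total, by = tr$dt)
  KD <- tr$koff / tr$kon
  rows <- lapply(concs, function(C) {
    Req <- tr$Rmax * C / (C + KD)
    kobs <- tr$kon * C + tr$koff
    Rend <- Req * (1 - exp(-kobs * tr$t_assoc))
    R <- ifelse(times <= tr$t_assoc,
                Req * (1 - exp(-kobs * times)),
                Rend * exp(-tr$koff * (times - tr$t_assoc)))
    data.frame(time = times, conc = C, response = R)
  })
  data <- do.call(rbind, rows)
  if (noise > 0) {
    data$response <- withr::with_seed(seed, {
      data$response + stats::rnorm(nrow(data), 0, noise)
    })
  }
  list(data = data, truth = c(tr, list(KD = KD)))
}
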