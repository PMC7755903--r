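# Shrake-Rupley solvent-accessible surface area and buried interface area.

# Van der Waals radii (Angstrom) by element; a standard published set.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98, FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.94,
               `NA` = 2.27, K = 2.75, MN = 1.40, CU = 1.40)

# Deterministic quasi-uniform sphere point set (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area using a deterministic golden-spiral point set
#' on each atom's solvent-expanded sphere; a point is accessible when it
#' lies outside every neighboring atom's expanded sphere.
#'
#' @param model A `structure_model`, or an atom data.frame with columns
#'   `element`, `x`, `y`, `z`.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample count per atom.
#' @param radii Optional named vector overriding/extending the built-in
#'   van der Waals radii (names are element symbols).
#'
#' @return Numeric vector of per-atom areas (A^2); `sum()` gives the total.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960, radii = NULL) {
  atoms <- if (inherits(model, "structure_model")) model$atoms else model
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  rtab <- VDW_RADII
  if (!is.null(radii)) rtab[names(radii)] <- radii
  elem <- toupper(atoms$element)
  unknown <- setdiff(unique(elem), names(rtab))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), "; supply `radii`")
  }
  r <- unname(rtab[elem]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  pts <- sphere_points(n_points)

  # neighbor candidates via a cell list sized to the largest reach
  cell <- 2 * max(r)
  origin <- apply(xyz, 2, min) - cell
  cand <- grid_candidates(xyz, xyz, cell, origin)

  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- cand[[i]]
    nb <- nb[nb != i]
    if (length(nb)) {
      d2 <- colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2)
      nb <- nb[d2 < (r[i] + r[nb])^2]
    }
    if (!length(nb)) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    P <- pts * r[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  areas
}

#' Buried surface area of an interface between two chain groups
#'
#' Computes Shrake-Rupley SASA for each group alone and for the complex;
#' the headline buried surface area is the half-sum convention
#' `(dSASA_A + dSASA_B) / 2`, with per-side totals and per-chain shares
#' also reported.
#'
#' @param model A `structure_model`.
#' @param groupA,groupB Disjoint, non-empty chain-id vectors.
#' @param probe Probe radius (A).
#' @param n_points Sphere sample count per atom.
#'
#' @return An `interface_area` list: `bsa_total`, `bsa_sideA`,
#'   `bsa_sideB` (A^2), and `share_sideA`/`share_sideB` (named per-chain
#'   fractions summing to 1 per side; zero-burial sides give NA shares).
#' @export
interface_area <- function(model, groupA, groupB, probe = 1.4,
                           n_points = 960) {
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  A <- sel_atoms(model, groupA)
  B <- sel_atoms(model, groupB)
  if (!nrow(A) || !nrow(B)) stop("empty chain group")
  AB <- rbind(A, B)
  sA <- sasa(A, probe, n_points)
  sB <- sasa(B, probe, n_points)
  sAB <- sasa(AB, probe, n_points)
  dA <- sA - sAB[seq_len(nrow(A))]
  dB <- sB - sAB[nrow(A) + seq_len(nrow(B))]
  side_share <- function(atoms, d) {
    tot <- sum(d)
    if (tot <= 0) return(NA)
    sh <- tapply(d, atoms$chain, sum) / tot
    sh[sh < 0] <- 0
    sh / sum(sh)
  }
  structure(list(bsa_total = (sum(dA) + sum(dB)) / 2,
                 bsa_sideA = sum(dA), bsa_sideB = sum(dB),
                 share_sideA = side_share(A, dA),
                 share_sideB = side_share(B, dB),
                 probe = probe, n_points = n_points),
            class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  cat(sprintf("interface area: %.1f A^2 (side A %.1f, side B %.1f; probe %.1f A)\n",
              x$bsa_total, x$bsa_sideA, x$bsa_sideB, x$probe))
  invisible(x)
}
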