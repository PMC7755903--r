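# Structural interface analytics: models, contact maps, anchor distances,
# stoichiometry counting and Kabsch superposition.

#' Read a macromolecular structure
#'
#' Thin wrapper over bio3d's PDB/mmCIF parsers returning a light
#' `structure_model`: an atom table (chain, residue, atom name, element,
#' coordinates) plus optional chain-role annotation.  Only the first
#' alternate location is kept; waters and hydrogens are dropped by default
#' so interface math operates on heavy atoms.
#'
#' @param file Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param roles Optional data.frame with columns `chain`, `role`
#'   (`"protomer"`, `"fab_heavy"`, `"fab_light"`) and `unit` (Fab id or
#'   protomer id); see [set_roles()].
#' @param keep_waters,keep_hydrogens Keep solvent / hydrogen atoms.
#'
#' @return A `structure_model` list with `atoms` and `roles`.
#' @export
read_structure <- function(file, roles = NULL, keep_waters = FALSE,
                           keep_hydrogens = FALSE) {
  if (!file.exists(file)) stop("cannot read structure file: ", file)
  pdb <- tryCatch({
    if (grepl("\\.cif$", file, ignore.case = TRUE)) bio3d::read.cif(file)
    else bio3d::read.pdb(file)
  }, error = function(e) {
    stop("failed to parse ", file, ": ", conditionMessage(e), call. = FALSE)
  })
  at <- pdb$atom
  alt <- at$alt
  keep <- is.na(alt) | alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- toupper(substr(elem, 1, 1))
  }
  elem <- toupper(trimws(elem))
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, element = elem,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", file)
  }
  structure_model(atoms, roles)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`.
#' @param roles Optional chain-role annotation (see [read_structure()]).
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, roles = NULL) {
  needed <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  stopifnot(all(needed %in% names(atoms)))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, roles = roles), class = "structure_model")
}

#' Annotate chain roles on a structure model
#'
#' @param model A `structure_model`.
#' @param roles data.frame with columns `chain`, `role`, `unit`.
#' @return The annotated model.
#' @export
set_roles <- function(model, roles) {
  stopifnot(inherits(model, "structure_model"),
            all(c("chain", "role", "unit") %in% names(roles)))
  model$roles <- roles
  model
}

sel_atoms <- function(model, chains) {
  model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Cell-list index: integer cell key per atom for a given cell size.
cell_keys <- function(xyz, cell, origin) {
  ijk <- floor(sweep(xyz, 2, origin) / cell)
  paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
}

# For query points, list candidate indices of `xyz` within one cell in any
# direction (27 neighboring cells).
grid_candidates <- function(q_xyz, xyz, cell, origin) {
  keys <- cell_keys(xyz, cell, origin)
  lut <- split(seq_len(nrow(xyz)), keys)
  qijk <- floor(sweep(q_xyz, 2, origin) / cell)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(nrow(q_xyz)), function(i) {
    ks <- paste(qijk[i, 1] + offs[, 1], qijk[i, 2] + offs[, 2],
                qijk[i, 3] + offs[, 3], sep = ",")
    unlist(lut[ks], use.names = FALSE)
  })
}

#' Residue-residue contact map between two chain groups
#'
#' Lists every residue pair with any inter-atomic distance at or below the
#' cutoff (4 Angstrom by default, the convention for epitope/paratope
#' definition), with the minimum atom distance per pair.  The
#' grid-accelerated method and the brute-force all-pairs computation give
#' identical results.
#'
#' @param model A `structure_model`.
#' @param groupA,groupB Disjoint character vectors of chain ids.
#' @param cutoff Contact cutoff in Angstrom.
#' @param method `"grid"` (cell-list acceleration) or `"brute"`.
#'
#' @return data.frame of class `contact_set`: `chain_a`, `resno_a`,
#'   `resid_a`, `chain_b`, `resno_b`, `resid_b`, `dist`.
#' @export
contact_map <- function(model, groupA, groupB, cutoff = 4.0,
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  A <- sel_atoms(model, groupA)
  B <- sel_atoms(model, groupB)
  if (!nrow(A) || !nrow(B)) stop("empty chain group")
  xa <- coords_of(A)
  xb <- coords_of(B)
  pairs <- NULL
  if (method == "brute") {
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(ia = hit[, 1], ib = hit[, 2],
                          dist = sqrt(pmax(0, d2[hit])))
    }
  } else {
    origin <- apply(rbind(xa, xb), 2, min) - cutoff
    cand <- grid_candidates(xa, xb, cutoff, origin)
    res <- list()
    for (i in seq_len(nrow(xa))) {
      cb <- cand[[i]]
      if (!length(cb)) next
      d2 <- colSums((t(xb[cb, , drop = FALSE]) - xa[i, ])^2)
      ok <- d2 <= cutoff^2 + 1e-12
      if (any(ok)) {
        res[[length(res) + 1L]] <- data.frame(ia = i, ib = cb[ok],
                                              dist = sqrt(d2[ok]))
      }
    }
    if (length(res)) pairs <- do.call(rbind, res)
  }
  if (is.null(pairs)) {
    out <- data.frame(chain_a = character(0), resno_a = integer(0),
                      resid_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("contact_set", "data.frame"),
                     cutoff = cutoff))
  }
  key_a <- paste(A$chain[pairs$ia], A$resno[pairs$ia])
  key_b <- paste(B$chain[pairs$ib], B$resno[pairs$ib])
  grp <- paste(key_a, key_b, sep = "|")
  best <- tapply(seq_len(nrow(pairs)), grp, function(ix) ix[which.min(pairs$dist[ix])])
  best <- unname(unlist(best))
  out <- data.frame(chain_a = A$chain[pairs$ia[best]],
                    resno_a = A$resno[pairs$ia[best]],
                    resid_a = A$resid[pairs$ia[best]],
                    chain_b = B$chain[pairs$ib[best]],
                    resno_b = B$resno[pairs$ib[best]],
                    resid_b = B$resid[pairs$ib[best]],
                    dist = pairs$dist[best], stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
  rownames(out) <- NULL
  structure(out, class = c("contact_set", "data.frame"), cutoff = cutoff)
}

#' Distance between two uniquely selected atoms
#'
#' @param model A `structure_model`.
#' @param selA,selB Lists with `chain`, `resno` and optionally `elety`
#'   (default `"CA"`), each resolving to exactly one atom.
#' @return Euclidean distance in Angstrom.
#' @export
anchor_distance <- function(model, selA, selB) {
  pick <- function(sel) {
    elety <- if (is.null(sel$elety)) "CA" else sel$elety
    at <- model$atoms
    hit <- at[at$chain == sel$chain & at$resno == sel$resno &
                at$elety == elety, , drop = FALSE]
    if (nrow(hit) != 1L) {
      cand <- at[at$chain == sel$chain & at$resno == sel$resno, , drop = FALSE]
      stop("selection resolves to ", nrow(hit), " atoms (chain ", sel$chain,
           ", resno ", sel$resno, ", atom ", elety, "); candidates: ",
           paste(unique(cand$elety), collapse = ", "), call. = FALSE)
    }
    as.numeric(hit[1, c("x", "y", "z")])
  }
  a <- pick(selA)
  b <- pick(selB)
  sqrt(sum((a - b)^2))
}

#' Count Fabs bound to the protomer ring
#'
#' A Fab (heavy/light chain unit from the role annotation) counts as bound
#' when at least one of its atoms lies within `cutoff` of any protomer
#' atom.
#'
#' @param model A `structure_model` with role annotation.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Integer count of bound Fabs.
#' @export
count_bound_fabs <- function(model, cutoff = 4.0) {
  if (is.null(model$roles)) stop("model lacks chain role annotation")
  roles <- model$roles
  prot_chains <- roles$chain[roles$role == "protomer"]
  fab_units <- unique(roles$unit[roles$role %in% c("fab_heavy", "fab_light")])
  if (!length(prot_chains) || !length(fab_units)) {
    stop("role annotation must include protomer and fab chains")
  }
  xp <- coords_of(sel_atoms(model, prot_chains))
  n_bound <- 0L
  for (u in fab_units) {
    ch <- roles$chain[roles$unit == u & roles$role %in% c("fab_heavy", "fab_light")]
    xf <- coords_of(sel_atoms(model, ch))
    d2 <- outer(rowSums(xf^2), rowSums(xp^2), "+") - 2 * xf %*% t(xp)
    if (min(d2) <= cutoff^2 + 1e-12) n_bound <- n_bound + 1L
  }
  n_bound
}

#' Kabsch superposition RMSD
#'
#' Root-mean-square deviation after optimal rigid-body superposition
#' (Kabsch algorithm, proper rotation enforced via the SVD determinant
#' correction).
#'
#' @param X,Y n x 3 coordinate matrices of paired atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) {
    stop("coordinate sets must be equal-size n x 3 matrices")
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Yr <- Xc %*% t(R)
  sqrt(mean(rowSums((Yc - Yr)^2)))
}

#' Main-chain coordinates of a chain
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param atoms Atom names considered main chain.
#' @return n x 3 coordinate matrix ordered by residue number.
#' @export
main_chain_coords <- function(model, chain, atoms = c("N", "CA", "C", "O")) {
  at <- sel_atoms(model, chain)
  at <- at[at$elety %in% atoms, , drop = FALSE]
  at <- at[order(at$resno, match(at$elety, atoms)), , drop = FALSE]
  coords_of(at)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure model: %d atoms, %d chains%s\n", nrow(x$atoms),
              length(unique(x$atoms$chain)),
              if (is.null(x$roles)) "" else " (roles annotated)"))
  invisible(x)
}
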