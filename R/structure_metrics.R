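# Structural post-metrics on peptide-MHC models: superposition-based
# peptide RMSD, Shrake-Rupley solvent-accessible surface area, exposed
# hydrophobic surface, and salt-bridge detection.

#' Van der Waals radii used for SASA (Angstrom)
#'
#' @format Named numeric vector (C 1.70, N 1.55, O 1.52, S 1.80); elements
#'   not listed fall back to 1.70.
#' @export
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

element_radius <- function(element, radii = ELEMENT_RADII) {
  r <- radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

guess_element <- function(name) {
  e <- sub("^[0-9]*", "", trimws(name))
  first <- substr(e, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

#' Construct a peptide-MHC model
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. `"CA"`),
#'   `element`, `resid` (3-letter residue name), `resno`, `chain`, `x`,
#'   `y`, `z`; a `radius` column is added from [ELEMENT_RADII] when absent.
#' @param peptide_chain,mhc_chain Chain identifiers; both must be present.
#' @return Object of class `pmhc_model`.
#' @export
pmhc_model <- function(atoms, peptide_chain, mhc_chain) {
  required <- c("name", "element", "resid", "resno", "chain", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  for (ch in c(peptide_chain, mhc_chain)) {
    if (!ch %in% atoms$chain) stop("chain '", ch, "' not present in model")
  }
  if (!"radius" %in% names(atoms)) {
    atoms$radius <- element_radius(atoms$element)
  }
  structure(list(atoms = atoms, peptide_chain = peptide_chain,
                 mhc_chain = mhc_chain),
            class = "pmhc_model")
}

#' @export
print.pmhc_model <- function(x, ...) {
  np <- length(unique(x$atoms$resno[x$atoms$chain == x$peptide_chain]))
  cat(sprintf("<pmhc_model> %d atoms; peptide chain %s (%d residues), MHC chain %s\n",
              nrow(x$atoms), x$peptide_chain, np, x$mhc_chain))
  invisible(x)
}

#' Read a peptide-MHC model from a PDB file
#'
#' Parses standard fixed-column ATOM/HETATM records via bio3d. Only the
#' first MODEL of a multi-model file is used; waters and (by default) all
#' HETATM records are dropped. Malformed ATOM records are reported with
#' their line number.
#'
#' @param path PDB file path.
#' @param peptide_chain,mhc_chain Chain identifiers of the peptide and the
#'   MHC heavy chain.
#' @param keep_het Keep non-water HETATM records (default FALSE).
#' @return A `pmhc_model`.
#' @export
read_pdb_model <- function(path, peptide_chain, mhc_chain,
                           keep_het = FALSE) {
  lines <- readLines(path)
  # truncate multi-model files at the first ENDMDL
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1L)]
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || any(is.na(coords))) {
      stop("malformed ATOM/HETATM record at line ", i, ": ", ln)
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$resid != "HOH" & (keep_het | a$type == "ATOM")
  a <- a[keep, , drop = FALSE]
  element <- a$elesy
  element[is.na(element) | !nzchar(trimws(element))] <-
    guess_element(a$elety[is.na(element) | !nzchar(trimws(element))])
  atoms <- data.frame(name = a$elety, element = trimws(element),
                      resid = a$resid, resno = a$resno, chain = a$chain,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  pmhc_model(atoms, peptide_chain, mhc_chain)
}

#' Write a peptide-MHC model to a PDB file
#'
#' @param model A `pmhc_model`.
#' @param path Output path.
#' @export
write_pdb_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$name, elesy = a$element)
  invisible(path)
}

atom_key <- function(atoms) paste(atoms$resno, atoms$name)

backbone_names <- c("N", "CA", "C", "O")

# Least-squares superposition of model B onto model A using the MHC-chain
# backbone, peptide excluded from the fit. Returns B with moved coordinates.
superpose_on_mhc <- function(modelA, modelB) {
  fa <- modelA$atoms[modelA$atoms$chain == modelA$mhc_chain &
                       modelA$atoms$name %in% backbone_names, , drop = FALSE]
  fb <- modelB$atoms[modelB$atoms$chain == modelB$mhc_chain &
                       modelB$atoms$name %in% backbone_names, , drop = FALSE]
  keys <- intersect(atom_key(fa), atom_key(fb))
  if (length(keys) < 3) {
    stop("fewer than 3 shared MHC backbone atoms; cannot superpose")
  }
  ia <- match(keys, atom_key(fa))
  ib <- match(keys, atom_key(fb))
  fb_atom_idx <- which(modelB$atoms$chain == modelB$mhc_chain &
                         modelB$atoms$name %in% backbone_names)[ib]
  xyz_a <- as.numeric(t(as.matrix(fa[ia, c("x", "y", "z")])))
  xyz_b_all <- as.numeric(t(as.matrix(modelB$atoms[, c("x", "y", "z")])))
  moved <- bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b_all,
                          fixed.inds = seq_along(xyz_a),
                          mobile.inds = bio3d::atom2xyz(fb_atom_idx))
  out <- modelB
  m <- matrix(moved, ncol = 3, byrow = TRUE)
  out$atoms$x <- m[, 1]
  out$atoms$y <- m[, 2]
  out$atoms$z <- m[, 3]
  out
}

#' Peptide RMSD between two superposed peptide-MHC models
#'
#' Model B is first least-squares superposed onto model A using the shared
#' MHC-chain backbone atoms (the peptide takes no part in the fit), then the
#' RMSD is computed over the matched peptide atom pairs with no further
#' fitting, so it measures conformational change of the peptide in the
#' groove frame. `selection = "backbone"` uses N/CA/C/O; `"common_heavy"`
#' uses every heavy atom whose (residue number, atom name) pair exists in
#' both models, i.e. the atoms shared by both residue types at each
#' position.
#'
#' @param modelA,modelB `pmhc_model` objects with equal peptide lengths.
#' @param selection `"backbone"` or `"common_heavy"`.
#' @return List of class `rmsd_report` with `selection`, `n_atoms`, `rmsd`.
#' @export
peptide_rmsd <- function(modelA, modelB,
                         selection = c("backbone", "common_heavy")) {
  selection <- match.arg(selection)
  pa <- modelA$atoms[modelA$atoms$chain == modelA$peptide_chain, , drop = FALSE]
  pb <- modelB$atoms[modelB$atoms$chain == modelB$peptide_chain, , drop = FALSE]
  if (length(unique(pa$resno)) != length(unique(pb$resno))) {
    stop("peptide length mismatch between the two models")
  }
  modelB <- superpose_on_mhc(modelA, modelB)
  pb <- modelB$atoms[modelB$atoms$chain == modelB$peptide_chain, , drop = FALSE]
  if (selection == "backbone") {
    pa <- pa[pa$name %in% backbone_names, , drop = FALSE]
    pb <- pb[pb$name %in% backbone_names, , drop = FALSE]
  } else {
    pa <- pa[pa$element != "H", , drop = FALSE]
    pb <- pb[pb$element != "H", , drop = FALSE]
  }
  keys <- intersect(atom_key(pa), atom_key(pb))
  if (length(keys) == 0) stop("empty peptide atom selection")
  ma <- as.matrix(pa[match(keys, atom_key(pa)), c("x", "y", "z")])
  mb <- as.matrix(pb[match(keys, atom_key(pb)), c("x", "y", "z")])
  structure(
    list(selection = selection, n_atoms = length(keys),
         rmsd = sqrt(mean(rowSums((ma - mb)^2)))),
    class = "rmsd_report"
  )
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("<rmsd_report> %s: %.3f A over %d atoms\n",
              x$selection, x$rmsd, x$n_atoms))
  invisible(x)
}

# Near-uniform points on the unit sphere (golden-spiral construction).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals spheres by sampling
#' `n_points` near-uniform points on each atom's expanded sphere
#' (radius + probe) and counting the points not buried inside any
#' neighboring expanded sphere.
#'
#' @param x A `pmhc_model` or an atom data.frame with columns `x`, `y`,
#'   `z`, `radius`.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960; >= 100).
#' @return Numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
sasa <- function(x, probe = 1.4, n_points = 960L) {
  atoms <- if (inherits(x, "pmhc_model")) x$atoms else x
  if (!"radius" %in% names(atoms)) {
    atoms$radius <- element_radius(atoms$element)
  }
  if (n_points < 100) stop("n_points must be at least 100")
  pts <- sphere_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$radius + probe
  n <- nrow(atoms)
  areas <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neighbors <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in neighbors) {
      if (!any(accessible)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 >= rad[j]^2
    }
    areas[i] <- sum(accessible) / n_points * 4 * pi * rad[i]^2
  }
  areas
}

# Apolar atoms: carbon or sulfur not covalently bonded to nitrogen or
# oxygen, bonds inferred from heavy-atom distances below `bond_cutoff`.
apolar_mask <- function(atoms, bond_cutoff = 1.9) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  no_idx <- which(atoms$element %in% c("N", "O"))
  cand <- which(atoms$element %in% c("C", "S"))
  mask <- rep(FALSE, nrow(atoms))
  for (i in cand) {
    if (length(no_idx) > 0) {
      d2 <- (xyz[no_idx, 1] - xyz[i, 1])^2 + (xyz[no_idx, 2] - xyz[i, 2])^2 +
        (xyz[no_idx, 3] - xyz[i, 3])^2
      if (any(d2 < bond_cutoff^2)) next
    }
    mask[i] <- TRUE
  }
  mask
}

#' SASA report for the peptide of a model
#'
#' Computes per-atom SASA in the full-complex context (so peptide surface
#' buried against the MHC is excluded) and reports the peptide totals.
#'
#' @param model A `pmhc_model`.
#' @param probe,n_points Passed to [sasa()].
#' @return List of class `sasa_report`: `per_atom` (full model),
#'   `peptide_total`, `peptide_hydrophobic` (Angstrom^2).
#' @export
sasa_report <- function(model, probe = 1.4, n_points = 960L) {
  areas <- sasa(model, probe = probe, n_points = n_points)
  pep <- model$atoms$chain == model$peptide_chain
  apolar <- apolar_mask(model$atoms)
  structure(
    list(per_atom = areas,
         peptide_total = sum(areas[pep]),
         peptide_hydrophobic = sum(areas[pep & apolar])),
    class = "sasa_report"
  )
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf("<sasa_report> peptide total %.1f A^2, hydrophobic exposed %.1f A^2\n",
              x$peptide_total, x$peptide_hydrophobic))
  invisible(x)
}

#' Exposed hydrophobic surface area of the peptide
#'
#' Sum of per-atom SASA over the apolar atoms (carbon/sulfur not bonded to
#' N or O) of the peptide chain, computed in the full-complex context.
#'
#' @inheritParams sasa_report
#' @return Area in Angstrom^2.
#' @export
hydrophobic_exposed_area <- function(model, probe = 1.4, n_points = 960L) {
  sasa_report(model, probe = probe, n_points = n_points)$peptide_hydrophobic
}

#' Relative change between a wild-type and a mutant surface area
#'
#' `(a_mut - a_wt) / a_wt`; multiply by 100 for percent.
#'
#' @param a_wt,a_mut Areas (or any positive quantities).
#' @return Relative change.
#' @export
relative_change <- function(a_wt, a_mut) {
  if (any(a_wt <= 0)) stop("wild-type value must be positive")
  (a_mut - a_wt) / a_wt
}

SALT_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                   HIS = c("ND1", "NE2"))
SALT_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect salt bridges in a model
#'
#' Pairs every basic side-chain nitrogen (Arg NH1/NH2/NE, Lys NZ, His
#' ND1/NE2 when `include_his`) with every acidic side-chain oxygen (Asp
#' OD1/OD2, Glu OE1/OE2, plus the C-terminal OXT when `include_termini`)
#' and reports one record per residue pair at the minimum atom-atom
#' distance, when that distance is at most `cutoff`.
#'
#' @param model A `pmhc_model`.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param include_his Treat histidine as basic (default FALSE).
#' @param include_termini Treat C-terminal OXT atoms as acidic
#'   (default FALSE).
#' @return data.frame with columns `basic_resid`, `basic_chain`,
#'   `basic_resno`, `acidic_resid`, `acidic_chain`, `acidic_resno`,
#'   `distance`.
#' @export
detect_salt_bridges <- function(model, cutoff = 4.0, include_his = FALSE,
                                include_termini = FALSE) {
  a <- model$atoms
  basic_res <- SALT_BASIC
  if (!include_his) basic_res$HIS <- NULL
  is_basic <- mapply(function(resid, name) {
    resid %in% names(basic_res) && name %in% basic_res[[resid]]
  }, a$resid, a$name)
  is_acidic <- mapply(function(resid, name) {
    resid %in% names(SALT_ACIDIC) && name %in% SALT_ACIDIC[[resid]]
  }, a$resid, a$name)
  if (include_termini) is_acidic <- is_acidic | a$name == "OXT"
  bi <- which(is_basic)
  ai <- which(is_acidic)
  empty <- data.frame(basic_resid = character(), basic_chain = character(),
                      basic_resno = integer(), acidic_resid = character(),
                      acidic_chain = character(), acidic_resno = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (length(bi) == 0 || length(ai) == 0) return(empty)
  rows <- list()
  for (b in bi) {
    for (ac in ai) {
      if (a$chain[b] == a$chain[ac] && a$resno[b] == a$resno[ac]) next
      d <- sqrt((a$x[b] - a$x[ac])^2 + (a$y[b] - a$y[ac])^2 +
                  (a$z[b] - a$z[ac])^2)
      if (d > cutoff) next
      key <- paste(a$chain[b], a$resno[b], a$chain[ac], a$resno[ac])
      if (is.null(rows[[key]]) || rows[[key]]$distance > d) {
        rows[[key]] <- data.frame(
          basic_resid = a$resid[b], basic_chain = a$chain[b],
          basic_resno = a$resno[b], acidic_resid = a$resid[ac],
          acidic_chain = a$chain[ac], acidic_resno = a$resno[ac],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$distance), , drop = FALSE]
}
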