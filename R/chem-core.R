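# Molecular data model, structure/activity I/O, activity curation,
# RMSD and torsion-grid conformer generation.

.ELEMENT_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                    P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                   Br = 79.904, I = 126.904)

.element_radius <- function(el) {
  r <- .ELEMENT_RADII[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

.element_mass <- function(el) {
  m <- .ELEMENT_MASS[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a molecule
#'
#' A molecule is a set of typed atoms plus a bond list.  3D coordinates
#' supplied here become the molecule's reference geometry (its input
#' pose); all poses of the molecule share the atom ordering given here.
#' Feature classes (steric / donor / acceptor / cation / anion) are
#' assigned deterministically from the elements, bonds and formal
#' charges: charged atoms become cation/anion, N or O bearing an
#' explicit hydrogen becomes a donor, other N and all remaining O
#' become acceptors, and everything else (C, S, P, halogens, H) is
#' steric.
#'
#' @param id character identifier, unique within a ligand set.
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstroms.
#' @param bonds integer matrix (m x 3) of (i, j, order); may have zero
#'   rows for a single atom.
#' @param charges numeric vector of formal charges (default all 0).
#' @return An object of class `pq_molecule`.
#' @export
molecule <- function(id, elements, coords, bonds = NULL, charges = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  if (n == 0L) stop("molecule '", id, "' has zero atoms")
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching elements")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3L)
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
  if (nrow(bonds) > 0L && (max(bonds[, 1:2]) > n || min(bonds[, 1:2]) < 1L))
    stop("bond atom indices out of range for molecule '", id, "'")
  if (is.null(charges)) charges <- numeric(n)
  feat <- assign_feature_classes(elements, bonds, charges)
  mol <- structure(list(
    id = as.character(id),
    elements = as.character(elements),
    feature = feat,
    radius = .element_radius(elements),
    coords = unname(coords),
    bonds = unname(bonds),
    charges = as.numeric(charges),
    mol_weight = sum(.element_mass(elements))
  ), class = "pq_molecule")
  mol$rotatable <- rotatable_bonds(mol)
  mol
}

#' Deterministic feature-class assignment
#'
#' @param elements character vector of element symbols.
#' @param bonds integer matrix (m x 3) of (i, j, order).
#' @param charges numeric vector of formal charges.
#' @return Character vector in
#'   `c("steric", "donor", "acceptor", "cation", "anion")`.
#' @export
assign_feature_classes <- function(elements, bonds, charges = NULL) {
  n <- length(elements)
  if (is.null(charges)) charges <- numeric(n)
  has_h <- logical(n)
  if (NROW(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      if (elements[j] == "H") has_h[i] <- TRUE
      if (elements[i] == "H") has_h[j] <- TRUE
    }
  }
  feat <- rep("steric", n)
  feat[elements %in% c("N", "O") & !has_h] <- "acceptor"
  feat[elements %in% c("N", "O") & has_h] <- "donor"
  feat[charges > 0] <- "cation"
  feat[charges < 0] <- "anion"
  feat
}

#' Construct a pose
#'
#' A pose is one 3D placement (conformation plus orientation) of a
#' molecule.  All poses of one model live in a single global Cartesian
#' frame; no re-superposition is implied by any pose comparison.
#'
#' @param mol a `pq_molecule` (or its id as character when coords carry
#'   the full geometry and the molecule is resolved elsewhere).
#' @param coords n x 3 coordinate matrix, one row per atom of `mol`.
#' @param score optional score in pKi units.
#' @param provenance one of `"input"`, `"conformer"`, `"aligned"`,
#'   `"fitted"`.
#' @return Object of class `pq_pose`.
#' @export
pose <- function(mol, coords = NULL, score = NA_real_,
                 provenance = c("input", "conformer", "aligned", "fitted")) {
  provenance <- match.arg(provenance)
  if (inherits(mol, "pq_molecule")) {
    if (is.null(coords)) coords <- mol$coords
    id <- mol$id
    if (nrow(coords) != length(mol$elements))
      stop("pose has ", nrow(coords), " coordinates for a molecule with ",
           length(mol$elements), " atoms")
  } else {
    id <- as.character(mol)
    if (is.null(coords)) stop("coords required when mol is given as an id")
  }
  structure(list(molecule_id = id, coords = unname(as.matrix(coords)),
                 score = score, provenance = provenance),
            class = "pq_pose")
}

#' Root-mean-square deviation between two poses of one molecule
#'
#' Computed over corresponding atoms in the common model frame, with no
#' re-superposition.
#'
#' @param a,b `pq_pose` objects with equal atom counts.
#' @return RMSD in Angstroms.
#' @export
pose_rmsd <- function(a, b) {
  ca <- if (inherits(a, "pq_pose")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "pq_pose")) b$coords else as.matrix(b)
  if (nrow(ca) != nrow(cb))
    stop("atom-count mismatch: ", nrow(ca), " vs ", nrow(cb))
  sqrt(sum((ca - cb)^2) / nrow(ca))
}

#' Construct a ligand set
#'
#' @param molecules list of `pq_molecule`.
#' @param activities data frame with columns `id`, `activity` and
#'   optionally `n_assays`, `activity_range`; or NULL.
#' @return Object of class `pq_ligandset` with elements `molecules`
#'   (named list) and `activities` (data frame, one row per id).
#' @export
ligand_set <- function(molecules, activities = NULL) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(molecules) <- ids
  if (!is.null(activities)) {
    activities <- as.data.frame(activities)
    missing <- setdiff(activities$id, ids)
    if (length(missing))
      stop("activity ids with no structure: ", paste(missing, collapse = ", "))
    if (!"n_assays" %in% names(activities)) {
      agg <- aggregate_activities(activities$id, activities$activity)
      activities <- agg
    }
    rownames(activities) <- activities$id
  }
  structure(list(molecules = molecules, activities = activities),
            class = "pq_ligandset")
}

#' @export
print.pq_ligandset <- function(x, ...) {
  cat("Ligand set:", length(x$molecules), "molecules,",
      if (is.null(x$activities)) 0L else nrow(x$activities),
      "with activities\n")
  invisible(x)
}

# collapse duplicate assays to mean activity, keeping count and range
aggregate_activities <- function(ids, values) {
  sp <- split(as.numeric(values), as.character(ids))
  out <- data.frame(
    id = names(sp),
    activity = vapply(sp, mean, numeric(1)),
    n_assays = vapply(sp, length, integer(1)),
    activity_range = vapply(sp, function(v) diff(range(v)), numeric(1)),
    stringsAsFactors = FALSE
  )
  out[order(out$id), , drop = FALSE]
}

#' Curate an activity table
#'
#' Applies the standard pre-modelling filters: drop compounds with
#' molecular weight outside 100-800 Da, drop compounds whose assay
#' values are all at or below 4.0 (log units), average duplicate assay
#' values per compound, and drop compounds whose assay values disagree
#' by more than 2 log units.
#'
#' @param raw data frame with columns `id`, `activity`, `mol_weight`
#'   (one row per assay value; ids may repeat).
#' @return List with `kept` (data frame of id, activity, n_assays,
#'   activity_range, mol_weight) and `dropped` (data frame of id,
#'   reason).
#' @export
curate_activities <- function(raw) {
  raw <- as.data.frame(raw)
  if (nrow(raw) == 0L)
    return(list(kept = data.frame(id = character(0), activity = numeric(0),
                                  n_assays = integer(0),
                                  activity_range = numeric(0),
                                  mol_weight = numeric(0)),
                dropped = data.frame(id = character(0), reason = character(0))))
  sp <- split(raw, as.character(raw$id))
  kept <- list(); dropped <- list()
  for (id in sort(names(sp))) {
    g <- sp[[id]]
    mw <- g$mol_weight[1L]
    vals <- as.numeric(g$activity)
    rng <- diff(range(vals))
    if (!is.na(mw) && (mw < 100 || mw > 800)) {
      dropped[[id]] <- sprintf("MW out of range (%.1f)", mw)
    } else if (all(vals <= 4.0)) {
      dropped[[id]] <- "all activities <= 4.0"
    } else if (rng > 2.0) {
      dropped[[id]] <- sprintf("range %.2f > 2 log units", rng)
    } else {
      kept[[id]] <- data.frame(id = id, activity = mean(vals),
                               n_assays = length(vals),
                               activity_range = rng, mol_weight = mw,
                               stringsAsFactors = FALSE)
    }
  }
  list(
    kept = if (length(kept)) do.call(rbind, kept) else
      data.frame(id = character(0), activity = numeric(0),
                 n_assays = integer(0), activity_range = numeric(0),
                 mol_weight = numeric(0)),
    dropped = if (length(dropped))
      data.frame(id = names(dropped), reason = unlist(dropped),
                 row.names = NULL, stringsAsFactors = FALSE) else
      data.frame(id = character(0), reason = character(0))
  )
}

## ---------------------------------------------------------------- I/O

#' Read ligands from an SDF or MOL2 file, with an optional activity CSV
#'
#' Input 3D coordinates are preserved as each molecule's reference
#' geometry (its `"input"` pose).  The activity CSV must have a header
#' `id,activity`; duplicate ids are averaged, with the assay count and
#' value range recorded.
#'
#' @param structure_path path to an SDF (V2000) or MOL2 (TRIPOS) file;
#'   format chosen by extension (`.sdf`/`.mol` vs `.mol2`).
#' @param activity_path optional path to a CSV with columns
#'   `id,activity`.
#' @return A `pq_ligandset`.
#' @export
read_ligands <- function(structure_path, activity_path = NULL) {
  if (!file.exists(structure_path)) stop("no such file: ", structure_path)
  ext <- tolower(sub(".*\\.", "", structure_path))
  mols <- if (ext == "mol2") read_mol2_molecules(structure_path)
          else read_sdf_molecules(structure_path)
  act <- NULL
  if (!is.null(activity_path)) {
    tab <- read.csv(activity_path, stringsAsFactors = FALSE)
    if (!all(c("id", "activity") %in% names(tab)))
      stop("activity CSV must have columns id,activity")
    act <- aggregate_activities(tab$id, tab$activity)
  }
  ligand_set(mols, act)
}

#' Write a ligand set to SDF (plus optional activity CSV)
#'
#' @param ls a `pq_ligandset`.
#' @param structure_path output SDF path.
#' @param activity_path optional output CSV path (`id,activity`).
#' @return `structure_path`, invisibly.
#' @export
write_ligands <- function(ls, structure_path, activity_path = NULL) {
  write_sdf(ls$molecules, structure_path)
  if (!is.null(activity_path) && !is.null(ls$activities))
    write.csv(ls$activities[, c("id", "activity")], activity_path,
              row.names = FALSE, quote = FALSE)
  invisible(structure_path)
}

# SDF (V2000) reading via ChemmineR; formal charges recovered from the
# raw "M  CHG" lines, which ChemmineR does not surface directly.
read_sdf_molecules <- function(path) {
  raw <- readLines(path)
  rec_start <- c(1L, which(raw == "$$$$") + 1L)
  rec_start <- rec_start[rec_start <= length(raw)]
  # validate counts lines up front so zero-atom records are reported
  # by index rather than surfacing as downstream parse oddities
  for (k in seq_along(rec_start)) {
    cl <- raw[rec_start[k] + 3L]
    if (is.na(cl)) next
    n_at <- suppressWarnings(as.integer(substr(cl, 1L, 3L)))
    if (!is.na(n_at) && n_at == 0L)
      stop("empty molecule at record ", k)
  }
  sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e) stop("unparseable SDF: ",
                                            conditionMessage(e)))
  mols <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
    if (is.null(ab) || nrow(ab) == 0L)
      stop("empty molecule at record ", k)
    el <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
    bonds <- if (!is.null(bb) && nrow(bb) > 0L)
      unname(as.matrix(bb[, 1:3, drop = FALSE])) else NULL
    id <- ChemmineR::sdfid(sdf)
    if (is.null(id) || !nzchar(id)) id <- sprintf("mol%03d", k)
    charges <- numeric(length(el))
    # scan this record's raw text for charge lines
    from <- rec_start[k]
    to <- if (k < length(rec_start)) rec_start[k + 1L] - 1L else length(raw)
    for (line in grep("^M  CHG", raw[from:to], value = TRUE)) {
      toks <- as.numeric(strsplit(trimws(sub("^M  CHG", "", line)),
                                  "[[:space:]]+")[[1]])
      nchg <- toks[1L]
      for (q in seq_len(nchg))
        charges[toks[2L * q]] <- toks[2L * q + 1L]
    }
    mols[[k]] <- molecule(id, el, coords, bonds, charges)
  }
  mols
}

# minimal fixed-width V2000 writer (keeps M CHG lines, 4-decimal coords)
write_sdf <- function(mols, path) {
  if (inherits(mols, "pq_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    n <- length(m$elements); nb <- nrow(m$bonds)
    writeLines(c(m$id, "  pocketqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (i in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         m$coords[i, 1], m$coords[i, 2], m$coords[i, 3],
                         m$elements[i]), con)
    for (b in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0", m$bonds[b, 1], m$bonds[b, 2],
                         m$bonds[b, 3]), con)
    chg <- which(m$charges != 0)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg,
                                       as.integer(m$charges[chg])),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

# MOL2 (TRIPOS) reading via bio3d; multi-record files are split on
# @<TRIPOS>MOLECULE and parsed record by record.
read_mol2_molecules <- function(path) {
  raw <- readLines(path)
  starts <- grep("^@<TRIPOS>MOLECULE", raw)
  if (length(starts) == 0L) stop("unparseable MOL2: no MOLECULE record")
  ends <- c(starts[-1L] - 1L, length(raw))
  mols <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    tmp <- tempfile(fileext = ".mol2")
    writeLines(raw[starts[k]:ends[k]], tmp)
    x <- tryCatch(bio3d::read.mol2(tmp),
                  error = function(e) stop("unparseable MOL2 record ", k,
                                           ": ", conditionMessage(e)))
    unlink(tmp)
    if (is.null(x$atom) || nrow(x$atom) == 0L)
      stop("empty molecule at record ", k)
    el <- sub("\\..*$", "", x$atom$elety)
    coords <- cbind(x$atom$x, x$atom$y, x$atom$z)
    bonds <- if (!is.null(x$bond) && nrow(x$bond) > 0L)
      cbind(x$bond$origin, x$bond$target,
            suppressWarnings(ifelse(is.na(as.integer(x$bond$type)), 1L,
                                    as.integer(x$bond$type)))) else NULL
    id <- if (!is.null(x$name) && nzchar(x$name[1])) x$name[1] else
      sprintf("mol%03d", k)
    charges <- round(x$atom$charge)   # formal charges taken verbatim
    charges[is.na(charges)] <- 0
    mols[[k]] <- molecule(id, el, coords, bonds, charges)
  }
  mols
}

# MOL2 writer via bio3d (one call per record, appended)
write_mol2 <- function(mols, path) {
  if (inherits(mols, "pq_molecule")) mols <- list(mols)
  first <- TRUE
  for (m in mols) {
    n <- length(m$elements); nb <- nrow(m$bonds)
    atom <- data.frame(
      eleno = seq_len(n),
      elena = paste0(m$elements, seq_len(n)),
      x = m$coords[, 1], y = m$coords[, 2], z = m$coords[, 3],
      elety = m$elements, resno = 1L, resid = "LIG",
      charge = as.numeric(m$charges), statbit = NA,
      stringsAsFactors = FALSE)
    bond <- if (nb > 0L) data.frame(
      id = seq_len(nb), origin = m$bonds[, 1], target = m$bonds[, 2],
      type = as.character(m$bonds[, 3]), statbit = NA,
      stringsAsFactors = FALSE) else
      data.frame(id = integer(0), origin = integer(0), target = integer(0),
                 type = character(0), statbit = logical(0))
    x <- structure(list(atom = atom, bond = bond, substructure = NULL,
                        xyz = matrix(t(m$coords), nrow = 1),
                        info = c(n, nb, 0, 0, 0), name = m$id),
                   class = "mol2")
    bio3d::write.mol2(x, file = path, append = !first)
    first <- FALSE
  }
  invisible(path)
}

## ------------------------------------------------- conformer generation

# adjacency list from a bond matrix
.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(NROW(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# atoms reachable from `from` without crossing bond (from, to)
.side_atoms <- function(adj, from, excl) {
  seen <- logical(length(adj))
  seen[excl] <- TRUE
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
  }
  seen[excl] <- FALSE
  which(seen)
}

# TRUE when atom i is reachable from atom j without crossing bond b
.bond_in_ring <- function(n, bonds, b) {
  i <- bonds[b, 1L]; j <- bonds[b, 2L]
  seen <- logical(n)
  seen[j] <- TRUE
  stack <- j
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (bb in seq_len(nrow(bonds))) {
      if (bb == b) next
      u <- if (bonds[bb, 1L] == v) bonds[bb, 2L]
           else if (bonds[bb, 2L] == v) bonds[bb, 1L] else next
      if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
  }
  seen[i]
}

# rotatable = single-order, acyclic, both endpoints with another
# neighbour (rotating a terminal atom about its own bond is a no-op)
rotatable_bonds <- function(mol) {
  bonds <- mol$bonds
  if (NROW(bonds) == 0L) return(integer(0))
  n <- length(mol$elements)
  adj <- .adjacency(n, bonds)
  deg <- lengths(adj)
  out <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (bonds[b, 3L] != 1L) next
    if (deg[i] < 2L || deg[j] < 2L) next
    if (.bond_in_ring(n, bonds, b)) next
    out <- c(out, b)
  }
  out
}

# Rodrigues rotation matrix about unit axis u by angle theta
.rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# rotate subtree distal to bond (i -> j) by theta about the bond axis
.apply_torsion <- function(coords, adj, i, j, theta) {
  moving <- .side_atoms(adj, j, i)
  moving <- setdiff(moving, j)
  if (!length(moving)) return(coords)
  axis <- coords[j, ] - coords[i, ]
  R <- .rotation_about(axis, theta)
  shifted <- sweep(coords[moving, , drop = FALSE], 2, coords[j, ])
  coords[moving, ] <- sweep(shifted %*% t(R), 2, coords[j, ], "+")
  coords
}

#' Generate conformers by deterministic torsion-grid sampling
#'
#' Each rotatable bond is sampled on a fixed 60-degree grid; the full
#' grid is enumerated in lexicographic order and, when it exceeds `n`,
#' a seeded random subset (always including the input conformation) is
#' taken.  Bonded distances are preserved exactly (rigid subtree
#' rotations).
#'
#' @param mol a `pq_molecule`.
#' @param n maximum number of conformers.
#' @param seed integer seed controlling grid subsampling.
#' @param step_deg torsion grid step (default 60).
#' @return List of `pq_pose` with provenance `"conformer"`; fewer than
#'   `n` poses when the molecule admits fewer distinct grid states.
#' @export
generate_conformers <- function(mol, n, seed = 1L, step_deg = 60) {
  stopifnot(n >= 1L)
  rot <- mol$rotatable
  if (length(rot) == 0L)
    return(list(pose(mol, mol$coords, provenance = "conformer")))
  nsteps <- as.integer(round(360 / step_deg))
  total <- nsteps^length(rot)
  idx <- if (total <= n) seq_len(total) else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sort(unique(c(1L, sample.int(total, n - 1L))))
  }
  adj <- .adjacency(length(mol$elements), mol$bonds)
  out <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    state <- idx[q] - 1L
    coords <- mol$coords
    for (r in seq_along(rot)) {
      a <- state %% nsteps
      state <- state %/% nsteps
      if (a > 0) {
        b <- mol$bonds[rot[r], ]
        coords <- .apply_torsion(coords, adj, b[1L], b[2L],
                                 a * step_deg * pi / 180)
      }
    }
    out[[q]] <- pose(mol, coords, provenance = "conformer")
  }
  out
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Kabsch optimal rigid superposition of B onto A (n x 3 each);
# returns transformed B
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(B0 %*% t(R), 2, ca, "+")
}
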