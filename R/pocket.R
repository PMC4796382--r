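# Probe taxonomy and placement, pose-vs-probe interaction scoring,
# clash, probe redundancy, exploration envelope and its penalty.

#' Default pocket scoring constants
#'
#' The per-contact scoring surrogate: kind-compatible Gaussian wells in
#' distance (steric-steric optimum 4.0 A, width 1.0 A; polar
#' donor/acceptor pairs optimum 2.9 A, width 0.4 A with a squared-
#' cosine directionality factor inside a 60-degree cone), per-contact
#' maxima chosen so that roughly six to ten good contacts span the
#' typical pKi activity range, and a linear clash penalty below a
#' hard-core distance.
#'
#' @param steric_d0,steric_w,steric_max steric well position (A), width
#'   (A) and per-contact maximum (pKi).
#' @param polar_d0,polar_w,polar_max polar (donor-acceptor) well
#'   position, width, and per-contact maximum.
#' @param cone_deg half-angle of the polar interaction cone, degrees.
#' @param clash_core_polar,clash_core_steric hard-core distances (A)
#'   below which the linear clash penalty applies, for compatible polar
#'   pairs and for all other atom-probe pairs respectively.
#' @param clash_slope clash penalty slope, pKi per Angstrom.
#' @param cutoff interaction distance cutoff (A).
#' @return Named list of scoring constants.
#' @export
scoring_params <- function(steric_d0 = 4.0, steric_w = 1.0, steric_max = 1.0,
                           polar_d0 = 2.9, polar_w = 0.4, polar_max = 1.5,
                           cone_deg = 60,
                           clash_core_polar = 2.2, clash_core_steric = 3.0,
                           clash_slope = 2.0, cutoff = 8.0) {
  list(steric_d0 = steric_d0, steric_w = steric_w, steric_max = steric_max,
       polar_d0 = polar_d0, polar_w = polar_w, polar_max = polar_max,
       cone_deg = cone_deg, clash_core_polar = clash_core_polar,
       clash_core_steric = clash_core_steric, clash_slope = clash_slope,
       cutoff = cutoff)
}

#' Construct a probe set
#'
#' @param kind character vector in `c("steric","donor","acceptor")`.
#' @param position n x 3 matrix of probe centers (A).
#' @param direction n x 3 matrix of unit direction vectors (rows may be
#'   NA for steric probes).
#' @param weight numeric selection weights in [0, 1] (default 1).
#' @return Object of class `pq_probes`.
#' @export
probes <- function(kind, position, direction = NULL, weight = NULL) {
  position <- matrix(as.numeric(position), ncol = 3L)
  n <- length(kind)
  stopifnot(nrow(position) == n)
  if (is.null(direction)) direction <- matrix(NA_real_, n, 3L)
  direction <- matrix(as.numeric(direction), ncol = 3L)
  for (i in seq_len(n)) {
    if (!anyNA(direction[i, ])) {
      nv <- sqrt(sum(direction[i, ]^2))
      if (nv > 0) direction[i, ] <- direction[i, ] / nv
    }
  }
  if (is.null(weight)) weight <- rep(1, n)
  stopifnot(all(weight >= 0 & weight <= 1))
  structure(list(kind = as.character(kind), position = unname(position),
                 direction = unname(direction), weight = as.numeric(weight)),
            class = "pq_probes")
}

#' @export
length.pq_probes <- function(x) length(x$kind)

#' @export
`[.pq_probes` <- function(x, i) {
  probes(x$kind[i], x$position[i, , drop = FALSE],
         x$direction[i, , drop = FALSE], x$weight[i])
}

#' @export
print.pq_probes <- function(x, ...) {
  cat("Probe set:", length(x), "probes (",
      paste(names(table(x$kind)), table(x$kind), collapse = ", "), ")\n")
  invisible(x)
}

# combine two probe sets
c_probes <- function(a, b) {
  probes(c(a$kind, b$kind), rbind(a$position, b$position),
         rbind(a$direction, b$direction), c(a$weight, b$weight))
}

# probe kind compatible with which atom feature classes
.COMPATIBLE <- list(steric = c("steric"),
                    donor = c("acceptor", "anion"),
                    acceptor = c("donor", "cation"))

# Per-probe interaction and clash contributions of one pose at unit
# probe weight: the cached building block of all scoring.
probe_contributions <- function(p, prb, mol, params = scoring_params()) {
  A <- p$coords
  n <- nrow(A); K <- length(prb)
  S <- numeric(K); C <- numeric(K)
  if (K == 0L || n == 0L) return(list(S = S, C = C))
  # distances: n x K
  D2 <- outer(rowSums(A^2), rowSums(prb$position^2), "+") -
    2 * A %*% t(prb$position)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  cosang <- matrix(1, n, K)
  polar <- prb$kind != "steric"
  if (any(polar)) {
    for (k in which(polar)) {
      v <- sweep(A, 2, prb$position[k, ])       # probe -> atom
      nv <- sqrt(rowSums(v^2)); nv[nv == 0] <- 1
      cosang[, k] <- (v %*% prb$direction[k, ]) / nv
    }
  }
  cone_cos <- cos(params$cone_deg * pi / 180)
  feat <- mol$feature
  # hydrogens are volume-less here: no steric attraction, no clash
  # (in particular the H of a donor group legitimately sits well
  # inside any heavy-atom core distance of its acceptor)
  hyd <- mol$elements == "H"
  for (k in seq_len(K)) {
    compat <- feat %in% .COMPATIBLE[[prb$kind[k]]] & !hyd
    d <- D[, k]
    within <- compat & d <= params$cutoff
    if (prb$kind[k] == "steric") {
      if (any(within))
        S[k] <- sum(params$steric_max *
                      exp(-(d[within] - params$steric_d0)^2 /
                            (2 * params$steric_w^2)))
    } else {
      ok <- within & cosang[, k] >= cone_cos
      if (any(ok))
        S[k] <- sum(params$polar_max *
                      exp(-(d[ok] - params$polar_d0)^2 /
                            (2 * params$polar_w^2)) * cosang[ok, k]^2)
    }
    core <- ifelse(compat & prb$kind[k] != "steric",
                   params$clash_core_polar, params$clash_core_steric)
    pen <- pmin(0, d - core)
    pen[hyd] <- 0
    C[k] <- -params$clash_slope * sum(-pen[pen < 0])
  }
  list(S = S, C = C)
}

#' Interaction score and clash of a pose against a probe set
#'
#' The score is a weighted sum over kind-compatible (atom, probe) pairs
#' of smooth distance terms (see [scoring_params()]); the clash is the
#' accumulated linear penetration penalty (always <= 0).  Both are
#' linear in the probe weights and deterministic.
#'
#' @param p a `pq_pose`.
#' @param prb a `pq_probes` set (non-empty).
#' @param mol the `pq_molecule` the pose refers to.
#' @param params scoring constants.
#' @return List with `score` and `clash`, pKi units.
#' @export
interaction_score <- function(p, prb, mol, params = scoring_params()) {
  if (length(prb) == 0L) stop("probe set is empty")
  pc <- probe_contributions(p, prb, mol, params)
  list(score = sum(pc$S * prb$weight), clash = sum(pc$C * prb$weight))
}

#' Score of a ligand against a probe set: best pose in its pool
#'
#' Each pose's value is interaction score plus clash plus any
#' substructure-constraint penalties; the maximum over the pool is the
#' ligand's score and that pose is its optimal pose.  Ties go to the
#' lowest pose index.
#'
#' @param pool a `pq_posepool`.
#' @param prb a `pq_probes` set.
#' @param mol the `pq_molecule`.
#' @param params scoring constants.
#' @param constraints optional list of `pq_constraint`.
#' @return List with `best` (pKi), `optimal` (`pq_pose`),
#'   `optimal_index`, and per-pose `values`.
#' @export
ligand_score <- function(pool, prb, mol, params = scoring_params(),
                         constraints = NULL) {
  stopifnot(length(pool$poses) >= 1L)
  vals <- vapply(pool$poses, function(p) {
    sc <- interaction_score(p, prb, mol, params)
    sc$score + sc$clash + .constraint_total(p, constraints, mol)
  }, numeric(1))
  i <- which.max(vals)      # which.max takes the first (lowest index) tie
  list(best = vals[i], optimal = pool$poses[[i]], optimal_index = i,
       values = vals)
}

#' Spatial redundancy of a probe set
#'
#' For every like-kind probe pair closer than the preferred minimum
#' separation for that kind, the shortfall (threshold minus distance)
#' accrues; well-separated sets score 0.
#'
#' @param prb a `pq_probes` set.
#' @param min_dist_by_kind named numeric vector of preferred minimum
#'   separations (A) per kind.
#' @param weights optional probe weights (defaults to the probes' own);
#'   pair shortfalls are scaled by the product of the two weights so
#'   the binary case reduces to plain accumulation.
#' @return Redundancy R >= 0.
#' @export
probe_redundancy <- function(prb,
                             min_dist_by_kind = c(steric = 2.0, donor = 1.5,
                                                  acceptor = 1.5),
                             weights = NULL) {
  V <- redundancy_matrix(prb, min_dist_by_kind)
  w <- if (is.null(weights)) prb$weight else weights
  as.numeric(t(w) %*% V %*% w) / 2
}

# symmetric matrix of pairwise like-kind shortfalls (zero diagonal)
redundancy_matrix <- function(prb, min_dist_by_kind) {
  K <- length(prb)
  V <- matrix(0, K, K)
  if (K < 2L) return(V)
  P <- prb$position
  D2 <- outer(rowSums(P^2), rowSums(P^2), "+") - 2 * P %*% t(P)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  same <- outer(prb$kind, prb$kind, "==")
  thr <- matrix(min_dist_by_kind[prb$kind], K, K)
  short <- (thr - D) * (same & D < thr)
  diag(short) <- 0
  short
}

#' Exploration-envelope penalty parameters
#'
#' Default constants of the sigmoidal excursion penalty:
#' `eta = -2.0` pKi (asymptotic penalty), `kappa = -0.75` A (negated
#' midpoint), `lambda = 0.15` A (steepness).
#'
#' @param eta,kappa,lambda see description.
#' @return Named list.
#' @export
envelope_params <- function(eta = -2.0, kappa = -0.75, lambda = 0.15) {
  stopifnot(lambda > 0, eta <= 0)
  list(eta = eta, kappa = kappa, lambda = lambda)
}

#' Sigmoidal penalty for an atomic excursion beyond the envelope
#'
#' `e(d) = eta * (1 - 1 / (1 + exp((d + kappa) / lambda)))`: zero-ish
#' for small excursions, half the asymptote at `d = -kappa` (0.75 A by
#' default), approaching `eta` (-2.0 pKi) for deep protrusions.
#' Monotone non-increasing in `d`, bounded in `(eta, 0)`.
#'
#' @param d excursion distance(s), A, >= 0.
#' @param params an [envelope_params()] list.
#' @return Penalty (<= 0), vectorized over `d`.
#' @export
envelope_penalty <- function(d, params = envelope_params()) {
  params$eta * (1 - 1 / (1 + exp((d + params$kappa) / params$lambda)))
}

#' Build the exploration envelope from a set of poses
#'
#' The envelope is the union of atom-centered spheres of radius (atom
#' van der Waals radius + margin) over all atoms of the given poses.
#'
#' @param poses list of `pq_pose`.
#' @param molecules named list of `pq_molecule` resolving the poses.
#' @param margin added to each atomic radius (A), default 0.
#' @return Object of class `pq_envelope` with `centers` (m x 3) and
#'   `radii`.
#' @export
build_envelope <- function(poses, molecules, margin = 0) {
  stopifnot(length(poses) >= 1L)
  centers <- do.call(rbind, lapply(poses, `[[`, "coords"))
  radii <- unlist(lapply(poses, function(p)
    molecules[[p$molecule_id]]$radius)) + margin
  structure(list(centers = unname(centers), radii = unname(radii)),
            class = "pq_envelope")
}

#' Per-atom excursions of a pose beyond the envelope
#'
#' For each atom, the distance from its center to the nearest sphere
#' surface, measured from outside (zero when the atom center lies
#' inside any sphere).
#'
#' @param p a `pq_pose` (or coordinate matrix).
#' @param env a `pq_envelope`.
#' @return Numeric vector of excursions d_i >= 0, one per atom.
#' @export
pose_excursions <- function(p, env) {
  A <- if (inherits(p, "pq_pose")) p$coords else as.matrix(p)
  D2 <- outer(rowSums(A^2), rowSums(env$centers^2), "+") -
    2 * A %*% t(env$centers)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  exc <- sweep(D, 2, env$radii)
  pmax(0, apply(exc, 1, min))
}

# total envelope penalty of a pose (sum over atoms)
pose_envelope_penalty <- function(p, env, params = envelope_params()) {
  sum(envelope_penalty(pose_excursions(p, env), params))
}

#' Place candidate probes around a collection of pose pools
#'
#' Donor/acceptor candidates are placed along the polar-atom directions
#' of the leading poses of each pool at hydrogen-bond distance, with
#' the probe direction pointing back at the ligand atom; steric
#' candidates are lattice points on a shell around the pose union at
#' the steric optimum distance.  Candidates are deduplicated on grids
#' (polar spacing `polar_spacing`, steric spacing `steric_spacing`)
#' and returned in a deterministic order.
#'
#' @param pools list of `pq_posepool`.
#' @param molecules named list of `pq_molecule`.
#' @param params scoring constants (supplies the placement distances).
#' @param polar_spacing dedup grid spacing for polar candidates, A.
#'   Smaller values yield denser polar candidate sets.
#' @param steric_spacing lattice spacing for steric shell points, A.
#' @param top_poses number of leading poses used per pool.
#' @return A `pq_probes` candidate set (weights 0).
#' @export
place_candidate_probes <- function(pools, molecules,
                                   params = scoring_params(),
                                   polar_spacing = 1.0,
                                   steric_spacing = 1.5,
                                   top_poses = 3L) {
  if (length(pools) == 0L) stop("empty pool list")
  polar_kind <- character(0); polar_pos <- NULL; polar_dir <- NULL
  allcoords <- NULL; allrad <- numeric(0)
  for (pl in pools) {
    mol <- molecules[[pl$molecule_id]]
    use <- pl$poses[seq_len(min(top_poses, length(pl$poses)))]
    for (p in use) {
      allcoords <- rbind(allcoords, p$coords)
      allrad <- c(allrad, mol$radius)
      adj <- .adjacency(length(mol$elements), mol$bonds)
      for (i in seq_along(mol$feature)) {
        f <- mol$feature[i]
        if (!f %in% c("donor", "acceptor", "cation", "anion")) next
        nb <- adj[[i]]
        heavy <- nb[mol$elements[nb] != "H"]
        u <- if (length(heavy)) {
          v <- p$coords[i, ] - colMeans(p$coords[heavy, , drop = FALSE])
          v / sqrt(sum(v^2))
        } else c(0, 0, 1)
        pk <- if (f %in% c("donor", "cation")) "acceptor" else "donor"
        polar_kind <- c(polar_kind, pk)
        polar_pos <- rbind(polar_pos, p$coords[i, ] + params$polar_d0 * u)
        polar_dir <- rbind(polar_dir, -u)
      }
    }
  }
  # dedup polar candidates on a grid, keeping first occurrence per cell
  keep_p <- integer(0)
  if (length(polar_kind)) {
    cell <- paste(polar_kind,
                  round(polar_pos[, 1] / polar_spacing),
                  round(polar_pos[, 2] / polar_spacing),
                  round(polar_pos[, 3] / polar_spacing))
    keep_p <- which(!duplicated(cell))
  }
  # steric shell lattice around the pose union
  lo <- apply(allcoords, 2, min) - params$steric_d0 - 1
  hi <- apply(allcoords, 2, max) + params$steric_d0 + 1
  gx <- seq(lo[1], hi[1], by = steric_spacing)
  gy <- seq(lo[2], hi[2], by = steric_spacing)
  gz <- seq(lo[3], hi[3], by = steric_spacing)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  D2 <- outer(rowSums(G^2), rowSums(allcoords^2), "+") - 2 * G %*% t(allcoords)
  D2[D2 < 0] <- 0
  dmin <- sqrt(apply(D2, 1, min))
  shell <- G[dmin >= params$steric_d0 - 0.5 & dmin <= params$steric_d0 + 0.5,
             , drop = FALSE]
  kinds <- c(if (length(keep_p)) polar_kind[keep_p],
             rep("steric", nrow(shell)))
  pos <- rbind(if (length(keep_p)) polar_pos[keep_p, , drop = FALSE], shell)
  dirs <- rbind(if (length(keep_p)) polar_dir[keep_p, , drop = FALSE],
                matrix(NA_real_, nrow(shell), 3))
  ord <- order(match(kinds, c("steric", "donor", "acceptor")),
               round(pos[, 1], 6), round(pos[, 2], 6), round(pos[, 3], 6))
  probes(kinds[ord], pos[ord, , drop = FALSE], dirs[ord, , drop = FALSE],
         weight = rep(0, length(ord)))
}

## ------------------------------------------ pocketmol serialization

#' Serialize a fitted pocket model to JSON
#'
#' Versioned plain-text document holding the probes, envelope spheres,
#' quality-metric distributions, scoring constants, training optimal
#' poses and activities: sufficient to score new ligands.
#'
#' @param model a `pocketqsar` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pocketmol <- function(model, path) {
  mol_doc <- lapply(names(model$training_poses), function(id) {
    m <- model$molecules[[id]]
    list(id = id, elements = m$elements, feature = m$feature,
         radius = m$radius, charges = m$charges,
         bonds = m$bonds, input_coords = m$coords,
         optimal_coords = model$training_poses[[id]]$coords)
  })
  doc <- list(
    format = "pocketqsar-pocketmol",
    version = 1L,
    probes = list(kind = model$probes$kind,
                  position = model$probes$position,
                  direction = model$probes$direction,
                  weight = model$probes$weight),
    envelope = list(centers = model$envelope$centers,
                    radii = model$envelope$radii),
    distributions = model$distributions,
    scoring = model$config$scoring,
    envelope_params = model$config$envelope,
    envelope_margin = model$config$envelope_margin,
    n_poses = model$config$n_poses,
    objective = model$objective,
    training = list(
      ids = names(model$training_poses),
      activities = as.list(model$activities),   # keep names in JSON
      scores = as.list(model$training_scores),
      molecules = mol_doc)
  )
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a pocket model from its JSON serialization
#'
#' Reconstructs a scoring-capable `pocketqsar` object: probes,
#' envelope, quality distributions, training optimal poses and their
#' molecules.  Training pose pools and substructure constraints are
#' not serialized, so re-estimating distributions or incremental
#' training requires the original fitted object.
#'
#' @param path path written by [write_pocketmol()].
#' @return A `pocketqsar` model usable with [predict.pocketqsar()].
#' @export
read_pocketmol <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pocketqsar-pocketmol"))
    stop("not a pocketmol document: ", path)
  prb <- probes(doc$probes$kind, doc$probes$position,
                doc$probes$direction, doc$probes$weight)
  env <- structure(list(centers = matrix(doc$envelope$centers, ncol = 3),
                        radii = as.numeric(doc$envelope$radii)),
                   class = "pq_envelope")
  mols <- list(); tposes <- list()
  md <- doc$training$molecules
  get1 <- function(x) if (is.list(x) && length(x) == 1L) x[[1L]] else x
  as_mat3 <- function(x) {
    x <- get1(x)
    if (is.matrix(x)) x else matrix(unlist(x), ncol = 3, byrow = TRUE)
  }
  n_tr <- if (is.data.frame(md)) nrow(md) else length(md)
  for (k in seq_len(n_tr)) {
    row <- if (is.data.frame(md)) md[k, ] else md[[k]]
    bonds <- get1(row$bonds)
    if (!is.null(bonds) && !is.matrix(bonds) && length(unlist(bonds)))
      bonds <- matrix(unlist(bonds), ncol = 3, byrow = TRUE)
    if (is.matrix(bonds) && nrow(bonds) == 0L) bonds <- NULL
    m <- molecule(get1(row$id), unlist(get1(row$elements)),
                  as_mat3(row$input_coords), bonds,
                  unlist(get1(row$charges)))
    mols[[m$id]] <- m
    tposes[[m$id]] <- pose(m, as_mat3(row$optimal_coords),
                           provenance = "fitted")
  }
  act <- unlist(doc$training$activities)
  cfg <- pq_config(n_poses = doc$n_poses,
                   scoring = as.list(doc$scoring),
                   envelope = as.list(doc$envelope_params),
                   envelope_margin = doc$envelope_margin)
  dists <- lapply(doc$distributions, as.list)
  structure(list(probes = prb, training_pools = NULL,
                 training_poses = tposes, pose_values = NULL,
                 envelope = env, molecules = mols, activities = act,
                 constraints = NULL, config = cfg,
                 objective = doc$objective,
                 training_scores = unlist(doc$training$scores),
                 training_report = NULL, log = NULL,
                 distributions = dists, call = NULL),
            class = "pocketqsar")
}

#' Export envelope spheres as PDB pseudo-atoms for visualization
#'
#' @param env a `pq_envelope`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_envelope_pdb <- function(env, path) {
  lines <- sprintf(
    "HETATM%5d  ENV ENV A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_along(env$radii), seq_along(env$radii),
    env$centers[, 1], env$centers[, 2], env$centers[, 3],
    1.0, env$radii)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
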