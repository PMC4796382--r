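# Feature-channel Gaussian-overlap 3D similarity, alignment-hypothesis
# construction, pose-pool generation, substructure constraints.

# channel membership: charged atoms reinforce the corresponding
# hydrogen-bonding role, hydrogens count as (small) steric volume
.CHANNEL_OF <- c(steric = "steric", donor = "donor", acceptor = "acceptor",
                 cation = "donor", anion = "acceptor")
.CHANNEL_WEIGHTS <- c(steric = 1.0, donor = 0.5, acceptor = 0.5)
.GAUSS_WIDTH_SCALE <- 0.5   # per-atom Gaussian width = radius * this

# resolve pose -> (coords, channel, width); molecules looked up by the
# caller-supplied resolver (a named list of pq_molecule)
.pose_field <- function(p, mols) {
  m <- mols[[p$molecule_id]]
  if (is.null(m)) stop("unknown molecule id: ", p$molecule_id)
  list(coords = p$coords,
       channel = unname(.CHANNEL_OF[m$feature]),
       width = m$radius * .GAUSS_WIDTH_SCALE)
}

# total Gaussian-pair overlap between two atom fields restricted to one
# channel; closed form of the integral of a product of two isotropic
# Gaussians
.channel_overlap <- function(ca, wa, cb, wb) {
  if (length(wa) == 0L || length(wb) == 0L) return(0)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  d2[d2 < 0] <- 0
  s2 <- outer(wa^2, wb^2, "+")
  pref <- (2 * pi * outer(wa^2, wb^2) / s2)^1.5
  sum(pref * exp(-d2 / (2 * s2)))
}

# shared kernel: overlap terms per channel for fields fa, fb
.overlap_by_channel <- function(fa, fb) {
  chans <- union(unique(fa$channel), unique(fb$channel))
  out <- setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    ia <- fa$channel == ch; ib <- fb$channel == ch
    out[ch] <- .channel_overlap(fa$coords[ia, , drop = FALSE], fa$width[ia],
                                fb$coords[ib, , drop = FALSE], fb$width[ib])
  }
  out
}

# field with cached self-overlap; self-overlap is invariant under any
# rigid motion of the pose, which makes repeated alignment scoring cheap
.make_field <- function(p, mols) {
  f <- .pose_field(p, mols)
  f$self <- .overlap_by_channel(f, f)
  f
}

# similarity between two prebuilt fields (the hot path)
.sim_between <- function(fa, fb) {
  oab <- .overlap_by_channel(fa, fb)
  num <- 0; den <- 0
  for (ch in names(oab)) {
    wch <- .CHANNEL_WEIGHTS[[ch]]
    saa <- if (ch %in% names(fa$self)) unname(fa$self[ch]) else 0
    sbb <- if (ch %in% names(fb$self)) unname(fb$self[ch]) else 0
    if (saa <= 0 && sbb <= 0) next
    den <- den + wch
    if (saa > 0 && sbb > 0) num <- num + wch * oab[ch] / sqrt(saa * sbb)
  }
  if (den == 0) return(0)
  min(1, max(0, unname(num / den)))
}

#' 3D molecular similarity of two poses
#'
#' A normalized feature-channel Gaussian-overlap measure: each atom
#' contributes a spherical Gaussian (width half its van der Waals
#' radius) to its feature channel (steric, donor, acceptor; charged
#' atoms reinforce the matching polar channel).  Per channel the
#' similarity is `overlap(a,b) / sqrt(overlap(a,a) * overlap(b,b))`;
#' channels are combined with fixed weights (steric 1.0, donor 0.5,
#' acceptor 0.5).  The measure is symmetric, lies in [0, 1], equals 1
#' exactly when the two poses present identical feature-weighted shape
#' fields, and is smooth in the coordinates.
#'
#' @param a,b `pq_pose` objects in the common frame.
#' @param molecules named list of `pq_molecule` used to resolve atom
#'   typing for the two poses.
#' @return Similarity in [0, 1].
#' @export
similarity3d <- function(a, b, molecules) {
  .sim_between(.make_field(a, molecules), .make_field(b, molecules))
}

# similarity of a pose to the pooled field of several poses: per
# channel, the fraction of the pose's own field mass covered by the
# union field, capped at 1.  Used as the novelty surrogate.
union_similarity <- function(p, union_poses, molecules) {
  fa <- .pose_field(p, molecules)
  fus <- lapply(union_poses, .pose_field, mols = molecules)
  fu <- list(coords = do.call(rbind, lapply(fus, `[[`, "coords")),
             channel = unlist(lapply(fus, `[[`, "channel")),
             width = unlist(lapply(fus, `[[`, "width")))
  oau <- .overlap_by_channel(fa, fu)
  oaa <- .overlap_by_channel(fa, fa)
  num <- 0; den <- 0
  for (ch in names(oaa)) {
    wch <- .CHANNEL_WEIGHTS[[ch]]
    if (oaa[ch] <= 0) next
    den <- den + wch
    cov <- oau[ch] / oaa[ch]
    num <- num + wch * min(1, cov)
  }
  if (den == 0) return(0)
  min(1, max(0, num / den))
}

## --------------------------------------------- alignment machinery

# principal-axes frame of an atom cloud (rows of eigenvectors, det +1)
.principal_frame <- function(coords) {
  c0 <- colMeans(coords)
  X <- sweep(coords, 2, c0)
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = c0, axes = V)
}

# the four proper sign flips of a right-handed frame
.FLIPS <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

# candidate rigid placements of `coords` onto the frame of `ref_coords`
.moment_alignments <- function(coords, ref_coords) {
  fa <- .principal_frame(coords)
  fr <- .principal_frame(ref_coords)
  lapply(.FLIPS, function(s) {
    R <- fr$axes %*% diag(s) %*% t(fa$axes)
    sweep(sweep(coords, 2, fa$center) %*% t(R), 2, fr$center, "+")
  })
}

# greedy local rigid refinement of pose coords maximizing scorefun
.refine_rigid <- function(coords, scorefun, rot_steps = c(0.15, 0.05),
                          trans_steps = c(0.3, 0.1), max_sweeps = 6) {
  best <- scorefun(coords)
  axes <- diag(3)
  for (sweepi in seq_len(max_sweeps)) {
    improved <- FALSE
    ctr <- colMeans(coords)
    for (stp in seq_along(rot_steps)) {
      for (ax in 1:3) {
        for (sgn in c(1, -1)) {
          R <- .rotation_about(axes[ax, ], sgn * rot_steps[stp])
          cand <- sweep(sweep(coords, 2, ctr) %*% t(R), 2, ctr, "+")
          sc <- scorefun(cand)
          if (sc > best + 1e-9) { coords <- cand; best <- sc; improved <- TRUE }
        }
        for (sgn in c(1, -1)) {
          cand <- coords
          cand[, ax] <- cand[, ax] + sgn * trans_steps[stp]
          sc <- scorefun(cand)
          if (sc > best + 1e-9) { coords <- cand; best <- sc; improved <- TRUE }
        }
      }
    }
    if (!improved) break
  }
  list(coords = coords, score = best)
}

#' Build a seed alignment hypothesis from two or three ligands
#'
#' The first ligand's input geometry anchors the common frame.  Each
#' further ligand is assigned the pose (over its torsion-grid
#' conformers, moment-based rigid placements and local rigid
#' refinement) that maximizes the sum of pairwise 3D similarities to
#' the poses already in the hypothesis.  Deterministic throughout.
#'
#' Externally supplied aligned poses are passed through unchanged via
#' `poses` (`source = "external"`).
#'
#' @param ligands list of 2-3 `pq_molecule` from distinct molecules.
#' @param n_conf conformers considered per ligand.
#' @param seed conformer-grid seed.
#' @param poses optional list of externally aligned `pq_pose` (one per
#'   ligand) to pass through unchanged.
#' @return Object of class `pq_hypothesis` with fields `poses`,
#'   `molecules`, `source`.
#' @export
build_hypothesis <- function(ligands, n_conf = 12L, seed = 1L, poses = NULL) {
  if (!is.null(poses)) {
    if (length(poses) < 2L) stop("need at least 2 external poses")
    mols <- if (missing(ligands) || is.null(ligands)) NULL else ligands
    return(structure(list(poses = poses, molecules = .named_mols(mols),
                          source = "external"), class = "pq_hypothesis"))
  }
  if (length(ligands) < 2L) stop("need at least 2 ligands for a hypothesis")
  if (length(ligands) > 3L) ligands <- ligands[1:3]
  mols <- .named_mols(ligands)
  anchor <- pose(ligands[[1L]], provenance = "aligned")
  hyp <- list(anchor)
  hyp_fields <- list(.make_field(anchor, mols))
  for (m in ligands[-1L]) {
    confs <- generate_conformers(m, n_conf, seed = seed)
    best <- NULL; best_sc <- -Inf
    for (cf in confs) {
      meta <- .make_field(cf, mols)   # self-overlap survives rigid motion
      scorefun <- function(cc) {
        fa <- meta; fa$coords <- cc
        sum(vapply(hyp_fields, function(hf) .sim_between(fa, hf), numeric(1)))
      }
      for (cand in .moment_alignments(cf$coords,
                                      do.call(rbind, lapply(hyp, `[[`, "coords")))) {
        ref <- .refine_rigid(cand, scorefun)
        if (ref$score > best_sc + 1e-9) {
          best_sc <- ref$score
          best <- pose(m, ref$coords, provenance = "aligned")
        }
      }
    }
    hyp <- c(hyp, list(best))
    hyp_fields <- c(hyp_fields, list(.make_field(best, mols)))
  }
  structure(list(poses = hyp, molecules = mols, source = "similarity"),
            class = "pq_hypothesis")
}

.named_mols <- function(ligands) {
  if (is.null(ligands)) return(list())
  if (inherits(ligands, "pq_ligandset")) return(ligands$molecules)
  setNames(ligands, vapply(ligands, `[[`, character(1), "id"))
}

#' Substructure-constraint specification
#'
#' @param fragment a `pq_molecule` whose input geometry is the
#'   reference pose of the fragment in the model frame.
#' @param mode `"conformation"` (internal geometry only; deviation
#'   measured after optimal rigid superposition) or
#'   `"conformation_and_alignment"` (deviation measured in the fixed
#'   model frame).
#' @param weight penalty weight in pKi per squared Angstrom
#'   (default 1.0); the penalty applied is `-weight * MSD`.
#' @return Object of class `pq_constraint`.
#' @export
substructure_constraint <- function(fragment,
                                    mode = c("conformation",
                                             "conformation_and_alignment"),
                                    weight = 1.0) {
  mode <- match.arg(mode)
  stopifnot(weight >= 0)
  structure(list(fragment = fragment, mode = mode, weight = weight),
            class = "pq_constraint")
}

# element-colored VF2 subgraph matching of fragment into molecule;
# returns list of index vectors (fragment atom -> molecule atom),
# memoised per (molecule id, fragment id)
.match_cache <- new.env(parent = emptyenv())

substructure_matches <- function(mol, frag) {
  key <- paste0(mol$id, "\r", frag$id, "\r", length(mol$elements), "_",
                length(frag$elements))
  hit <- .match_cache[[key]]
  if (!is.null(hit)) return(hit)
  gm <- igraph::graph_from_edgelist(
    if (nrow(mol$bonds)) mol$bonds[, 1:2, drop = FALSE] else
      matrix(integer(0), ncol = 2), directed = FALSE)
  gm <- igraph::add_vertices(gm, max(0, length(mol$elements) -
                                       igraph::vcount(gm)))
  gf <- igraph::graph_from_edgelist(
    if (nrow(frag$bonds)) frag$bonds[, 1:2, drop = FALSE] else
      matrix(integer(0), ncol = 2), directed = FALSE)
  gf <- igraph::add_vertices(gf, max(0, length(frag$elements) -
                                       igraph::vcount(gf)))
  els <- sort(unique(c(mol$elements, frag$elements)))
  cm <- match(mol$elements, els)
  cf <- match(frag$elements, els)
  # vertex.color1 colors the target graph, vertex.color2 the pattern
  iso <- igraph::subgraph_isomorphisms(gf, gm, method = "vf2",
                                       vertex.color1 = cm,
                                       vertex.color2 = cf)
  out <- lapply(iso, as.integer)
  .match_cache[[key]] <- out
  out
}

#' Penalty for deviation of a matched substructure from its reference
#'
#' The fragment is substructure-matched into the pose's molecule
#' (element-typed subgraph isomorphism).  If it does not match, the
#' penalty is 0 (not every molecule need contain the constrained
#' fragment).  Otherwise the penalty is `-weight` times the mean
#' squared deviation (in squared Angstroms) of the matched atoms from
#' the fragment's reference coordinates; for `mode = "conformation"`
#' the deviation is measured after optimal rigid superposition, for
#' `mode = "conformation_and_alignment"` in the fixed model frame.
#' Over multiple matches the least-penalized match counts.
#'
#' @param p a `pq_pose`.
#' @param constraint a `pq_constraint`.
#' @param mol the `pq_molecule` that `p` refers to.
#' @return Penalty in pKi units (<= 0).
#' @export
constraint_penalty <- function(p, constraint, mol) {
  matches <- substructure_matches(mol, constraint$fragment)
  if (length(matches) == 0L) return(0)
  ref <- constraint$fragment$coords
  best <- Inf
  for (mp in matches) {
    sub <- p$coords[mp, , drop = FALSE]
    msd <- if (constraint$mode == "conformation") {
      fitted <- .kabsch(sub, ref)
      mean(rowSums((sub - fitted)^2))
    } else mean(rowSums((sub - ref)^2))
    if (msd < best) best <- msd
  }
  -constraint$weight * best
}

# total constraint penalty of a pose over a list of constraints
.constraint_total <- function(p, constraints, mol) {
  if (is.null(constraints) || length(constraints) == 0L) return(0)
  sum(vapply(constraints, function(cc) constraint_penalty(p, cc, mol),
             numeric(1)))
}

#' Generate a pool of aligned poses for one molecule
#'
#' Torsion-grid conformers are rigidly placed onto each hypothesis pose
#' (principal-moment pre-alignment with the four proper axis flips,
#' then greedy local rigid refinement of similarity), scored by their
#' best similarity to the hypothesis plus any substructure-constraint
#' penalties, deduplicated, and ranked.  The molecule's input pose is
#' always considered as a candidate.  Deterministic for a fixed seed;
#' ties are broken by candidate generation order.
#'
#' @param mol a `pq_molecule`.
#' @param hyp a `pq_hypothesis`.
#' @param n maximum pool size.
#' @param seed conformer-grid seed.
#' @param constraints optional list of `pq_constraint`.
#' @param n_conf number of conformers tried (default `n`).
#' @return Object of class `pq_posepool` with fields `molecule_id`,
#'   `poses` (list of `pq_pose`, provenance `"aligned"`, each with its
#'   guidance score), `optimal_index` (NA until model selection).
#' @export
generate_pose_pool <- function(mol, hyp, n, seed = 1L, constraints = NULL,
                               n_conf = NULL) {
  stopifnot(n >= 1L)
  if (is.null(n_conf)) n_conf <- max(4L, n)
  mols <- c(hyp$molecules, setNames(list(mol), mol$id))
  hyp_fields <- lapply(hyp$poses, .make_field, mols = mols)
  confs <- generate_conformers(mol, n_conf, seed = seed)
  cands <- list(pose(mol, mol$coords, provenance = "aligned"))
  cand_fields <- list(.make_field(cands[[1L]], mols))
  add_cand <- function(coords, meta) {
    p <- pose(mol, coords, provenance = "aligned")
    cands[[length(cands) + 1L]] <<- p
    fa <- meta; fa$coords <- coords
    cand_fields[[length(cand_fields) + 1L]] <<- fa
  }
  for (cf in confs) {
    meta <- .make_field(cf, mols)
    for (hi in seq_along(hyp$poses)) {
      hf <- hyp_fields[[hi]]
      scorefun <- function(cc) {
        fa <- meta; fa$coords <- cc
        .sim_between(fa, hf)
      }
      for (cand in .moment_alignments(cf$coords, hyp$poses[[hi]]$coords)) {
        ref <- .refine_rigid(cand, scorefun, max_sweeps = 3)
        add_cand(ref$coords, meta)
      }
    }
  }
  # optionally add fragment-snapped variants under alignment constraints
  if (!is.null(constraints)) {
    for (cc in constraints) {
      if (cc$mode != "conformation_and_alignment") next
      mm <- substructure_matches(mol, cc$fragment)
      if (length(mm) == 0L) next
      mp <- mm[[1L]]
      for (qi in seq_along(cands)) {
        # rigid move of the whole pose that lands the matched fragment
        # on its reference position
        p <- cands[[qi]]
        moved <- .kabsch_map(p$coords, p$coords[mp, , drop = FALSE],
                             cc$fragment$coords)
        add_cand(moved, cand_fields[[qi]])
      }
    }
  }
  # guidance score: best similarity to any hypothesis pose, plus
  # constraint penalties (pKi) acting as a soft filter
  gs <- vapply(seq_along(cands), function(qi) {
    s <- max(vapply(hyp_fields, function(hf)
      .sim_between(cand_fields[[qi]], hf), numeric(1)))
    s + .constraint_total(cands[[qi]], constraints, mol)
  }, numeric(1))
  ord <- order(-gs, seq_along(cands))
  keep <- list(); kept_scores <- numeric(0); kept_idx <- integer(0)
  for (k in ord) {
    dup <- FALSE
    for (kp in keep) if (pose_rmsd(cands[[k]], kp) < 0.05) { dup <- TRUE; break }
    if (!dup) {
      keep <- c(keep, list(cands[[k]]))
      kept_scores <- c(kept_scores, gs[k])
      kept_idx <- c(kept_idx, k)
      if (length(keep) >= n) break
    }
  }
  # the input pose (candidate 1) is never pruned outright: if the
  # ranking cut dropped it, it replaces the last kept pose, so input
  # coordinates always survive into the pool
  if (!any(vapply(keep, function(kp) pose_rmsd(cands[[1L]], kp) < 0.05,
                  logical(1)))) {
    keep[[length(keep)]] <- cands[[1L]]
    kept_scores[length(keep)] <- gs[1L]
  }
  for (q in seq_along(keep)) keep[[q]]$score <- kept_scores[q]
  structure(list(molecule_id = mol$id, poses = keep, optimal_index = NA_integer_),
            class = "pq_posepool")
}

# rigid transform of `coords` defined by superposing sub onto ref
.kabsch_map <- function(coords, sub, ref) {
  cs <- colMeans(sub); cr <- colMeans(ref)
  S0 <- sweep(sub, 2, cs); R0 <- sweep(ref, 2, cr)
  s <- svd(t(S0) %*% R0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(coords, 2, cs) %*% t(R), 2, cr, "+")
}
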