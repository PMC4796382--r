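# Deterministic greedy probe-subset selection: pose cliques, weighted
# then binarized probe optimization, refinement, incremental training,
# model-selection voting.

#' Objective weights for probe-subset selection
#'
#' The selection objective is `f = alpha*D + beta*(1-P) + gamma*R +
#' delta*C + epsilon*N` over the mean squared activity deviation D,
#' parsimony P, probe redundancy R, mean clash C (<= 0) and probe
#' count N.  The defaults make a unit improvement in f equivalent to:
#' 1.0 pKi^2 less deviation, 0.05 more parsimony, removal of a
#' like-kind probe pair 0.05 A closer than preferred, 1.0 pKi less
#' average clash magnitude, or about 33 fewer probes.
#'
#' @param alpha,beta,gamma,delta,epsilon term weights.
#' @return Named list of weights.
#' @export
objective_weights <- function(alpha = 1.0, beta = 20.0, gamma = 20.0,
                              delta = -1.0, epsilon = 0.03) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, delta <= 0, epsilon >= 0)
  list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
       epsilon = epsilon)
}

#' Evaluate the probe-selection objective
#'
#' @param terms list with `D` (pKi^2, >= 0), `P` (parsimony in [0,1]),
#'   `R` (redundancy >= 0), `C` (mean clash <= 0), `N` (probe count).
#' @param w an [objective_weights()] list.
#' @return Scalar f.
#' @export
objective <- function(terms, w = objective_weights()) {
  w$alpha * terms$D + w$beta * (1 - terms$P) + w$gamma * terms$R +
    w$delta * terms$C + w$epsilon * terms$N
}

#' Parsimony of a set of optimal poses
#'
#' The activity-weighted mean of pairwise pose similarities:
#' `P = sum_{i<j} w_ij sim(pose_i, pose_j) / sum_{i<j} w_ij` with
#' `w_ij = exp(-(act_i - act_j)^2 / (2 sigma_act^2))`, normalized to a
#' maximum of 1.  Identical activities weigh 1.0; widely separated
#' activities contribute little.
#'
#' @param optimal_poses list of `pq_pose`, one per molecule.
#' @param activities numeric vector of activities (pKi), same order.
#' @param molecules named list of `pq_molecule`.
#' @param sigma_act Gaussian width of the activity weighting (pKi).
#' @return P in [0, 1]; 0 (with a warning) if all pair weights vanish.
#' @export
parsimony <- function(optimal_poses, activities, molecules, sigma_act = 1.0) {
  n <- length(optimal_poses)
  stopifnot(n >= 2L, length(activities) == n)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    wij <- exp(-(activities[i] - activities[j])^2 / (2 * sigma_act^2))
    if (wij == 0) next
    num <- num + wij * similarity3d(optimal_poses[[i]], optimal_poses[[j]],
                                    molecules)
    den <- den + wij
  }
  if (den == 0) {
    warning("all parsimony pair weights are zero; P set to 0")
    return(0)
  }
  num / den
}

## -------------------------------------------------- selection state

# Precompute every cache the greedy optimizers touch: per-pose
# interaction/clash columns against every candidate probe, per-pose
# constraint constants, pairwise pose similarities between molecules,
# activity pair weights, and the probe redundancy matrix.
selection_state <- function(pools, candidates, molecules, activities,
                            weights = objective_weights(),
                            params = scoring_params(),
                            constraints = NULL, sigma_act = 1.0,
                            redundancy = c(steric = 2.0, donor = 1.5,
                                           acceptor = 1.5)) {
  stopifnot(length(pools) >= 1L, length(candidates) >= 1L)
  ids <- vapply(pools, `[[`, character(1), "molecule_id")
  act <- as.numeric(activities[ids])
  if (anyNA(act)) stop("missing activities for: ",
                       paste(ids[is.na(act)], collapse = ", "))
  n_mol <- length(pools)
  TS <- vector("list", n_mol); CM <- vector("list", n_mol)
  CONST <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    mol <- molecules[[ids[m]]]
    np <- length(pools[[m]]$poses)
    S <- matrix(0, np, length(candidates)); C <- matrix(0, np, length(candidates))
    cst <- numeric(np)
    for (q in seq_len(np)) {
      pc <- probe_contributions(pools[[m]]$poses[[q]], candidates, mol, params)
      S[q, ] <- pc$S; C[q, ] <- pc$C
      cst[q] <- .constraint_total(pools[[m]]$poses[[q]], constraints, mol)
    }
    TS[[m]] <- S + C; CM[[m]] <- C; CONST[[m]] <- cst
  }
  fields <- lapply(pools, function(pl)
    lapply(pl$poses, .make_field, mols = molecules))
  simpair <- vector("list", n_mol)
  for (i in seq_len(n_mol)) simpair[[i]] <- vector("list", n_mol)
  for (i in seq_len(max(0, n_mol - 1L))) for (j in (i + 1L):n_mol) {
    ni <- length(pools[[i]]$poses); nj <- length(pools[[j]]$poses)
    Sij <- matrix(0, ni, nj)
    for (a in seq_len(ni)) for (b in seq_len(nj))
      Sij[a, b] <- .sim_between(fields[[i]][[a]], fields[[j]][[b]])
    simpair[[i]][[j]] <- Sij
  }
  wpair <- exp(-outer(act, act, "-")^2 / (2 * sigma_act^2))
  diag(wpair) <- 0
  V <- redundancy_matrix(candidates, redundancy)
  e <- new.env(parent = emptyenv())
  e$pools <- pools; e$candidates <- candidates; e$ids <- ids; e$act <- act
  e$n_mol <- n_mol; e$K <- length(candidates)
  e$TS <- TS; e$CM <- CM; e$CONST <- CONST
  e$simpair <- simpair; e$wpair <- wpair
  e$wpair_den <- sum(wpair[upper.tri(wpair)])
  e$V <- V; e$weights <- weights
  class(e) <- "pq_selection_state"
  e
}

.state_parsimony <- function(st, opt) {
  if (st$n_mol < 2L) return(0)
  if (st$wpair_den == 0) return(0)
  num <- 0
  for (i in seq_len(st$n_mol - 1L)) for (j in (i + 1L):st$n_mol)
    num <- num + st$wpair[i, j] * st$simpair[[i]][[j]][opt[i], opt[j]]
  num / st$wpair_den
}

# exact objective at weight vector w; pose_idx fixes poses, NULL = free
state_objective <- function(st, w, pose_idx = NULL) {
  tot <- vector("list", st$n_mol)
  opt <- integer(st$n_mol); best <- numeric(st$n_mol); cl <- numeric(st$n_mol)
  for (m in seq_len(st$n_mol)) {
    tm <- drop(st$TS[[m]] %*% w) + st$CONST[[m]]
    tot[[m]] <- tm
    opt[m] <- if (is.null(pose_idx)) which.max(tm) else pose_idx[m]
    best[m] <- tm[opt[m]]
    cl[m] <- sum(st$CM[[m]][opt[m], ] * w)
  }
  terms <- list(D = mean((best - st$act)^2),
                P = .state_parsimony(st, opt),
                R = as.numeric(t(w) %*% st$V %*% w) / 2,
                C = mean(cl),
                N = sum(w > 1e-9))
  list(f = objective(terms, st$weights), terms = terms, opt = opt,
       tot = tot, best = best)
}

# Objective value for every single-coordinate move w -> w + deltas[k]*e_k,
# vectorized over k.  `cur` is the output of state_objective at w.
.move_objectives <- function(st, w, deltas, cur, pose_idx = NULL) {
  K <- st$K
  live <- which(deltas != 0)
  f <- rep(Inf, K)
  if (!length(live)) return(f)
  B <- matrix(0, st$n_mol, K)     # best score per molecule per move
  OPT <- matrix(0L, st$n_mol, K)  # optimal pose per molecule per move
  CL <- matrix(0, st$n_mol, K)    # clash of optimal pose per move
  for (m in seq_len(st$n_mol)) {
    tm <- cur$tot[[m]]
    if (is.null(pose_idx)) {
      M <- st$TS[[m]][, live, drop = FALSE]
      M <- sweep(M, 2, deltas[live], "*") + tm
      tM <- t(M)
      o <- max.col(tM, ties.method = "first")
      OPT[m, live] <- o
      B[m, live] <- M[cbind(o, seq_along(live))]
    } else {
      idx <- pose_idx[m]
      OPT[m, live] <- idx
      B[m, live] <- tm[idx] + st$TS[[m]][idx, live] * deltas[live]
    }
    cw <- drop(st$CM[[m]] %*% w)
    CL[m, live] <- cw[OPT[m, live]] +
      st$CM[[m]][cbind(OPT[m, live], live)] * deltas[live]
  }
  D <- colMeans((B[, live, drop = FALSE] - st$act)^2)
  C <- colMeans(CL[, live, drop = FALSE])
  # parsimony per move
  P <- numeric(length(live))
  if (st$n_mol >= 2L && st$wpair_den > 0) {
    num <- numeric(length(live))
    for (i in seq_len(st$n_mol - 1L)) for (j in (i + 1L):st$n_mol) {
      num <- num + st$wpair[i, j] *
        st$simpair[[i]][[j]][cbind(OPT[i, live], OPT[j, live])]
    }
    P <- num / st$wpair_den
  }
  Vw <- drop(st$V %*% w)
  R <- as.numeric(t(w) %*% Vw) / 2 + deltas[live] * Vw[live] +
    0.5 * deltas[live]^2 * diag(st$V)[live]
  wk <- w[live]
  N <- sum(w > 1e-9) + ((wk + deltas[live]) > 1e-9) - (wk > 1e-9)
  ww <- st$weights
  f[live] <- ww$alpha * D + ww$beta * (1 - P) + ww$gamma * R + ww$delta * C +
    ww$epsilon * N
  f
}

#' Find a parsimonious pose clique
#'
#' Starting from the first pose of every molecule, with one molecule's
#' pose held fixed, repeatedly sweeps over molecule pairs; for each
#' pair all replacement pose pairs are tried and the best is adopted
#' when it improves the clique parsimony.  Terminates at a local
#' optimum under pairwise replacement.  Deterministic: sweeps scan in
#' molecule-index order and ties keep the lowest pose indices.
#'
#' @param pools list of `pq_posepool`.
#' @param fixed integer pair `(molecule index, pose index)` held fixed.
#' @param molecules named list of `pq_molecule`.
#' @param activities named activities; when NULL, uniform activity
#'   weights are used.
#' @param sigma_act activity-weight width (pKi).
#' @param state optional prebuilt selection state (internal reuse).
#' @return List with `pose_idx` (chosen pose per molecule) and `P`.
#' @export
find_pose_clique <- function(pools, fixed, molecules = NULL,
                             activities = NULL, sigma_act = 1.0,
                             state = NULL) {
  if (is.null(state)) {
    ids <- vapply(pools, `[[`, character(1), "molecule_id")
    if (is.null(activities)) activities <- setNames(rep(0, length(ids)), ids)
    dummy <- probes("steric", matrix(0, 1, 3))
    state <- selection_state(pools, dummy, molecules, activities,
                             sigma_act = sigma_act)
  }
  st <- state
  n <- st$n_mol
  opt <- rep(1L, n)
  opt[fixed[1L]] <- as.integer(fixed[2L])
  if (n == 1L) return(list(pose_idx = opt, P = 0))
  if (st$wpair_den == 0) return(list(pose_idx = opt, P = 0))
  # per-molecule contribution to the parsimony numerator
  contrib <- function(i, p, cur) {
    s <- 0
    for (m in seq_len(n)) {
      if (m == i) next
      s <- s + st$wpair[i, m] * .sim_at(st, i, m, p, cur[m])
    }
    s
  }
  num <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    num <- num + st$wpair[i, j] * .sim_at(st, i, j, opt[i], opt[j])
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ni <- length(st$pools[[i]]$poses); nj <- length(st$pools[[j]]$poses)
      pi_cand <- if (i == fixed[1L]) opt[i] else seq_len(ni)
      pj_cand <- if (j == fixed[1L]) opt[j] else seq_len(nj)
      base <- num - contrib(i, opt[i], opt) - contrib(j, opt[j], opt) +
        st$wpair[i, j] * .sim_at(st, i, j, opt[i], opt[j])
      # A[p] = sum over m != i,j of w_im * S_im[p, opt_m]
      A <- vapply(pi_cand, function(p) {
        s <- 0
        for (m in seq_len(n)) if (m != i && m != j)
          s <- s + st$wpair[i, m] * .sim_at(st, i, m, p, opt[m])
        s
      }, numeric(1))
      Bv <- vapply(pj_cand, function(q) {
        s <- 0
        for (m in seq_len(n)) if (m != i && m != j)
          s <- s + st$wpair[j, m] * .sim_at(st, j, m, q, opt[m])
        s
      }, numeric(1))
      cross <- outer(pi_cand, pj_cand,
                     function(p, q) mapply(function(a, b)
                       .sim_at(st, i, j, a, b), p, q))
      candnum <- base + outer(A, Bv, "+") + st$wpair[i, j] * cross
      bi <- arrayInd(which.max(candnum), dim(candnum))
      if (candnum[bi] > num + 1e-12) {
        opt[i] <- pi_cand[bi[1L]]; opt[j] <- pj_cand[bi[2L]]
        num <- candnum[bi]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(pose_idx = opt, P = num / st$wpair_den)
}

# similarity between pose p of molecule i and pose q of molecule j
.sim_at <- function(st, i, j, p, q) {
  if (i < j) st$simpair[[i]][[j]][p, q] else st$simpair[[j]][[i]][q, p]
}

#' Greedy steepest-descent optimization of real probe weights
#'
#' Each cycle evaluates every single-probe weight change of the current
#' step size (both directions, clamped to [0, 1]) and applies the
#' single best improving change; ties go to the lowest probe index.
#' The step schedule (default 0.2 then 0.1) runs each step to a local
#' optimum or `max_cycles`.  With `free_poses`, each molecule's score
#' is the maximum over its pose pool; otherwise poses are fixed at
#' `pose_idx`.  f is non-increasing across accepted moves.
#'
#' @param state a selection state from `selection_state()`.
#' @param w starting weight vector in [0, 1].
#' @param pose_idx fixed pose per molecule (used when `free_poses` is
#'   FALSE).
#' @param free_poses logical.
#' @param step_schedule numeric vector of step sizes.
#' @param max_cycles cycle cap per step.
#' @param active logical mask of probes allowed to vary (default all).
#' @param log_env optional environment collecting `(stage, probe,
#'   delta, f)` move records in `log_env$log`.
#' @param stage label for logging.
#' @return List with `w`, `f`, `terms`, `opt`, `ever_positive`.
#' @export
optimize_probe_weights <- function(state, w, pose_idx = NULL,
                                   free_poses = is.null(pose_idx),
                                   step_schedule = c(0.2, 0.1),
                                   max_cycles = 10000L, active = NULL,
                                   log_env = NULL, stage = "weights") {
  st <- state
  if (is.null(active)) active <- rep(TRUE, st$K)
  fix <- if (free_poses) NULL else pose_idx
  cur <- state_objective(st, w, fix)
  ever_pos <- w > 1e-9
  for (step in step_schedule) {
    for (cycle in seq_len(max_cycles)) {
      dplus <- pmin(1, w + step) - w
      dminus <- pmax(0, w - step) - w
      dplus[!active] <- 0; dminus[!active] <- 0
      fp <- .move_objectives(st, w, dplus, cur, fix)
      fm <- .move_objectives(st, w, dminus, cur, fix)
      fbest <- pmin(fp, fm)
      k <- which.min(fbest)
      if (!(fbest[k] < cur$f - 1e-9)) break
      delta <- if (fp[k] <= fm[k]) dplus[k] else dminus[k]
      w[k] <- w[k] + delta
      cur <- state_objective(st, w, fix)
      ever_pos <- ever_pos | (w > 1e-9)
      if (!is.null(log_env))
        log_env$log[[length(log_env$log) + 1L]] <-
          list(stage = stage, probe = k, delta = delta, f = cur$f)
    }
  }
  list(w = w, f = cur$f, terms = cur$terms, opt = cur$opt,
       ever_positive = ever_pos)
}

#' Binarize probe weights by greedy single-flip descent
#'
#' Real weights are rounded to \{0, 1\} and single binary flips are
#' applied steepest-descent until no flip improves f.  The result is
#' locally optimal under any single binary weight change within the
#' active probe set.
#'
#' @inheritParams optimize_probe_weights
#' @param w real-valued weights from the weighted stage.
#' @return List with binary `w`, `f`, `terms`, `opt`, `delta_f`
#'   (f(binary) - f(real)) and `flag` (TRUE when that gap exceeds 1.0).
#' @export
binarize_weights <- function(state, w, pose_idx = NULL,
                             free_poses = is.null(pose_idx),
                             max_cycles = 10000L, active = NULL,
                             log_env = NULL, stage = "binarize") {
  st <- state
  if (is.null(active)) active <- rep(TRUE, st$K)
  fix <- if (free_poses) NULL else pose_idx
  f_real <- state_objective(st, w, fix)$f
  wb <- as.numeric(w >= 0.5)
  wb[!active & w < 0.5] <- 0
  cur <- state_objective(st, wb, fix)
  for (cycle in seq_len(max_cycles)) {
    deltas <- 1 - 2 * wb
    deltas[!active] <- 0
    f <- .move_objectives(st, wb, deltas, cur, fix)
    k <- which.min(f)
    if (!(f[k] < cur$f - 1e-9)) break
    wb[k] <- wb[k] + deltas[k]
    cur <- state_objective(st, wb, fix)
    if (!is.null(log_env))
      log_env$log[[length(log_env$log) + 1L]] <-
        list(stage = stage, probe = k, delta = deltas[k], f = cur$f)
  }
  delta_f <- cur$f - f_real
  list(w = wb, f = cur$f, terms = cur$terms, opt = cur$opt,
       delta_f = delta_f, flag = isTRUE(delta_f > 1.0))
}

#' Select a probe subset forming an initial pocket model
#'
#' Cold start: up to ten parsimonious pose cliques are built, each by
#' fixing one of the first five poses of the first or second training
#' molecule; for each clique the four-stage greedy procedure runs
#' (clique, weighted optimization at fixed poses with steps 0.2 and
#' 0.1, weighted optimization with free pose choice restricted to
#' probes that held positive weight, binarization), and the lowest-f
#' result wins (ties to the lowest clique index).  Warm start
#' (`warm_start` = logical or numeric starting weights): cliques are
#' skipped; optimization starts from the existing probes' weights with
#' free poses, then all probes are considered.
#'
#' @param pools list of `pq_posepool` for the training molecules.
#' @param candidates `pq_probes` candidate set.
#' @param molecules named list of `pq_molecule`.
#' @param activities named numeric activities (pKi).
#' @param weights an [objective_weights()] list.
#' @param params scoring constants.
#' @param constraints optional list of `pq_constraint`.
#' @param sigma_act parsimony activity width.
#' @param redundancy preferred like-kind probe separations (A).
#' @param n_cliques number of pose cliques attempted (cold start).
#' @param step_schedule weight step schedule.
#' @param max_cycles cycle cap per optimization stage.
#' @param warm_start NULL for cold start, or a numeric weight vector of
#'   length equal to the candidates giving the pre-existing probe set.
#' @param good_probe_min candidate-set size above which the free-pose
#'   and binarization stages restrict weight variation to "good"
#'   probes (those that held positive weight earlier); the restriction
#'   exists to limit computational cost, so small problems are always
#'   optimized over the full candidate set.
#' @param state optional prebuilt selection state.
#' @return List of class `pq_selection` with `w` (binary weights),
#'   `probes` (selected subset), `pose_idx`, `f`, `terms`, `clique`,
#'   `log` (list of move records), `binarize_flag`.
#' @export
select_probe_subset <- function(pools, candidates, molecules, activities,
                                weights = objective_weights(),
                                params = scoring_params(),
                                constraints = NULL, sigma_act = 1.0,
                                redundancy = c(steric = 2.0, donor = 1.5,
                                               acceptor = 1.5),
                                n_cliques = 10L,
                                step_schedule = c(0.2, 0.1),
                                max_cycles = 10000L,
                                warm_start = NULL, good_probe_min = 32L,
                                state = NULL) {
  if (is.null(state))
    state <- selection_state(pools, candidates, molecules, activities,
                             weights, params, constraints, sigma_act,
                             redundancy)
  st <- state
  log_env <- new.env(parent = emptyenv()); log_env$log <- list()
  if (!is.null(warm_start)) {
    w0 <- as.numeric(warm_start)
    stopifnot(length(w0) == st$K)
    res1 <- optimize_probe_weights(st, w0, free_poses = TRUE,
                                   step_schedule = step_schedule,
                                   max_cycles = max_cycles,
                                   active = w0 > 1e-9,
                                   log_env = log_env, stage = "warm-restricted")
    res2 <- optimize_probe_weights(st, res1$w, free_poses = TRUE,
                                   step_schedule = step_schedule,
                                   max_cycles = max_cycles,
                                   log_env = log_env, stage = "warm-all")
    bin <- binarize_weights(st, res2$w, free_poses = TRUE,
                            max_cycles = max_cycles,
                            log_env = log_env, stage = "warm-binarize")
    best <- list(w = bin$w, f = bin$f, terms = bin$terms, opt = bin$opt,
                 clique = NA_integer_, flag = bin$flag)
  } else {
    # clique anchors: first/second molecule x first five poses
    anchors <- list()
    for (mi in c(1L, 2L)) {
      if (mi > st$n_mol) next
      npose <- length(pools[[mi]]$poses)
      for (pi in seq_len(min(5L, npose)))
        anchors[[length(anchors) + 1L]] <- c(mi, pi)
    }
    anchors <- anchors[seq_len(min(n_cliques, length(anchors)))]
    best <- NULL
    for (ci in seq_along(anchors)) {
      clq <- find_pose_clique(pools, anchors[[ci]], state = st)
      res <- optimize_probe_weights(st, rep(0, st$K),
                                    pose_idx = clq$pose_idx,
                                    free_poses = FALSE,
                                    step_schedule = step_schedule,
                                    max_cycles = max_cycles,
                                    log_env = log_env,
                                    stage = sprintf("clique%02d-fixed", ci))
      good <- res$ever_positive
      if (!any(good) || st$K <= good_probe_min) good <- rep(TRUE, st$K)
      res2 <- optimize_probe_weights(st, res$w, free_poses = TRUE,
                                     step_schedule = step_schedule,
                                     max_cycles = max_cycles, active = good,
                                     log_env = log_env,
                                     stage = sprintf("clique%02d-free", ci))
      bin <- binarize_weights(st, res2$w, free_poses = TRUE,
                              max_cycles = max_cycles, active = good,
                              log_env = log_env,
                              stage = sprintf("clique%02d-binarize", ci))
      if (is.null(best) || bin$f < best$f - 1e-12) {
        best <- list(w = bin$w, f = bin$f, terms = bin$terms, opt = bin$opt,
                     clique = ci, flag = bin$flag)
      }
    }
  }
  sel <- which(best$w > 0.5)
  chosen <- st$candidates[sel]
  chosen$weight <- rep(1, length(sel))
  structure(list(w = best$w, probes = chosen,
                 selected = sel, pose_idx = best$opt, f = best$f,
                 terms = best$terms, clique = best$clique,
                 log = log_env$log, binarize_flag = best$flag),
            class = "pq_selection")
}

#' Refine probe positions and training poses
#'
#' Alternates (a) local perturbation of each probe position on a fixed
#' six-direction stencil, accepted only when the mean squared activity
#' deviation D decreases, and (b) re-selection of each molecule's
#' optimal pose.  The pocket composition (probe count and kinds) never
#' changes; D is non-increasing across rounds.
#'
#' @param prb selected `pq_probes` (binary weights).
#' @param pools list of `pq_posepool`.
#' @param molecules named list of `pq_molecule`.
#' @param activities named activities.
#' @param params scoring constants.
#' @param constraints optional constraints.
#' @param n_rounds refinement rounds.
#' @param step stencil displacement(s) (A); a vector is recycled over
#'   rounds, so a coarse-to-fine schedule like `c(0.2, 0.1)` walks
#'   probes off the candidate grid before polishing.
#' @return List with refined `probes`, `pose_idx`, `D`, `D_trace`.
#' @export
refine_probes <- function(prb, pools, molecules, activities,
                          params = scoring_params(), constraints = NULL,
                          n_rounds = 4L, step = c(0.2, 0.1)) {
  ids <- vapply(pools, `[[`, character(1), "molecule_id")
  act <- as.numeric(activities[ids])
  n_mol <- length(pools)
  # per-molecule contribution caches (columns recomputed when a probe moves)
  TS <- vector("list", n_mol); CONST <- vector("list", n_mol)
  fill_col <- function(prb_now, k = NULL) {
    for (m in seq_len(n_mol)) {
      mol <- molecules[[ids[m]]]
      for (q in seq_along(pools[[m]]$poses)) {
        pc <- probe_contributions(pools[[m]]$poses[[q]],
                                  if (is.null(k)) prb_now else prb_now[k],
                                  mol, params)
        if (is.null(k)) TS[[m]][q, ] <<- pc$S + pc$C
        else TS[[m]][q, k] <<- pc$S + pc$C
      }
    }
  }
  for (m in seq_len(n_mol)) {
    np <- length(pools[[m]]$poses)
    TS[[m]] <- matrix(0, np, length(prb))
    mol <- molecules[[ids[m]]]
    CONST[[m]] <- vapply(pools[[m]]$poses, function(p)
      .constraint_total(p, constraints, mol), numeric(1))
  }
  fill_col(prb)
  D_of <- function() {
    best <- numeric(n_mol)
    for (m in seq_len(n_mol))
      best[m] <- max(rowSums(TS[[m]]) + CONST[[m]])
    mean((best - act)^2)
  }
  steps <- rep(step, length.out = n_rounds)
  D_trace <- D_cur <- D_of()
  for (round in seq_len(n_rounds)) {
    stencil <- rbind(diag(3) * steps[round], -diag(3) * steps[round])
    for (k in seq_along(prb$kind)) {
      base_pos <- prb$position[k, ]
      best_D <- D_cur; best_pos <- base_pos
      for (s in seq_len(nrow(stencil))) {
        prb$position[k, ] <- base_pos + stencil[s, ]
        fill_col(prb, k)
        Dn <- D_of()
        if (Dn < best_D - 1e-12) { best_D <- Dn; best_pos <- prb$position[k, ] }
      }
      prb$position[k, ] <- best_pos
      fill_col(prb, k)
      D_cur <- best_D
    }
    D_trace <- c(D_trace, D_cur)
  }
  opt <- integer(n_mol)
  for (m in seq_len(n_mol))
    opt[m] <- which.max(rowSums(TS[[m]]) + CONST[[m]])
  list(probes = prb, pose_idx = opt, D = D_cur, D_trace = D_trace)
}

#' Vote-based model selection
#'
#' Each candidate model carries a training report; the best candidate
#' on each of Kendall's tau (higher), mean absolute error (lower) and
#' parsimony (higher) receives a vote, and the most-voted candidate
#' wins.  Ties break by best tau, then lowest error, then lowest
#' candidate index.
#'
#' @param candidates list of lists, each with elements `model` and
#'   `report` (the report holding `tau`, `mae`, `parsimony`).
#' @return The winning candidate's `model`, with the winning index in
#'   attribute `"selected"`.
#' @export
select_model <- function(candidates) {
  stopifnot(length(candidates) >= 1L)
  if (length(candidates) == 1L) {
    out <- candidates[[1L]]$model
    attr(out, "selected") <- 1L
    return(out)
  }
  tau <- vapply(candidates, function(x) x$report$tau, numeric(1))
  mae <- vapply(candidates, function(x) x$report$mae, numeric(1))
  pars <- vapply(candidates, function(x) x$report$parsimony, numeric(1))
  votes <- tabulate(c(which.max(tau), which.min(mae), which.max(pars)),
                    nbins = length(candidates))
  top <- which(votes == max(votes))
  if (length(top) > 1L) top <- top[order(-tau[top], mae[top], top)][1L]
  out <- candidates[[top]]$model
  attr(out, "selected") <- top
  out
}
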