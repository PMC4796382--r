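# Top-level model fitting: pocket_qsar() and the incremental trainer.

#' Configuration for pocket induction
#'
#' @param n_poses pose-pool size per training molecule.
#' @param seed master seed; all stage seeds derive from it.
#' @param weights an [objective_weights()] list.
#' @param scoring a [scoring_params()] list.
#' @param envelope an [envelope_params()] list.
#' @param envelope_margin added to atomic radii when building the
#'   envelope (A).
#' @param sigma_act parsimony activity-weight width (pKi).
#' @param redundancy preferred like-kind probe separations (A).
#' @param polar_densities polar candidate dedup spacings (A); one
#'   model is built per value and the best is kept by vote.
#' @param steric_spacing steric candidate lattice spacing (A).
#' @param n_cliques pose cliques attempted per model.
#' @param step_schedule weight-change step schedule.
#' @param max_cycles optimization cycle cap per stage.
#' @param refine_rounds probe-position refinement rounds.
#' @param tie_threshold tau tie threshold for training reports.
#' @return Named list of class `pq_config`.
#' @export
pq_config <- function(n_poses = 20L, seed = 1L,
                      weights = objective_weights(),
                      scoring = scoring_params(),
                      envelope = envelope_params(),
                      envelope_margin = 0,
                      sigma_act = 1.0,
                      redundancy = c(steric = 2.0, donor = 1.5,
                                     acceptor = 1.5),
                      polar_densities = c(0.75, 1.0, 1.5),
                      steric_spacing = 1.5,
                      n_cliques = 10L,
                      step_schedule = c(0.2, 0.1),
                      max_cycles = 10000L,
                      refine_rounds = 4L,
                      tie_threshold = 0.1) {
  structure(list(n_poses = n_poses, seed = as.integer(seed),
                 weights = weights, scoring = scoring, envelope = envelope,
                 envelope_margin = envelope_margin, sigma_act = sigma_act,
                 redundancy = redundancy, polar_densities = polar_densities,
                 steric_spacing = steric_spacing, n_cliques = n_cliques,
                 step_schedule = step_schedule, max_cycles = max_cycles,
                 refine_rounds = refine_rounds,
                 tie_threshold = tie_threshold),
            class = "pq_config")
}

# assemble the final model object from its parts
.finalize_model <- function(prb, pools, pose_idx, molecules, act,
                            constraints, config, selection, training_call) {
  n_mol <- length(pools)
  ids <- vapply(pools, `[[`, character(1), "molecule_id")
  pose_values <- vector("list", n_mol)
  scores <- numeric(n_mol)
  for (m in seq_len(n_mol)) {
    ls_m <- ligand_score(pools[[m]], prb, molecules[[ids[m]]],
                         config$scoring, constraints)
    pose_values[[m]] <- ls_m$values
    pools[[m]]$optimal_index <- pose_idx[m]
    scores[m] <- ls_m$values[pose_idx[m]]
  }
  training_poses <- setNames(lapply(seq_len(n_mol), function(m)
    pools[[m]]$poses[[pose_idx[m]]]), ids)
  env <- build_envelope(unname(training_poses), molecules,
                        margin = config$envelope_margin)
  P <- if (n_mol >= 2L)
    parsimony(unname(training_poses), act[ids], molecules,
              config$sigma_act) else NA_real_
  report <- list(
    tau = if (n_mol >= 2L) kendall_tau(act[ids], scores,
                                       config$tie_threshold) else NA_real_,
    mae = mean(abs(act[ids] - scores)),
    parsimony = P)
  model <- structure(list(
    probes = prb, training_pools = pools, training_poses = training_poses,
    pose_values = pose_values, envelope = env,
    molecules = molecules, activities = act, constraints = constraints,
    config = config, objective = selection[c("f", "terms", "clique")],
    training_scores = setNames(scores, ids), training_report = report,
    log = selection$log, distributions = NULL,
    call = training_call), class = "pocketqsar")
  model$distributions <- estimate_distributions(model)
  model
}

#' Induce a pocket model from ligands and activities
#'
#' The full induction pipeline: an alignment hypothesis (built from
#' the two most active ligands when not supplied), guided pose pools
#' for every training molecule, candidate probe placement at each
#' polar density, deterministic greedy probe-subset selection (ten
#' pose cliques, weighted then binarized optimization), probe-position
#' refinement, and model selection among the per-density candidates by
#' a three-metric vote (Kendall's tau, mean error, parsimony).  The
#' returned model carries the probes, the training optimal poses and
#' pose pools, the exploration envelope, and the quality-metric
#' distributions used for applicability-domain estimates.
#'
#' @param ligands a `pq_ligandset` (activities attached), or a list of
#'   `pq_molecule` with `activities` supplied separately.
#' @param activities optional named numeric vector of activities (pKi)
#'   overriding those in `ligands`.
#' @param hypothesis optional `pq_hypothesis`; by default built from
#'   the two most active training ligands.
#' @param constraints optional list of [substructure_constraint()].
#' @param config a [pq_config()] list.
#' @return An object of class `pocketqsar`.
#' @seealso [predict.pocketqsar()], [incremental_train()],
#'   [write_pocketmol()]
#' @export
pocket_qsar <- function(ligands, activities = NULL, hypothesis = NULL,
                        constraints = NULL, config = pq_config()) {
  cl <- match.call()
  mols <- .named_mols(ligands)
  if (is.null(activities)) {
    if (!inherits(ligands, "pq_ligandset") || is.null(ligands$activities))
      stop("activities required (attach to the ligand set or pass directly)")
    activities <- setNames(ligands$activities$activity, ligands$activities$id)
  }
  mols <- mols[names(mols) %in% names(activities)]
  if (length(mols) < 2L) stop("need at least 2 ligands with activities")
  act <- activities[names(mols)]
  if (is.null(hypothesis)) {
    top2 <- names(sort(act, decreasing = TRUE))[1:2]
    hypothesis <- build_hypothesis(mols[top2], seed = config$seed)
  }
  pools <- lapply(mols, function(m)
    generate_pose_pool(m, hypothesis, n = config$n_poses,
                       seed = config$seed, constraints = constraints))
  pools <- unname(pools)
  cands_list <- list()
  for (di in seq_along(config$polar_densities)) {
    d <- config$polar_densities[di]
    candidates <- place_candidate_probes(pools, mols, config$scoring,
                                         polar_spacing = d,
                                         steric_spacing = config$steric_spacing)
    sel <- select_probe_subset(pools, candidates, mols, act,
                               weights = config$weights,
                               params = config$scoring,
                               constraints = constraints,
                               sigma_act = config$sigma_act,
                               redundancy = config$redundancy,
                               n_cliques = config$n_cliques,
                               step_schedule = config$step_schedule,
                               max_cycles = config$max_cycles)
    ref <- refine_probes(sel$probes, pools, mols, act,
                         params = config$scoring, constraints = constraints,
                         n_rounds = config$refine_rounds)
    model <- .finalize_model(ref$probes, pools, ref$pose_idx, mols, act,
                             constraints, config, sel, cl)
    model$polar_density <- d
    cands_list[[di]] <- list(model = model, report = model$training_report)
  }
  final <- select_model(cands_list)
  final$n_density_candidates <- length(cands_list)
  final
}

#' Incrementally incorporate additional training ligands
#'
#' New ligands are posed against the existing model frame (guided by
#' the current training optimal poses), new candidate probes are
#' placed from their pools, and probe selection restarts warm from the
#' existing probe set (no pose cliques), followed by refinement over
#' the union training set.
#'
#' @param model a fitted `pocketqsar`.
#' @param extra a `pq_ligandset` (or list of `pq_molecule`) with
#'   activities for the added ligands.
#' @param activities optional named activities for `extra`.
#' @return An updated `pocketqsar` fitted on the union.
#' @export
incremental_train <- function(model, extra, activities = NULL) {
  new_mols <- .named_mols(extra)
  if (is.null(activities) && inherits(extra, "pq_ligandset") &&
      !is.null(extra$activities))
    activities <- setNames(extra$activities$activity, extra$activities$id)
  new_mols <- new_mols[!names(new_mols) %in% names(model$molecules)]
  if (length(new_mols) == 0L) return(model)
  config <- model$config
  act <- c(model$activities, activities[names(new_mols)])
  mols <- c(model$molecules, new_mols)
  guides <- model$training_poses
  gord <- order(-model$activities[names(guides)])
  hyp <- structure(list(poses = unname(guides[gord[seq_len(min(3L,
                     length(guides)))]]), molecules = model$molecules,
                        source = "external"), class = "pq_hypothesis")
  new_pools <- lapply(new_mols, function(m)
    generate_pose_pool(m, hyp, n = config$n_poses, seed = config$seed,
                       constraints = model$constraints))
  pools <- c(model$training_pools, unname(new_pools))
  new_cands <- place_candidate_probes(unname(new_pools), mols,
                                      config$scoring,
                                      polar_spacing =
                                        if (!is.null(model$polar_density))
                                          model$polar_density else
                                          config$polar_densities[1L],
                                      steric_spacing = config$steric_spacing)
  candidates <- c_probes(model$probes, new_cands)
  w0 <- c(rep(1, length(model$probes)), rep(0, length(new_cands)))
  sel <- select_probe_subset(pools, candidates, mols, act,
                             weights = config$weights,
                             params = config$scoring,
                             constraints = model$constraints,
                             sigma_act = config$sigma_act,
                             redundancy = config$redundancy,
                             step_schedule = config$step_schedule,
                             max_cycles = config$max_cycles,
                             warm_start = w0)
  ref <- refine_probes(sel$probes, pools, mols, act,
                       params = config$scoring,
                       constraints = model$constraints,
                       n_rounds = config$refine_rounds)
  out <- .finalize_model(ref$probes, pools, ref$pose_idx, mols, act,
                         model$constraints, config, sel, model$call)
  out$polar_density <- model$polar_density
  out$retained_fraction <- {
    old <- model$probes$position
    new <- sel$probes$position
    if (length(model$probes) == 0) NA_real_ else {
      hits <- 0
      for (i in seq_len(nrow(old))) {
        d <- sqrt(colSums((t(new) - old[i, ])^2))
        if (any(d < 1e-6 & sel$probes$kind == model$probes$kind[i]))
          hits <- hits + 1
      }
      hits / nrow(old)
    }
  }
  out
}
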