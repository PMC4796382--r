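# Fitting new ligands into a pocket model: flexible fit, quality
# metrics with probabilistic normalization, pose families with
# Boltzmann ranking, applicability-domain rules.

#' Survival probability of a metric value under a training distribution
#'
#' The area under the right-hand (high-value) side of the observed
#' training distribution, assumed normal:
#' `p = 1 - (1/2)(1 + erf((S - mu) / (sigma sqrt(2))))`.  Strictly
#' decreasing in S and clamped away from 0 and 1.
#'
#' @param S metric value(s).
#' @param dist list with `mu` and `sigma` (a quality distribution).
#' @return p in (0, 1), vectorized over S.
#' @export
p_metric <- function(S, dist) {
  p <- pnorm(S, mean = dist$mu, sd = dist$sigma, lower.tail = FALSE)
  pmin(1 - 1e-12, pmax(1e-12, p))
}

#' Statistical-potential style energy correction from a probability
#'
#' `w = -RT * ln(1 / p) = RT * ln(p)`, always <= 0; p = 1 gives zero
#' correction and small p (a value far into the native-like tail)
#' gives a large-magnitude correction.
#'
#' @param p probability in (0, 1].
#' @param RT temperature factor in pKi units (default 0.434, i.e.
#'   0.592 kcal/mol at 298 K divided by 1.364 kcal/mol per log unit).
#' @return w <= 0.
#' @export
energy_correction <- function(p, RT = 0.434) {
  if (any(p <= 0)) stop("p must be positive (clamp upstream)")
  -RT * log(1 / p)
}

#' Estimate the three quality-metric distributions of a model
#'
#' Confidence: over all non-self pairs of training molecules, the 3D
#' similarity of their optimal poses.  Novelty: for each training
#' molecule, the similarity of its optimal pose to the pooled field of
#' the other molecules' optimal poses.  Exclusion: each optimal pose's
#' total envelope penalty.  Per molecule, the contributing pose set is
#' expanded to all pool poses within 1.0 A RMSD of the optimal pose or
#' within 2.0 pKi of the optimal score, which stabilizes the moments
#' for small training sets.  Moments are sample mean and standard
#' deviation, with a floor on sigma.
#'
#' @param model a `pocketqsar` object (with training pools retained).
#' @param rmsd_threshold pool-expansion RMSD threshold (A).
#' @param score_threshold pool-expansion score threshold (pKi).
#' @param sigma_floor minimum sigma.
#' @return Named list of distributions `confidence`, `novelty`,
#'   `exclusion`, each with `mu`, `sigma`, `source_count`.
#' @export
estimate_distributions <- function(model, rmsd_threshold = 1.0,
                                   score_threshold = 2.0,
                                   sigma_floor = 0.05) {
  pools <- model$training_pools
  if (length(pools) < 2L) stop("need at least 2 training molecules")
  mols <- model$molecules
  # expanded pose set per molecule
  expanded <- lapply(seq_along(pools), function(m) {
    pl <- pools[[m]]
    opt <- pl$poses[[pl$optimal_index]]
    vals <- model$pose_values[[m]]
    keep <- vapply(seq_along(pl$poses), function(q) {
      pose_rmsd(pl$poses[[q]], opt) <= rmsd_threshold ||
        (vals[pl$optimal_index] - vals[q]) <= score_threshold
    }, logical(1))
    pl$poses[keep]
  })
  optimal <- lapply(pools, function(pl) pl$poses[[pl$optimal_index]])
  efields <- lapply(expanded, function(ps) lapply(ps, .make_field, mols = mols))
  # confidence: similarities over non-self molecule pairs, expanded sets
  conf <- c()
  for (i in seq_len(length(pools) - 1L)) for (j in (i + 1L):length(pools)) {
    for (fa in efields[[i]]) for (fb in efields[[j]])
      conf <- c(conf, .sim_between(fa, fb))
  }
  # novelty: each expanded pose vs the union of the *other* optimal poses
  nov <- c()
  for (i in seq_along(pools)) {
    others <- optimal[-i]
    for (pa in expanded[[i]])
      nov <- c(nov, union_similarity(pa, others, mols))
  }
  # exclusion: total envelope penalty of each expanded pose
  exc <- c()
  for (i in seq_along(pools)) {
    for (pa in expanded[[i]])
      exc <- c(exc, pose_envelope_penalty(pa, model$envelope,
                                          model$config$envelope))
  }
  mk <- function(v) {
    s <- if (length(v) >= 2L) sd(v) else 0
    if (!is.finite(s)) s <- 0
    list(mu = mean(v), sigma = max(sigma_floor, s), source_count = length(v))
  }
  list(confidence = mk(conf), novelty = mk(nov), exclusion = mk(exc))
}

#' Flexibly fit a molecule into a pocket model
#'
#' A pose pool is generated against the model frame (guided by
#' similarity to the training optimal poses), and each pose is locally
#' rigid-body optimized on the full objective: interaction score plus
#' clash plus the exploration-envelope penalty plus any substructure
#' constraint penalties.  Deterministic for a fixed seed.
#'
#' @param mol a `pq_molecule`.
#' @param model a `pocketqsar` object.
#' @param n pool size.
#' @param seed conformer-grid seed.
#' @return List of `pq_pose` with provenance `"fitted"`, each carrying
#'   its total score, sorted by decreasing score.
#' @export
fit_ligand <- function(mol, model, n = 20L, seed = 1L) {
  if (all(mol$feature == "none") || length(mol$elements) == 0L)
    stop("molecule has no scorable atoms")
  guides <- model$training_poses
  ord <- order(-model$activities[names(guides)])
  guides <- guides[ord[seq_len(min(3L, length(guides)))]]
  hyp <- structure(list(poses = unname(guides), molecules = model$molecules,
                        source = "external"), class = "pq_hypothesis")
  pool <- generate_pose_pool(mol, hyp, n = n, seed = seed,
                             constraints = model$constraints)
  total_score <- function(coords) {
    p <- pose(mol, coords, provenance = "fitted")
    sc <- interaction_score(p, model$probes, mol, model$config$scoring)
    sc$score + sc$clash +
      pose_envelope_penalty(p, model$envelope, model$config$envelope) +
      .constraint_total(p, model$constraints, mol)
  }
  # the local optimization is kept deliberately light: training scores
  # are pool maxima without per-pose polishing, so aggressive score
  # maximization here would bias predictions upward relative to the
  # training calibration
  fitted <- lapply(pool$poses, function(p) {
    ref <- .refine_rigid(p$coords, total_score,
                         rot_steps = 0.05, trans_steps = 0.1,
                         max_sweeps = 1)
    out <- pose(mol, ref$coords, provenance = "fitted")
    out$score <- ref$score
    out
  })
  scores <- vapply(fitted, `[[`, numeric(1), "score")
  fitted[order(-scores, seq_along(fitted))]
}

#' Cluster scored poses into families by single-linkage RMSD
#'
#' @param poses list of scored `pq_pose` for one molecule.
#' @param rmsd_cut linkage threshold (A), default 2.0.
#' @return List of `pq_posefamily`, each with `members` (pose indices),
#'   `poses`, `representative` (index of the highest-score member) and
#'   `score` (maximal unadjusted member score).  Deterministic; family
#'   order follows the first member index.
#' @export
make_families <- function(poses, rmsd_cut = 2.0) {
  n <- length(poses)
  stopifnot(n >= 1L)
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0, n - 1L))) for (j in (i + 1L):n) {
    if (pose_rmsd(poses[[i]], poses[[j]]) <= rmsd_cut) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fams <- lapply(sort(unique(roots)), function(r) {
    idx <- which(roots == r)
    scores <- vapply(poses[idx], `[[`, numeric(1), "score")
    rep_i <- idx[which.max(scores)]
    structure(list(members = idx, poses = poses[idx],
                   representative = rep_i, score = max(scores)),
              class = "pq_posefamily")
  })
  fams
}

#' Boltzmann-derived probability ranking of pose families
#'
#' Each pose's ranking value is its unadjusted score plus the
#' magnitudes of the three statistical-potential corrections (more
#' native-like poses, i.e. lower survival probabilities, gain more).
#' A family's probability is the Boltzmann weight of its members'
#' ranking values over all poses; probabilities sum to one.  Reported
#' family scores remain unadjusted; the per-family quality values are
#' the means over member poses.
#'
#' @param families list of `pq_posefamily` from [make_families()].
#' @param qualities data frame with one row per pose (in the original
#'   pose order) and columns `p_conf_rank`, `p_nov_rank`,
#'   `p_excl_rank`, `pConf`, `pNov`, `pExcl`.
#' @param RT Boltzmann temperature in pKi units.
#' @param use list of logical toggles for the three corrections.
#' @return The families, each gaining `probability`, `pConf`, `pNov`,
#'   `pExcl` and `adjusted`, sorted by decreasing probability.
#' @export
rank_families <- function(families, qualities, RT = 0.434,
                          use = list(conf = TRUE, nov = TRUE, excl = TRUE)) {
  adj_of <- function(i) {
    boost <- 0
    if (isTRUE(use$conf))
      boost <- boost - energy_correction(qualities$p_conf_rank[i], RT)
    if (isTRUE(use$nov))
      boost <- boost - energy_correction(qualities$p_nov_rank[i], RT)
    if (isTRUE(use$excl))
      boost <- boost - energy_correction(qualities$p_excl_rank[i], RT)
    boost
  }
  all_adj <- unlist(lapply(families, function(f)
    vapply(f$members, function(i) f$poses[[match(i, f$members)]]$score +
             adj_of(i), numeric(1))))
  shift <- max(all_adj)     # softmax shift invariance
  Z <- sum(exp((all_adj - shift) / RT))
  out <- lapply(families, function(f) {
    adj <- vapply(seq_along(f$members), function(q)
      f$poses[[q]]$score + adj_of(f$members[q]), numeric(1))
    f$adjusted <- adj
    f$probability <- sum(exp((adj - shift) / RT)) / Z
    f$pConf <- mean(qualities$pConf[f$members])
    f$pNov <- mean(qualities$pNov[f$members])
    f$pExcl <- mean(qualities$pExcl[f$members])
    f
  })
  out[order(-vapply(out, `[[`, numeric(1), "probability"),
            vapply(out, function(f) f$members[1L], integer(1)))]
}

# quality metrics of a list of fitted poses against a model
.pose_qualities <- function(poses, mol, model) {
  mols <- c(model$molecules, setNames(list(mol), mol$id))
  dist <- model$distributions
  tfields <- lapply(model$training_poses, .make_field, mols = mols)
  pfields <- lapply(poses, .make_field, mols = mols)
  S_conf <- vapply(pfields, function(pf)
    max(vapply(tfields, function(tf) .sim_between(pf, tf), numeric(1))),
    numeric(1))
  S_nov <- vapply(poses, function(p)
    union_similarity(p, unname(model$training_poses), mols), numeric(1))
  S_excl <- vapply(poses, function(p)
    pose_envelope_penalty(p, model$envelope, model$config$envelope),
    numeric(1))
  # survival orientation: high p = discordant with training.  For the
  # exclusion metric "worse" is more negative (deeper penetration), so
  # the survival form already maps worse-than-training to high p.
  p_conf_rank <- p_metric(S_conf, dist$confidence)
  p_nov_rank <- p_metric(S_nov, dist$novelty)
  p_excl_rank <- p_metric(S_excl, dist$exclusion)
  data.frame(
    S_conf = S_conf, S_nov = S_nov, S_excl = S_excl,
    p_conf_rank = p_conf_rank, p_nov_rank = p_nov_rank,
    p_excl_rank = p_excl_rank,
    pConf = 1 - p_conf_rank,   # high = confidently similar to training
    pNov = p_nov_rank,         # high = novel
    pExcl = p_excl_rank        # high = deep excluded-volume penetration
  )
}

#' Predict activity and poses for new molecules
#'
#' For each molecule: flexible fit into the pocket, per-pose quality
#' metrics, single-linkage pose families, Boltzmann re-ranking with
#' the statistical-potential corrections.  The reported activity is
#' the top-ranked family's maximal unadjusted score; pConf, pNov and
#' pExcl are that family's member means.
#'
#' @param object a `pocketqsar` model.
#' @param newdata a `pq_ligandset`, a list of `pq_molecule`, or a
#'   single `pq_molecule`.
#' @param n pose-pool size per molecule.
#' @param seed fitting seed.
#' @param rmsd_cut family linkage threshold (A).
#' @param RT Boltzmann temperature (pKi units).
#' @param in_model_rule applicability-domain rule, see [in_model()].
#' @param winner_cut predicted-activity threshold for the winner flag.
#' @param ... unused.
#' @return Object of class `pq_prediction`: a data frame (`$table`)
#'   with one row per molecule (id, predicted_activity, pConf, pNov,
#'   pExcl, in_model, winner) plus per-molecule family lists
#'   (`$families`).
#' @export
predict.pocketqsar <- function(object, newdata, n = 20L, seed = 1L,
                               rmsd_cut = 2.0, RT = 0.434,
                               in_model_rule = c("default", "strict", "raw"),
                               winner_cut = 7.5, ...) {
  in_model_rule <- match.arg(in_model_rule)
  mols <- if (inherits(newdata, "pq_ligandset")) newdata$molecules
          else if (inherits(newdata, "pq_molecule")) list(newdata)
          else newdata
  rows <- list(); fams_all <- list()
  for (mol in mols) {
    fitted <- fit_ligand(mol, object, n = n, seed = seed)
    qual <- .pose_qualities(fitted, mol, object)
    fams <- make_families(fitted, rmsd_cut)
    fams <- rank_families(fams, qual, RT = RT)
    top <- fams[[1L]]
    raw_sim <- max(qual$S_conf[top$members])
    raw_excl <- max(qual$S_excl[top$members])
    im <- in_model(list(pConf = top$pConf, pNov = top$pNov,
                        pExcl = top$pExcl, raw_similarity = raw_sim,
                        raw_exclusion = raw_excl), rule = in_model_rule)
    rows[[mol$id]] <- data.frame(
      id = mol$id, predicted_activity = top$score,
      pConf = top$pConf, pNov = top$pNov, pExcl = top$pExcl,
      raw_similarity = raw_sim, raw_exclusion = raw_excl,
      probability = top$probability, n_families = length(fams),
      in_model = im, winner = im && top$score >= winner_cut,
      stringsAsFactors = FALSE)
    fams_all[[mol$id]] <- fams
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 families = fams_all, rule = in_model_rule,
                 winner_cut = winner_cut),
            class = "pq_prediction")
}

#' @export
print.pq_prediction <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}

#' Applicability-domain decision for a prediction
#'
#' Default rule: pNov < 0.85 (low novelty).  Strict rule adds
#' pConf > 0.35 (high confidence) and pExcl < 0.95 (non-extreme
#' excluded-volume penetration).  Raw fallback (for models whose
#' training set is so narrow that the normalized novelty rule rejects
#' everything): raw similarity > 0.70 and raw exclusion penalty
#' > -0.40.
#'
#' @param q list or one-row data frame with `pNov`, `pConf`, `pExcl`,
#'   `raw_similarity`, `raw_exclusion`.
#' @param rule `"default"`, `"strict"` or `"raw"`.
#' @param thresholds named list overriding the default cutoffs.
#' @return Logical.
#' @export
in_model <- function(q, rule = c("default", "strict", "raw"),
                     thresholds = list()) {
  rule <- match.arg(rule)
  th <- modifyList(list(pNov = 0.85, pConf = 0.35, pExcl = 0.95,
                        raw_similarity = 0.70, raw_exclusion = -0.40),
                   thresholds)
  switch(rule,
         default = isTRUE(q$pNov < th$pNov),
         strict = isTRUE(q$pNov < th$pNov) && isTRUE(q$pConf > th$pConf) &&
           isTRUE(q$pExcl < th$pExcl),
         raw = isTRUE(q$raw_similarity > th$raw_similarity) &&
           isTRUE(q$raw_exclusion > th$raw_exclusion))
}
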