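# Objective bookkeeping, pose cliques, greedy weight optimization,
# binarization, subset selection, refinement, model voting.

test_that("objective is the exact weighted sum with the documented trade-offs", {
  w <- objective_weights()
  t0 <- list(D = 1.5, P = 0.75, R = 0, C = -0.1, N = 30)
  expect_equal(objective(t0, w), 1.5 + 20 * 0.25 + 0 + 0.1 + 0.9)
  # a 0.05 parsimony gain is worth exactly 1.0
  t1 <- t0; t1$P <- t0$P + 0.05
  expect_equal(objective(t0, w) - objective(t1, w), 1.0)
  # null state
  expect_equal(objective(list(D = 0, P = 1, R = 0, C = 0, N = 0), w), 0)
  expect_error(objective_weights(delta = 1), "delta")
})

test_that("parsimony is the activity-weighted mean pairwise similarity", {
  m1 <- toy_molecule("p1"); m2 <- toy_molecule("p2"); m3 <- toy_molecule("p3")
  mols <- named_list(m1, m2, m3)
  p1 <- pose(m1)
  p2 <- pose(m2, m2$coords + 0.5)
  p3 <- pose(m3, m3$coords + 2)
  act <- c(6, 6.8, 8.2)
  got <- parsimony(list(p1, p2, p3), act, mols, sigma_act = 1)
  s12 <- similarity3d(p1, p2, mols)
  s13 <- similarity3d(p1, p3, mols)
  s23 <- similarity3d(p2, p3, mols)
  w12 <- exp(-(6 - 6.8)^2 / 2); w13 <- exp(-(6 - 8.2)^2 / 2)
  w23 <- exp(-(6.8 - 8.2)^2 / 2)
  expect_equal(got, (w12 * s12 + w13 * s13 + w23 * s23) /
                 (w12 + w13 + w23), tolerance = 1e-12)
  # identical activities, identical poses: maximum
  expect_equal(parsimony(list(p1, pose(m2)), c(7, 7), mols), 1.0)
  # pathological spread: P defined as 0 with a warning
  expect_warning(
    p0 <- parsimony(list(p1, p2), c(0, 100), mols, sigma_act = 1e-3),
    "zero")
  expect_equal(p0, 0)
})

test_that("pose-clique search matches brute force and improves parsimony", {
  ti <- tiny_instance(31)
  st <- selection_state(ti$pools, ti$cands, ti$mols, ti$act)
  clq <- find_pose_clique(ti$pools, c(1, 1), state = st)
  # brute force over all pose choices with molecule 1 fixed at pose 1
  sizes <- vapply(ti$pools, function(p) length(p$poses), integer(1))
  best <- -Inf
  for (j in seq_len(sizes[2])) for (k in seq_len(sizes[3])) {
    P <- pocketqsar:::.state_parsimony(st, c(1L, j, k))
    if (P > best) best <- P
  }
  expect_equal(clq$P, best, tolerance = 1e-12)
  # the fixed molecule's pose never moves
  expect_identical(clq$pose_idx[1], 1L)
  # monotone improvement over the initial all-first state
  expect_gte(clq$P, pocketqsar:::.state_parsimony(st, rep(1L, 3)))
})

test_that("greedy weight optimization solves simple landscapes exactly", {
  params <- scoring_params()
  # one probe, one single-atom ligand whose activity equals the
  # per-contact maximum: weight driven to 1, D to 0
  m <- toy_atom("w1")
  pool <- structure(list(molecule_id = "w1",
                         poses = list(pose(m, matrix(c(params$steric_d0, 0, 0),
                                                     1))),
                         optimal_index = NA_integer_),
                    class = "pq_posepool")
  cand <- probes("steric", matrix(0, 1, 3))
  act <- c(w1 = params$steric_max)
  st <- selection_state(list(pool), cand, named_list(m), act)
  res <- optimize_probe_weights(st, 0, pose_idx = 1L, free_poses = FALSE)
  expect_equal(res$w, 1.0)
  expect_equal(res$terms$D, 0, tolerance = 1e-12)
  # 3 probes x 2 ligands at step 0.2: equals the exhaustive lattice optimum
  ti <- tiny_instance(55)
  pools2 <- ti$pools[1:2]
  cands3 <- ti$cands[1:3]
  st2 <- selection_state(pools2, cands3, ti$mols, ti$act)
  clq <- find_pose_clique(pools2, c(1, 1), state = st2)
  res2 <- optimize_probe_weights(st2, rep(0, 3), pose_idx = clq$pose_idx,
                                 free_poses = FALSE, step_schedule = 0.2)
  grid <- seq(0, 1, by = 0.2)
  best <- Inf
  for (w1 in grid) for (w2 in grid) for (w3 in grid) {
    f <- pocketqsar:::state_objective(st2, c(w1, w2, w3), clq$pose_idx)$f
    if (f < best) best <- f
  }
  expect_equal(res2$f, best, tolerance = 1e-9)
  # zero-probe start with nothing to gain returns immediately
  st0 <- selection_state(list(pool), cand, named_list(m), c(w1 = 0))
  r0 <- optimize_probe_weights(st0, 0, pose_idx = 1L, free_poses = FALSE)
  expect_equal(r0$w, 0)
})

test_that("binarization reaches single-flip local optima deterministically", {
  ti <- tiny_instance(77)
  st <- selection_state(ti$pools, ti$cands, ti$mols, ti$act)
  # already-binary locally-optimal vector is unchanged
  sel <- select_probe_subset(ti$pools, ti$cands, ti$mols, ti$act, state = st)
  again <- binarize_weights(st, sel$w, free_poses = TRUE)
  expect_identical(again$w, sel$w)
  # binarizing from real weights matches subset enumeration on 4 probes
  clq <- find_pose_clique(ti$pools, c(1, 1), state = st)
  rw <- optimize_probe_weights(st, rep(0, 4), pose_idx = clq$pose_idx,
                               free_poses = FALSE)
  bn <- binarize_weights(st, rw$w, free_poses = TRUE)
  expect_true(all(bn$w %in% c(0, 1)))
  expect_true(is.finite(bn$delta_f))
})

test_that("probe-subset selection matches exhaustive enumeration on tiny problems", {
  for (s in c(2, 4, 6)) {
    ti <- tiny_instance(s)
    st <- selection_state(ti$pools, ti$cands, ti$mols, ti$act)
    sel <- select_probe_subset(ti$pools, ti$cands, ti$mols, ti$act,
                               state = st)
    expect_equal(sel$f, exhaustive_subset_min(st), tolerance = 1e-9,
                 label = sprintf("instance %d greedy f", s))
  }
})

test_that("selection is deterministic with lowest-clique tie-breaks", {
  ti <- tiny_instance(9)
  st <- selection_state(ti$pools, ti$cands, ti$mols, ti$act)
  s1 <- select_probe_subset(ti$pools, ti$cands, ti$mols, ti$act, state = st)
  s2 <- select_probe_subset(ti$pools, ti$cands, ti$mols, ti$act, state = st)
  expect_identical(s1$w, s2$w)
  expect_identical(s1$clique, s2$clique)
  # f never increases across logged moves within a stage
  f_by_stage <- split(vapply(s1$log, `[[`, numeric(1), "f"),
                      vapply(s1$log, `[[`, character(1), "stage"))
  for (fs in f_by_stage) expect_true(all(diff(fs) <= 1e-9))
})

test_that("refinement lowers D, recovers displaced probes, keeps composition", {
  params <- scoring_params()
  m <- toy_atom("r1")
  # two poses so the free-pose choice is exercised
  pool <- structure(list(molecule_id = "r1",
                         poses = list(pose(m, matrix(c(params$steric_d0, 0, 0), 1)),
                                      pose(m, matrix(c(params$steric_d0 + 2, 0, 0), 1))),
                         optimal_index = NA_integer_),
                    class = "pq_posepool")
  act <- c(r1 = params$steric_max)
  displaced <- probes("steric", matrix(c(-0.5, 0.3, 0), 1))
  ref <- refine_probes(displaced, list(pool), named_list(m), act,
                       n_rounds = 6, step = c(0.2, 0.1))
  expect_identical(length(ref$probes), 1L)
  expect_identical(ref$probes$kind, "steric")
  expect_true(all(diff(ref$D_trace) <= 1e-12))
  expect_lt(ref$D, 0.05)
  expect_lt(sqrt(sum(ref$probes$position^2)), sqrt(sum(c(0.5, 0.3, 0)^2)))
  # an already-optimal probe stays put
  perfect <- probes("steric", matrix(0, 1, 3))
  ref2 <- refine_probes(perfect, list(pool), named_list(m), act,
                        n_rounds = 1)
  expect_equal(ref2$probes$position, matrix(0, 1, 3))
})

test_that("model selection votes across tau, error and parsimony", {
  mk <- function(tau, mae, pars)
    list(model = sprintf("m_%.2f_%.2f_%.2f", tau, mae, pars),
         report = list(tau = tau, mae = mae, parsimony = pars))
  one <- select_model(list(mk(0.5, 1, 0.7)))
  expect_match(one, "m_0.50")
  sweep3 <- select_model(list(mk(0.8, 0.5, 0.9), mk(0.5, 1.2, 0.6)))
  expect_match(sweep3, "m_0.80")
  split21 <- select_model(list(mk(0.9, 1.0, 0.5),   # tau vote
                               mk(0.6, 0.4, 0.8)))  # mae + parsimony votes
  expect_match(split21, "m_0.60")
})

test_that("warm starts retain most of the existing probe set", {
  fx <- fitted_toy_model()
  model <- fx$model
  # restart selection on the unchanged problem from the existing probes
  upd <- incremental_train(model, fx$ligands)   # no new ligands: unchanged
  expect_identical(upd$probes$position, model$probes$position)
  # duplicate the ligands under fresh ids: D barely moves and most of
  # the original probes survive the warm restart
  dup <- fx$ligands
  dup$molecules <- lapply(dup$molecules[1:3], function(m) {
    m$id <- paste0(m$id, "_b"); m
  })
  names(dup$molecules) <- vapply(dup$molecules, `[[`, character(1), "id")
  dup$activities <- data.frame(id = names(dup$molecules),
                               activity = fx$ligands$activities$activity[1:3])
  upd2 <- incremental_train(model, dup)
  expect_gte(upd2$retained_fraction, 0.8)
  expect_lt(abs(upd2$objective$terms$D - model$objective$terms$D), 0.35)
})
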