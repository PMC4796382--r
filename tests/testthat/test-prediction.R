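# Quality metrics, probabilistic corrections, pose families,
# Boltzmann ranking, applicability domain.

test_that("the survival probability transform matches the normal tail", {
  dist <- list(mu = 0.6, sigma = 0.1)
  expect_equal(p_metric(0.6, dist), 0.5)
  expect_equal(p_metric(0.7, dist), 0.1587, tolerance = 1e-3)
  S <- seq(0, 1.2, by = 0.01)
  expect_true(all(diff(p_metric(S, dist)) < 0))
  expect_gte(p_metric(1e6, dist), 1e-12)
  expect_lte(p_metric(-1e6, dist), 1 - 1e-12)
})

test_that("energy corrections follow w = RT ln p", {
  expect_equal(energy_correction(1), 0)
  expect_equal(energy_correction(0.5, RT = 0.434), -0.301, tolerance = 1e-3)
  expect_error(energy_correction(0), "positive")
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(energy_correction(p)) > 0))
  expect_true(all(energy_correction(p) <= 0))
})

test_that("quality distributions use expanded pose sets and sample moments", {
  fx <- fitted_toy_model()
  model <- fx$model
  d <- model$distributions
  for (nm in c("confidence", "novelty", "exclusion")) {
    expect_gt(d[[nm]]$sigma, 0)
    expect_gte(d[[nm]]$source_count, 1L)
  }
  expect_lte(d$confidence$mu, 1); expect_gte(d$confidence$mu, 0)
  # degenerate case: two identical ligands in identical poses
  m1 <- toy_molecule("d1"); m2 <- toy_molecule("d2")
  mini <- model
  mini$molecules <- named_list(m1, m2)
  pl <- function(m) structure(list(molecule_id = m$id,
                                   poses = list(pose(m)),
                                   optimal_index = 1L),
                              class = "pq_posepool")
  mini$training_pools <- list(pl(m1), pl(m2))
  mini$training_poses <- setNames(list(pose(m1), pose(m2)),
                                  c("d1", "d2"))
  mini$pose_values <- list(5, 5)
  mini$envelope <- build_envelope(list(pose(m1)), named_list(m1, m2))
  dd <- estimate_distributions(mini)
  expect_equal(dd$confidence$mu, 1.0)
  expect_equal(dd$confidence$sigma, 0.05)  # the floor
  mini1 <- mini
  mini1$training_pools <- mini1$training_pools[1]
  expect_error(estimate_distributions(mini1), "at least 2")
})

test_that("the distribution expansion rule keys on RMSD or score gap", {
  m <- toy_molecule("ex1"); m2 <- toy_molecule("ex2")
  mols <- named_list(m, m2)
  base <- pose(m)
  # uniform translations give exact RMSD values
  near <- pose(m, m$coords + 0.9 / sqrt(3))        # RMSD = 0.9
  far <- pose(m, m$coords + 1.1 / sqrt(3))         # RMSD = 1.1
  pool <- structure(list(molecule_id = "ex1",
                         poses = list(base, near, far),
                         optimal_index = 1L), class = "pq_posepool")
  pool2 <- structure(list(molecule_id = "ex2", poses = list(pose(m2)),
                          optimal_index = 1L), class = "pq_posepool")
  fx <- fitted_toy_model()
  mini <- fx$model
  mini$molecules <- mols
  mini$training_pools <- list(pool, pool2)
  mini$training_poses <- setNames(list(base, pose(m2)), c("ex1", "ex2"))
  # scores: optimal 8, near-in-rmsd 3 (gap 5: still in via RMSD),
  # far-in-rmsd 5.5 (gap 2.5: excluded on both rules)
  mini$pose_values <- list(c(8, 3, 5.5), 6)
  mini$envelope <- build_envelope(list(base, pose(m2)), mols)
  dd <- estimate_distributions(mini)
  # confidence pairs: expanded set of ex1 (2 poses) x ex2 (1 pose)
  expect_equal(dd$confidence$source_count, 2L)
})

test_that("pose families reproduce single-linkage clustering", {
  m <- toy_molecule("fam")
  set.seed(12)
  mkpose <- function(shift) {
    p <- pose(m, m$coords + matrix(shift, 5, 3, byrow = TRUE))
    p$score <- rnorm(1, 6, 1)
    p
  }
  poses <- c(lapply(1:4, function(i) mkpose(c(0.3 * i, 0, 0))),
             lapply(1:4, function(i) mkpose(c(20 + 0.3 * i, 0, 0))))
  fams <- make_families(poses, rmsd_cut = 2.0)
  # independent oracle: hclust single linkage on the RMSD matrix
  n <- length(poses)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- pose_rmsd(poses[[i]], poses[[j]])
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "single"),
                      h = 2.0)
  expect_equal(length(fams), length(unique(cl)))
  got <- integer(n)
  for (fi in seq_along(fams)) got[fams[[fi]]$members] <- fi
  expect_true(all(tapply(got, cl, function(v) length(unique(v))) == 1))
  # family score is the max member score
  for (f in fams)
    expect_equal(f$score, max(vapply(f$poses, `[[`, numeric(1), "score")))
  # all poses within the cut collapse to one family
  one <- make_families(poses[1:4], rmsd_cut = 2.0)
  expect_length(one, 1L)
})

test_that("Boltzmann ranking normalizes, is shift invariant, flattens with RT", {
  m <- toy_molecule("rk")
  mk <- function(score, shift) {
    p <- pose(m, m$coords + matrix(c(shift, 0, 0), 5, 3, byrow = TRUE))
    p$score <- score
    p
  }
  poses <- list(mk(7.0, 0), mk(6.5, 0.4), mk(6.8, 30))
  qual <- data.frame(p_conf_rank = c(0.5, 0.5, 0.5),
                     p_nov_rank = c(0.5, 0.5, 0.5),
                     p_excl_rank = c(0.5, 0.5, 0.5),
                     pConf = 0.5, pNov = 0.5, pExcl = 0.5)
  fams <- make_families(poses, rmsd_cut = 2.0)
  rk <- rank_families(fams, qual, RT = 0.434)
  probs <- vapply(rk, `[[`, numeric(1), "probability")
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  # single family normalizes to 1
  rk1 <- rank_families(make_families(poses[1:2], 2.0), qual[1:2, ])
  expect_equal(rk1[[1]]$probability, 1, tolerance = 1e-12)
  # two equal one-pose families split 50/50
  qual2 <- qual
  poses2 <- list(mk(6.0, 0), mk(6.0, 30))
  rk2 <- rank_families(make_families(poses2, 2.0), qual2)
  expect_equal(vapply(rk2, `[[`, numeric(1), "probability"), c(0.5, 0.5),
               tolerance = 1e-12)
  # raising RT flattens toward uniform
  spread <- function(RT) {
    r <- rank_families(fams, qual, RT = RT)
    diff(range(vapply(r, `[[`, numeric(1), "probability")))
  }
  expect_gt(spread(0.2), spread(0.434))
  expect_gt(spread(0.434), spread(2.0))
})

test_that("an excursion-heavy top pose loses the family ranking", {
  m <- toy_molecule("thr")
  mk <- function(score, shift, excl) {
    p <- pose(m, m$coords + matrix(c(shift, 0, 0), 5, 3, byrow = TRUE))
    p$score <- score
    p
  }
  # pose 1: best raw score but protrudes ~1.5 A (exclusion ~ -1.99);
  # poses 2-3: slightly lower scores, fully contained
  poses <- list(mk(7.3, 30), mk(7.2, 0), mk(7.15, 0.3))
  S_excl <- c(envelope_penalty(1.5), 0, 0)
  dist_excl <- list(mu = -0.2, sigma = 0.3)
  p_excl_rank <- p_metric(S_excl, dist_excl)
  qual <- data.frame(p_conf_rank = 0.5, p_nov_rank = 0.5,
                     p_excl_rank = p_excl_rank,
                     pConf = 0.5, pNov = 0.5, pExcl = p_excl_rank)
  fams <- make_families(poses, rmsd_cut = 2.0)
  expect_length(fams, 2L)
  rk <- rank_families(fams, qual, RT = 0.434)
  # the top-ranked family is the contained one, not the top-scoring pose
  expect_false(1L %in% rk[[1]]$members)
  expect_equal(rk[[1]]$score, 7.2)
  # and its reported score is unadjusted (lower than the excluded pose's)
  expect_lt(rk[[1]]$score, 7.3)
})

test_that("fitted poses carry exact score accounting and predictions are stable", {
  fx <- fitted_toy_model()
  model <- fx$model
  mol <- fx$ligands$molecules[[3]]
  fitted <- fit_ligand(mol, model, n = 4, seed = 5)
  expect_length(fit_ligand(mol, model, n = 1, seed = 5), 1L)
  for (p in fitted) {
    sc <- interaction_score(p, model$probes, mol, model$config$scoring)
    recomputed <- sc$score + sc$clash +
      pocketqsar:::pose_envelope_penalty(p, model$envelope,
                                         model$config$envelope)
    expect_equal(p$score, recomputed, tolerance = 1e-9)
  }
  pr1 <- predict(model, mol, n = 4, seed = 5)
  pr2 <- predict(model, mol, n = 4, seed = 5)
  expect_identical(pr1$table, pr2$table)
  expect_equal(pr1$table$predicted_activity,
               pr1$families[[mol$id]][[1]]$score)
})

test_that("training ligands re-fit close to their own activities", {
  fx <- fitted_toy_model()
  model <- fx$model
  ids <- names(model$training_scores)[c(2, 6, 9)]
  pr <- predict(model, fx$ligands$molecules[ids],
                n = model$config$n_poses, seed = 1)
  err <- abs(model$activities[pr$table$id] - pr$table$predicted_activity)
  expect_true(all(err <= 1.5))
  expect_true(mean(err) <= 1.0)
})

test_that("applicability-domain rules apply the documented thresholds", {
  q_in <- list(pNov = 0.5, pConf = 0.6, pExcl = 0.4,
               raw_similarity = 0.8, raw_exclusion = -0.1)
  expect_true(in_model(q_in, "default"))
  expect_true(in_model(q_in, "strict"))
  q_nov <- list(pNov = 0.9, pConf = 0.6, pExcl = 0.4,
                raw_similarity = 0.75, raw_exclusion = -0.2)
  expect_false(in_model(q_nov, "default"))
  expect_true(in_model(q_nov, "raw"))        # the raw-value fallback
  q_conf <- list(pNov = 0.5, pConf = 0.2, pExcl = 0.4,
                 raw_similarity = 0.5, raw_exclusion = -0.6)
  expect_true(in_model(q_conf, "default"))
  expect_false(in_model(q_conf, "strict"))
  expect_false(in_model(q_conf, "raw"))
})
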