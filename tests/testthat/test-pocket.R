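# Probe placement, interaction scoring, clash, redundancy, envelope.

test_that("envelope penalty matches its printed checkpoints and shape", {
  expect_lt(abs(envelope_penalty(0.2) - (-0.05)), 1e-3)
  expect_equal(envelope_penalty(0.75), -1.0, tolerance = 1e-9)
  expect_lt(abs(envelope_penalty(1.5) - (-1.9866)), 1e-3)
  d <- seq(0, 5, by = 0.05)
  e <- envelope_penalty(d)
  expect_true(all(diff(e) < 0))          # strictly decreasing
  expect_true(all(e > -2 & e < 0))       # bounded in (eta, 0)
  # closed form at random excursions
  set.seed(8)
  dr <- runif(20, 0, 3)
  expect_equal(envelope_penalty(dr),
               -2 * (1 - 1 / (1 + exp((dr - 0.75) / 0.15))),
               tolerance = 1e-12)
})

test_that("envelope construction and excursions follow sphere geometry", {
  m <- toy_atom()
  mols <- named_list(m)
  env <- build_envelope(list(pose(m)), mols)
  expect_equal(nrow(env$centers), 1L)
  expect_equal(env$radii, m$radius)
  # training atom has zero excursion from its own envelope
  expect_equal(pose_excursions(pose(m), env), 0)
  # point 0.5 beyond the sphere surface
  far <- matrix(c(m$radius + 0.5, 0, 0), 1)
  expect_equal(pose_excursions(far, env), 0.5, tolerance = 1e-9)
  # total penalty is additive over atoms: an interior atom contributes
  # only the (near-zero) zero-excursion value of the sigmoid
  mol2 <- molecule("two", c("C", "C"),
                   rbind(c(m$radius + 0.5, 0, 0), c(0, 0, 0)),
                   rbind(c(1, 2, 1)))
  p2 <- pose(mol2)
  expect_equal(pocketqsar:::pose_envelope_penalty(p2, env),
               envelope_penalty(0.5) + envelope_penalty(0), tolerance = 1e-9)
  expect_gt(envelope_penalty(0), -0.02)
})

test_that("interaction scoring is linear in weights with capped contacts", {
  params <- scoring_params()
  prb <- probes(c("steric", "donor"),
                rbind(c(0, 0, 0), c(10, 10, 10)),
                rbind(c(NA, NA, NA), c(0, 0, -1)))
  # single steric atom at the optimum distance: exactly the per-contact max
  m <- toy_atom()
  p <- pose(m, matrix(c(params$steric_d0, 0, 0), 1))
  sc <- interaction_score(p, prb, m, params)
  expect_equal(sc$score, params$steric_max, tolerance = 1e-9)
  expect_equal(sc$clash, 0)
  # no probes within cutoff
  pfar <- pose(m, matrix(c(50, 0, 0), 1))
  expect_equal(unlist(interaction_score(pfar, prb, m, params)),
               c(score = 0, clash = 0))
  # doubling the weights doubles score and clash
  prb_half <- probes(prb$kind, prb$position, prb$direction,
                     weight = c(0.5, 0.5))
  prb_full <- probes(prb$kind, prb$position, prb$direction,
                     weight = c(1, 1))
  pc <- pose(m, matrix(c(2.0, 0, 0), 1))  # inside the steric core: clash
  h <- interaction_score(pc, prb_half, m, params)
  f <- interaction_score(pc, prb_full, m, params)
  expect_equal(f$score, 2 * h$score)
  expect_equal(f$clash, 2 * h$clash)
  expect_lt(f$clash, 0)
})

test_that("polar contacts respect the interaction cone", {
  params <- scoring_params()
  prb <- probes("donor", matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1))
  o <- molecule("o1", "O", matrix(c(0, 0, params$polar_d0), 1))
  aligned <- interaction_score(pose(o), prb, o, params)
  expect_equal(aligned$score, params$polar_max, tolerance = 1e-9)
  # outside the 60-degree cone: no polar term
  side <- molecule("o2", "O",
                   matrix(c(params$polar_d0, 0, -0.5), 1))
  expect_equal(interaction_score(pose(side), prb, side, params)$score, 0)
})

test_that("ligand score equals the brute-force pool maximum", {
  set.seed(21)
  m <- toy_molecule("ls")
  prb <- probes(c("steric", "steric", "donor"),
                matrix(rnorm(9, sd = 3), 3),
                rbind(c(NA, NA, NA), c(NA, NA, NA), c(0, 0, 1)))
  poses <- lapply(1:5, function(i)
    pose(m, m$coords + matrix(rnorm(15, sd = 1.5), 5)))
  pool <- structure(list(molecule_id = "ls", poses = poses,
                         optimal_index = NA_integer_),
                    class = "pq_posepool")
  got <- ligand_score(pool, prb, m)
  brute <- vapply(poses, function(p) {
    sc <- interaction_score(p, prb, m)
    sc$score + sc$clash
  }, numeric(1))
  expect_equal(got$best, max(brute))
  expect_equal(got$optimal_index, which.max(brute))
  # permuting pose order preserves the best value
  perm <- c(3, 1, 5, 2, 4)
  pool2 <- structure(list(molecule_id = "ls", poses = poses[perm],
                          optimal_index = NA_integer_),
                     class = "pq_posepool")
  expect_equal(ligand_score(pool2, prb, m)$best, got$best)
  # singleton pool
  pool1 <- structure(list(molecule_id = "ls", poses = poses[1],
                          optimal_index = NA_integer_),
                     class = "pq_posepool")
  expect_equal(ligand_score(pool1, prb, m)$optimal_index, 1L)
})

test_that("probe redundancy accumulates like-kind shortfalls only", {
  thr <- c(steric = 2.0, donor = 1.5, acceptor = 1.5)
  apart <- probes(c("steric", "steric"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(probe_redundancy(apart, thr), 0)
  close_same <- probes(c("steric", "steric"),
                       rbind(c(0, 0, 0), c(1.95, 0, 0)))
  expect_equal(probe_redundancy(close_same, thr), 0.05, tolerance = 1e-9)
  close_mixed <- probes(c("steric", "donor"),
                        rbind(c(0, 0, 0), c(0.5, 0, 0)),
                        rbind(c(NA, NA, NA), c(0, 0, 1)))
  expect_equal(probe_redundancy(close_mixed, thr), 0)
})

test_that("candidate placement follows the documented geometric rules", {
  params <- scoring_params()
  m <- toy_atom("shell")
  pool <- structure(list(molecule_id = "shell", poses = list(pose(m)),
                         optimal_index = NA_integer_),
                    class = "pq_posepool")
  cands <- place_candidate_probes(list(pool), named_list(m), params)
  expect_true(all(cands$kind == "steric"))
  d <- sqrt(rowSums(cands$position^2))
  expect_true(all(d >= params$steric_d0 - 0.5 - 1e-9 &
                    d <= params$steric_d0 + 0.5 + 1e-9))
  # carbonyl oxygen generates a donor candidate along the C=O axis
  co <- toy_molecule("co")
  poolc <- structure(list(molecule_id = "co", poses = list(pose(co)),
                          optimal_index = NA_integer_),
                     class = "pq_posepool")
  cc <- place_candidate_probes(list(poolc), named_list(co), params)
  don <- which(cc$kind == "donor")
  expect_gte(length(don), 1L)
  axis <- (co$coords[2, ] - co$coords[1, ])
  axis <- axis / sqrt(sum(axis^2))
  angs <- vapply(don, function(k) {
    v <- cc$position[k, ] - co$coords[2, ]
    acos(sum(v * axis) / sqrt(sum(v^2))) * 180 / pi
  }, numeric(1))
  expect_lt(min(angs), 20)
  expect_error(place_candidate_probes(list(), named_list(co)), "empty")
})

test_that("interaction score is invariant under a common rigid transform", {
  m <- toy_molecule("inv")
  prb <- probes(c("steric", "acceptor"),
                rbind(c(3, 1, 0), c(-2, 2, 1)),
                rbind(c(NA, NA, NA), c(0.3, -1, 0)))
  p <- pose(m)
  s0 <- interaction_score(p, prb, m)
  R <- pocketqsar:::.rotation_about(c(0.2, 1, -0.4), 0.9)
  tr <- c(1, -4, 2)
  prb2 <- probes(prb$kind, sweep(prb$position %*% t(R), 2, tr, "+"),
                 prb$direction %*% t(R))
  p2 <- pose(m, sweep(p$coords %*% t(R), 2, tr, "+"))
  s1 <- interaction_score(p2, prb2, m)
  expect_equal(s0$score, s1$score, tolerance = 1e-9)
  expect_equal(s0$clash, s1$clash, tolerance = 1e-9)
})

test_that("pocketmol JSON serialization round-trips scoring exactly", {
  fx <- fitted_toy_model()
  model <- fx$model
  f <- tempfile(fileext = ".json")
  write_pocketmol(model, f)
  m2 <- read_pocketmol(f)
  expect_identical(m2$probes$kind, model$probes$kind)
  expect_equal(m2$probes$position, model$probes$position)
  expect_equal(m2$envelope$centers, model$envelope$centers)
  expect_equal(m2$distributions, model$distributions)
  mol <- fx$ligands$molecules[[4]]
  p1 <- predict(model, mol, n = 4, seed = 3)
  p2 <- predict(m2, mol, n = 4, seed = 3)
  expect_equal(p1$table$predicted_activity, p2$table$predicted_activity,
               tolerance = 1e-12)
  # envelope PDB export is well-formed
  pdb <- tempfile(fileext = ".pdb")
  write_envelope_pdb(model$envelope, pdb)
  lines <- readLines(pdb)
  expect_equal(sum(grepl("^HETATM", lines)), length(model$envelope$radii))
})
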