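# Shared toy fixtures, built in code.

# a 4-atom molecule with one carbonyl (C=O), one N-H donor and a charge
toy_molecule <- function(id = "toy1", charge_on = NULL) {
  charges <- numeric(5)
  if (!is.null(charge_on)) charges[charge_on] <- 1
  molecule(id,
           elements = c("C", "O", "N", "H", "C"),
           coords = rbind(c(0, 0, 0), c(1.23, 0, 0), c(-0.8, 1.1, 0),
                          c(-0.5, 2.05, 0), c(-1.0, -1.2, 0.4)),
           bonds = rbind(c(1, 2, 2), c(1, 3, 1), c(3, 4, 1), c(1, 5, 1)),
           charges = charges)
}

# rigid 3-membered carbon ring (no rotatable bonds)
toy_ring <- function(id = "ring1") {
  molecule(id, c("C", "C", "C"),
           rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)),
           rbind(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1)))
}

# butane-like chain with a single rotatable central bond
toy_rotor <- function(id = "rot1") {
  molecule(id, c("C", "C", "C", "C"),
           rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.7, 1.3, 0.2)),
           rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
}

# single-atom molecule at the origin
toy_atom <- function(id = "atom1", element = "C") {
  molecule(id, element, matrix(c(0, 0, 0), 1))
}

named_list <- function(...) {
  xs <- list(...)
  setNames(xs, vapply(xs, `[[`, character(1), "id"))
}

# random tiny selection problem: 3 molecules x 2-3 poses, 4 steric
# candidate probes; used by the exhaustive-enumeration oracles
tiny_instance <- function(seed) {
  set.seed(seed)
  mols <- list(); pools <- list()
  for (m in 1:3) {
    n_at <- sample(2:3, 1)
    coords <- matrix(rnorm(n_at * 3, sd = 2), ncol = 3)
    mol <- molecule(paste0("t", m), rep("C", n_at), coords,
                    cbind(seq_len(n_at - 1), 2:n_at, 1))
    mols[[mol$id]] <- mol
    np <- sample(2:3, 1)
    poses <- lapply(seq_len(np), function(q)
      pose(mol, coords + matrix(rnorm(3, sd = 1.2), ncol = 3, nrow = n_at,
                                byrow = TRUE), provenance = "aligned"))
    pools[[m]] <- structure(list(molecule_id = mol$id, poses = poses,
                                 optimal_index = NA_integer_),
                            class = "pq_posepool")
  }
  cands <- probes(rep("steric", 4), matrix(rnorm(12, sd = 3), ncol = 3))
  act <- setNames(runif(3, 3, 8), names(mols))
  list(mols = mols, pools = pools, cands = cands, act = act)
}

# exhaustive minimum of f over all binary probe subsets (free poses)
exhaustive_subset_min <- function(st) {
  K <- st$K
  best <- Inf
  for (mask in 0:(2^K - 1)) {
    w <- as.numeric(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    f <- pocketqsar:::state_objective(st, w)$f
    if (f < best) best <- f
  }
  best
}

# shared small fitted model for prediction tests (built once per run)
fitted_toy_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pk <- make_pocket(7)
    cfg <- synthetic_config(n_ligands = 10, noise_sd = 0.3, seed = 42,
                            rotors_range = c(0L, 1L))
    ls <- sample_ligand_series(pk, cfg)
    model <- pocket_qsar(ls, config = pq_config(
      n_poses = 8, n_cliques = 3, polar_densities = 1.0, seed = 1,
      refine_rounds = 2))
    cache <<- list(pocket = pk, ligands = ls, model = model)
    cache
  }
})
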