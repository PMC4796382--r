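# Molecular data model, file I/O, curation, RMSD, conformers.

test_that("feature classes are assigned deterministically by rule", {
  m <- toy_molecule()
  # C=O oxygen: acceptor; N with H: donor; carbons and H: steric
  expect_identical(m$feature, c("steric", "acceptor", "donor", "steric",
                                "steric"))
  mc <- toy_molecule(charge_on = 3)
  expect_identical(mc$feature[3], "cation")
  expect_identical(assign_feature_classes("O", matrix(integer(0), ncol = 3),
                                          -1), "anion")
  expect_error(molecule("bad", c("C", "C"), matrix(0, 2, 3),
                        rbind(c(1, 5, 1))), "out of range")
})

test_that("SDF round trip is a fixed point for ids, elements, coordinates", {
  mols <- named_list(toy_molecule("a"), toy_ring("b"),
                     toy_molecule("c", charge_on = 3))
  ls <- ligand_set(mols, data.frame(id = c("a", "b", "c"),
                                    activity = c(6.1, 5.2, 7.3)))
  sdf <- tempfile(fileext = ".sdf"); csv <- tempfile(fileext = ".csv")
  write_ligands(ls, sdf, csv)
  back <- read_ligands(sdf, csv)
  expect_identical(names(back$molecules), c("a", "b", "c"))
  for (id in names(mols)) {
    expect_identical(back$molecules[[id]]$elements, mols[[id]]$elements)
    expect_lt(max(abs(back$molecules[[id]]$coords - mols[[id]]$coords)), 1e-3)
    expect_identical(back$molecules[[id]]$charges, mols[[id]]$charges)
  }
  expect_equal(back$activities["a", "activity"], 6.1)
  # write/read again: unchanged
  sdf2 <- tempfile(fileext = ".sdf")
  write_ligands(back, sdf2)
  again <- read_ligands(sdf2)
  expect_lt(max(abs(again$molecules[["a"]]$coords -
                      back$molecules[["a"]]$coords)), 1e-6)
})

test_that("MOL2 and SDF encodings of one molecule read back identically", {
  m <- toy_molecule("xfmt")
  sdf <- tempfile(fileext = ".sdf"); mol2 <- tempfile(fileext = ".mol2")
  pocketqsar:::write_sdf(list(m), sdf)
  pocketqsar:::write_mol2(list(m), mol2)
  a <- read_ligands(sdf)$molecules[[1]]
  b <- read_ligands(mol2)$molecules[[1]]
  expect_identical(length(a$elements), length(b$elements))
  expect_identical(a$elements, b$elements)
  expect_lt(max(abs(a$coords - b$coords)), 1e-3)
})

test_that("degenerate structure files raise informative errors", {
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c("empty", "  x", "",
               "  0  0  0  0  0  0  0  0  0  0999 V2000",
               "M  END", "$$$$"), sdf)
  expect_error(read_ligands(sdf), "record")
  expect_error(read_ligands(tempfile(fileext = ".sdf")), "no such file")
  # activity id without a structure
  m <- toy_molecule("only")
  sdf2 <- tempfile(fileext = ".sdf"); csv <- tempfile(fileext = ".csv")
  pocketqsar:::write_sdf(list(m), sdf2)
  write.csv(data.frame(id = c("only", "ghost"), activity = c(5, 6)), csv,
            row.names = FALSE)
  expect_error(read_ligands(sdf2, csv), "ghost")
})

test_that("activity curation applies the MW, floor, averaging and outlier rules", {
  raw <- data.frame(
    id = c("A", "A", "B", "B", "C", "D"),
    activity = c(6.0, 6.5, 5.0, 7.5, 8.0, 3.2),
    mol_weight = c(350, 350, 400, 400, 90, 300))
  out <- curate_activities(raw)
  a <- out$kept[out$kept$id == "A", ]
  expect_equal(a$activity, 6.25)
  expect_equal(a$n_assays, 2L)
  expect_equal(a$activity_range, 0.5)
  expect_match(out$dropped$reason[out$dropped$id == "B"], "range 2.50 > 2")
  expect_match(out$dropped$reason[out$dropped$id == "C"], "MW out of range")
  expect_match(out$dropped$reason[out$dropped$id == "D"], "<= 4.0")
  # idempotence on the kept output
  again <- curate_activities(out$kept[, c("id", "activity", "mol_weight")])
  expect_equal(again$kept$activity, out$kept$activity)
  expect_equal(nrow(again$dropped), 0L)
  # empty input is not an error
  empty <- curate_activities(data.frame(id = character(0),
                                        activity = numeric(0),
                                        mol_weight = numeric(0)))
  expect_equal(nrow(empty$kept), 0L)
})

test_that("pose RMSD is exact and a metric on poses of one molecule", {
  m <- toy_ring()
  p <- pose(m)
  expect_equal(pose_rmsd(p, p), 0)
  shifted <- pose(m, m$coords + matrix(c(1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(pose_rmsd(p, shifted), 1)
  # hand-computed per-atom perturbation
  d <- rbind(c(0.1, 0, 0), c(0, 0.2, 0), c(0, 0, 0.3))
  expect_equal(pose_rmsd(p, pose(m, m$coords + d)),
               sqrt(sum(d^2) / 3))
  expect_error(pose_rmsd(p, pose("ring1", matrix(0, 2, 3))), "mismatch")
  # metric properties on random triples
  set.seed(5)
  for (r in 1:20) {
    pa <- pose(m, m$coords + matrix(rnorm(9, sd = 0.7), 3))
    pb <- pose(m, m$coords + matrix(rnorm(9, sd = 0.7), 3))
    pc <- pose(m, m$coords + matrix(rnorm(9, sd = 0.7), 3))
    expect_equal(pose_rmsd(pa, pb), pose_rmsd(pb, pa))
    expect_gte(pose_rmsd(pa, pb), 0)
    expect_lte(pose_rmsd(pa, pc),
               pose_rmsd(pa, pb) + pose_rmsd(pb, pc) + 1e-12)
  }
})

test_that("torsion-grid conformers are deterministic and preserve bonds", {
  ring <- toy_ring()
  expect_length(generate_conformers(ring, 10), 1L)
  rot <- toy_rotor()
  c1 <- generate_conformers(rot, 3, seed = 4)
  c2 <- generate_conformers(rot, 3, seed = 4)
  expect_identical(lapply(c1, `[[`, "coords"), lapply(c2, `[[`, "coords"))
  expect_length(c1, 3L)
  # torsions pairwise differ by at least 30 degrees
  dihedral <- function(coords) {
    b1 <- coords[2, ] - coords[1, ]; b2 <- coords[3, ] - coords[2, ]
    b3 <- coords[4, ] - coords[3, ]
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    atan2(sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2))
  }
  pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  tor <- vapply(c1, function(p) dihedral(p$coords), numeric(1)) * 180 / pi
  dif <- abs(outer(tor, tor, "-"))
  dif <- pmin(dif, 360 - dif)
  expect_true(all(dif[upper.tri(dif)] >= 30 - 1e-6))
  # bonded distances preserved
  ref <- sqrt(rowSums((rot$coords[rot$bonds[, 1], ] -
                         rot$coords[rot$bonds[, 2], ])^2))
  for (p in c1) {
    got <- sqrt(rowSums((p$coords[rot$bonds[, 1], ] -
                           p$coords[rot$bonds[, 2], ])^2))
    expect_equal(got, ref, tolerance = 1e-9)
    expect_identical(p$provenance, "conformer")
  }
})
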