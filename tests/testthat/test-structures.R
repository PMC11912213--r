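test_that("Kabsch superposition is exact on rigid transforms and matches oracles", {
  ens <- generate_toy_peptides(12, "coil", seed = 41)
  s <- ens$members[[1]]
  expect_equal(kabsch_rmsd(s, s)$rmsd, 0, tolerance = 1e-12)
  moved <- random_rigid_copy(s, 4)
  expect_lt(kabsch_rmsd(s, moved)$rmsd, 1e-10)

  # 4-point toy sets with one displaced point vs a rotation-search oracle
  P <- structure(list(atoms = data.frame(
    elety = "CA", resno = 1:4, resid = "ALA",
    x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1), element = "C")),
    class = "pstructure")
  Q <- P
  Q$atoms$x[4] <- Q$atoms$x[4] + 1
  set.seed(1)
  oracle <- euler_rmsd_oracle(as.matrix(P$atoms[, c("x", "y", "z")]),
                              as.matrix(Q$atoms[, c("x", "y", "z")]))
  expect_equal(kabsch_rmsd(P, Q, selection = 1:4)$rmsd, oracle, tolerance = 1e-3)

  # independent cross-check against bio3d's fitted RMSD
  ens2 <- generate_toy_peptides(15, "coil", jitter = 0.8, n_models = 2, seed = 42)
  a <- ens2$members[[1]]; b <- ens2$members[[2]]
  ref <- bio3d::rmsd(as.numeric(t(as.matrix(a$atoms[, c("x", "y", "z")]))),
                     as.numeric(t(as.matrix(b$atoms[, c("x", "y", "z")]))),
                     fit = TRUE)
  expect_equal(kabsch_rmsd(a, b, selection = "all")$rmsd, ref, tolerance = 1e-4)

  degen <- P
  degen$atoms$x <- 1:4; degen$atoms$y <- 2 * (1:4); degen$atoms$z <- 0
  expect_error(kabsch_rmsd(degen, degen, selection = 1:4), "degenerate")
})

test_that("RMSD matrices are symmetric pseudometrics and order helix vs extended sensibly", {
  ens <- generate_toy_peptides(10, "helix", jitter = 0.4, n_models = 4, seed = 5)
  M <- rmsd_matrix(ens)
  expect_equal(M, t(M), tolerance = 1e-9)
  expect_equal(diag(M), rep(0, 4))
  expect_true(all(M >= 0))
  # triangle inequality
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(M[i, j], M[i, k] + M[k, j] + 1e-6)

  dup <- structure_ensemble(rep(ens$members[1], 3))
  expect_equal(max(rmsd_matrix(dup)), 0, tolerance = 1e-12)

  seqn <- paste(rep("A", 28), collapse = "")
  helix <- generate_toy_peptides(28, "helix", sequence = seqn)$members[[1]]
  helix2 <- generate_toy_peptides(28, "helix", sequence = seqn, jitter = 0.1,
                                  n_models = 1, seed = 8)$members[[1]]
  extended <- generate_toy_peptides(28, "extended", sequence = seqn)$members[[1]]
  expect_gt(kabsch_rmsd(helix, extended)$rmsd, kabsch_rmsd(helix, helix2)$rmsd)
})

test_that("RMSF isolates jittered residues and matches a direct variance oracle", {
  seqn <- paste(rep("A", 8), collapse = "")
  base <- generate_toy_peptides(8, "extended", sequence = seqn)$members[[1]]
  same <- structure_ensemble(list(base, base, base))
  expect_equal(rmsf(same), rep(0, 8), tolerance = 1e-12)

  # displace residue 4 by +-d along z in alternating members (CA and CB)
  d <- 0.9
  perturbed <- lapply(1:4, function(m) {
    s <- base
    rows <- s$atoms$resno == 4
    s$atoms$z[rows] <- s$atoms$z[rows] + d * c(1, -1, 1, -1)[m]
    s
  })
  ens <- structure_ensemble(perturbed)
  # align on the untouched residues: only residue 4 fluctuates, by exactly d
  sel_fixed <- which(ens$members[[1]]$atoms$resno != 4)
  rf <- rmsf(ens, selection = "all", align_selection = sel_fixed)
  expect_equal(rf[4], d, tolerance = 1e-10)
  expect_equal(rf[-4], rep(0, 7), tolerance = 1e-10)

  # direct per-coordinate variance oracle on an aligned ensemble
  ens2 <- generate_toy_peptides(9, "coil", jitter = 0.3, n_models = 6, seed = 10)
  aligned <- align_ensemble(ens2, "all")
  sel <- atom_selection(aligned$members[[1]], "all")
  resno <- aligned$members[[1]]$atoms$resno[sel]
  cents <- lapply(aligned$members, function(s) {
    xyz <- as.matrix(s$atoms[sel, c("x", "y", "z")])
    t(vapply(sort(unique(resno)),
             function(r) colMeans(xyz[resno == r, , drop = FALSE]), numeric(3)))
  })
  mean_c <- Reduce("+", cents) / length(cents)
  oracle <- sqrt(Reduce("+", lapply(cents, function(cc)
    rowSums((cc - mean_c)^2))) / length(cents))
  expect_equal(rmsf(ens2, "all"), oracle, tolerance = 1e-10)

  expect_warning(rmsf(structure_ensemble(list(base))), "single-member")
})

test_that("radius of gyration matches closed forms", {
  one <- pstructure(data.frame(elety = "CA", resno = 1, resid = "ALA",
                               x = 0, y = 0, z = 0, element = "C"))
  expect_equal(radius_of_gyration(one), 0)

  two <- pstructure(data.frame(elety = c("CA", "CA"), resno = 1:2,
                               resid = "ALA", x = c(0, 2), y = 0, z = 0,
                               element = "C"))
  expect_equal(radius_of_gyration(two), 1.0)

  # N equally spaced unit masses on a line, spacing d
  for (N in c(5, 16)) {
    d <- 1.3
    lin <- pstructure(data.frame(elety = "CA", resno = 1:N, resid = "GLY",
                                 x = d * (0:(N - 1)), y = 0, z = 0,
                                 element = "C"))
    expect_equal(radius_of_gyration(lin, mass_weighted = FALSE),
                 sqrt((N^2 - 1) / 12) * d, tolerance = 1e-12)
  }
  # extended chains are less compact than helices
  expect_gt(radius_of_gyration(generate_toy_peptides(28, "extended", seed = 1)$members[[1]]),
            radius_of_gyration(generate_toy_peptides(28, "helix", seed = 1)$members[[1]]))
})

test_that("distance maps aggregate ensemble distances with zero diagonal", {
  ens1 <- generate_toy_peptides(7, "coil", seed = 3)
  dm1 <- distance_maps(ens1)
  expect_equal(max(abs(dm1$std)), 0)
  expect_equal(diag(dm1$mean), rep(0, 7))

  # hand-computed two-member check
  ens2 <- generate_toy_peptides(5, "coil", jitter = 1.2, n_models = 2, seed = 6)
  d1 <- as.matrix(stats::dist(ens2$members[[1]]$atoms[
    atom_selection(ens2$members[[1]], "cbeta"), c("x", "y", "z")]))
  d2 <- as.matrix(stats::dist(ens2$members[[2]]$atoms[
    atom_selection(ens2$members[[2]], "cbeta"), c("x", "y", "z")]))
  dm2 <- distance_maps(ens2)
  expect_equal(dm2$mean, (d1 + d2) / 2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(dm2$std, abs(d1 - d2) / 2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("binary contact maps follow the inclusive 8-angstrom CASP rule", {
  ext <- generate_toy_peptides(20, "extended", seed = 2)$members[[1]]
  A <- binary_contact_map(ext)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(1, 20))
  expect_equal(A[1, 10], 0)  # 3.5 A/residue: far pairs not in contact

  # boundary inclusivity at exactly the cutoff
  pair <- pstructure(data.frame(elety = c("CA", "CA"), resno = 1:2,
                                resid = "GLY", x = c(0, 8), y = 0, z = 0,
                                element = "C"))
  expect_equal(binary_contact_map(pair)[1, 2], 1)
  pair$atoms$x[2] <- 8.0001
  expect_equal(binary_contact_map(pair)[1, 2], 0)

  # helix short-range contacts vs a brute-force distance oracle
  helix <- generate_toy_peptides(28, "helix", seed = 9)$members[[1]]
  Ah <- binary_contact_map(helix)
  xyz <- as.matrix(helix$atoms[atom_selection(helix, "cbeta"), c("x", "y", "z")])
  for (i in 1:28) for (j in 1:28) {
    expect_equal(Ah[i, j],
                 as.numeric(i == j || sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 8))
  }
  expect_true(all(Ah[cbind(1:25, 4:28)] == 1))  # (i, i+3)
  expect_true(all(Ah[cbind(1:24, 5:28)] == 1))  # (i, i+4)

  # glycine falls back to CA; residues lacking both are an error
  noca <- pstructure(data.frame(elety = c("CB", "N"), resno = 1:2,
                                resid = c("ALA", "ALA"), x = c(0, 1), y = 0,
                                z = 0, element = c("C", "N")))
  expect_error(binary_contact_map(noca), "neither CB nor CA")
})

test_that("PDB export/import round-trips multi-model ensembles through bio3d", {
  ens <- generate_toy_peptides(6, "coil", jitter = 0.5, n_models = 3, seed = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble_pdb(f)
  expect_equal(length(back$members), 3)
  expect_equal(back$sequence, ens$sequence)
  for (m in 1:3) {
    expect_equal(as.matrix(back$members[[m]]$atoms[, c("x", "y", "z")]),
                 as.matrix(ens$members[[m]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})
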