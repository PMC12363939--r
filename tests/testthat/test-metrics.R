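test_that("lDDT reproduces the hand-enumerated 3-atom case", {
  ref <- point_state(cbind(c(0, 4, 8), 0, 0))
  pred <- point_state(cbind(c(0, 4, 9.2), 0, 0))
  r <- lddt(pred, ref)
  # deviations {0, 1.2, 1.2} -> pair scores {1, 0.5, 0.5} -> global 2/3
  expect_equal(r$global_score, 2 / 3, tolerance = 1e-12)
  expect_equal(r$n_pairs, 3)
  # identity and rigid motion give exactly 1
  expect_equal(lddt(ref, ref)$global_score, 1)
  set.seed(5)
  expect_equal(lddt(apply_rigid(ref), ref)$global_score, 1)
  # zero reference pairs is an error, not NaN
  lone <- point_state(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_error(lddt(lone, lone), "zero reference pairs")
})

test_that("lDDT equals the brute-force oracle on random fixtures", {
  for (k in 1:10) {
    n <- sample(20:80, 1)
    ref <- random_fixture_state(n, seed = 1000 + k)
    pred <- perturb_structure(ref, sigma = runif(1, 0, 1.5), seed = 2000 + k)
    expect_equal(lddt(pred, ref)$global_score,
                 lddt_bruteforce(pred, ref), tolerance = 1e-12, info = k)
  }
})

test_that("lDDT degrades monotonically with noise", {
  ref <- random_fixture_state(60, seed = 7)
  means <- vapply(c(0, 0.25, 1, 4), function(s) {
    mean(vapply(1:20, function(d)
      lddt(perturb_structure(ref, s, seed = d), ref)$global_score, 1))
  }, 1)
  expect_true(all(diff(means) <= 0))
  expect_equal(means[1], 1)
})

test_that("interface lDDT restricts to cross-group pairs", {
  ref <- random_fixture_state(40, seed = 31)
  expect_equal(interface_lddt(ref, ref, "A", "B")$global_score, 1)
  # disjointness is enforced
  expect_error(interface_lddt(ref, ref, "A", "A"), "disjoint")
  # chains far apart: a distinct no-interface error
  apart <- ref
  selB <- apart$table$atoms$chain_id == "B"
  apart$table$atoms$x[selB] <- apart$table$atoms$x[selB] + 100
  expect_error(interface_lddt(apart, apart, "A", "B"), "no interface")
  # translating chain B: strictly between 0 and 1 and equal to the
  # cross-pair brute force (oracle restricted by the same filter)
  pred <- ref
  pb <- pred$table$atoms$chain_id == "B"
  pred$table$atoms$x[pb] <- pred$table$atoms$x[pb] + 1.5
  r <- interface_lddt(pred, ref, "A", "B")
  expect_true(r$global_score > 0 && r$global_score < 1)
  # symmetric in the two groups
  expect_equal(interface_lddt(pred, ref, "B", "A")$global_score,
               r$global_score)
})

test_that("backbone RMSD is superposition-aware and reflection-excluding", {
  n <- 8
  tor <- data.frame(phi = rep(-57, n), psi = rep(-47, n), omega = rep(180, n))
  tp <- make_toy_peptide(strrep("A", n), torsions = tor)
  expect_equal(backbone_rmsd(tp$state, tp$state), 0, tolerance = 1e-9)
  set.seed(13)
  expect_equal(backbone_rmsd(apply_rigid(tp$state), tp$state), 0,
               tolerance = 1e-9)
  # a mirrored helix cannot be superposed by a proper rotation
  expect_gt(backbone_rmsd(invert_structure(tp$state), tp$state), 0.5)
  # needs at least 3 corresponding atoms
  small <- make_toy_peptide("AA")
  one <- small$state
  one$table$atoms <- one$table$atoms[one$table$atoms$atom_name == "CA", ][1, ]
  expect_error(backbone_rmsd(one, one), "at least 3")
})

test_that("Shrake-Rupley SASA matches the single-sphere closed form", {
  st <- point_state(rbind(c(0, 0, 0)))
  area <- per_atom_sasa(st)
  expect_equal(unname(area), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
  # an atom enclosed by a tight shell has (near) zero accessibility
  shell <- sphere_pts <- NULL
  pts <- structforge:::sphere_points(40) * 2.8
  enc <- point_state(rbind(c(0, 0, 0), pts))
  areas <- per_atom_sasa(enc)
  expect_lt(areas[1], 1)
  # occlusion: total SASA decreases on contact
  two_far <- point_state(rbind(c(0, 0, 0), c(50, 0, 0)))
  two_near <- point_state(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_lt(sum(per_atom_sasa(two_near)), sum(per_atom_sasa(two_far)))
  # identical coordinates are an error naming atoms
  dup <- point_state(rbind(c(0, 0, 0), c(0, 0, 0)), res = 1:2)
  expect_error(per_atom_sasa(dup), "overlapping")
})

test_that("mean RASA normalizes by residue type and clips to [0, 1]", {
  # central residue of an extended tripeptide sits near its normalization max
  tp <- make_toy_peptide("GAG")
  r <- mean_rasa(tp$state, data.frame(chain_id = "A", res_index = 2))
  expect_gt(r, 0.5)
  expect_lte(r, 1)
  # empty region and unknown residue type are errors
  expect_error(mean_rasa(tp$state, data.frame(chain_id = character(),
                                              res_index = integer())),
               "empty region")
  st2 <- tp$state
  st2$table$atoms$comp_id <- "XXX"
  expect_error(mean_rasa(st2, data.frame(chain_id = "A", res_index = 2)),
               "max ASA")
})

test_that("clustering follows the ccd and 40%-identity protocols", {
  # identical sequences collapse to one cluster
  cl <- cluster_members(rep("ACDEFGH", 3), "sequence_identity_40",
                        ids = c("a", "b", "c"))
  expect_equal(length(unique(cl$membership)), 1L)
  # exact comp_id partition
  cl2 <- cluster_members(c("ATP", "ATP", "GTP"), "ccd_identity",
                         ids = c("m1", "m2", "m3"))
  expect_equal(length(unique(cl2$membership)), 2L)
  expect_equal(unname(cl2$membership["m1"]), unname(cl2$membership["m2"]))
  # two unrelated random 50-mers: identity below 0.40, two clusters
  set.seed(41)
  s1 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_lt(seq_identity_global(s1, s2), 0.40)
  cl3 <- cluster_members(c(s1, s2), "sequence_identity_40", ids = c("x", "y"))
  expect_equal(length(unique(cl3$membership)), 2L)
  # representatives are members of their cluster
  for (cid in names(cl3$representatives))
    expect_equal(unname(cl3$membership[cl3$representatives[cid]]), cid)
  expect_error(cluster_members(character()), "empty input")
})

test_that("clustered mean weights clusters, not members", {
  cl <- cluster_members(c("A", "A", "B"), "ccd_identity",
                        ids = c("m1", "m2", "m3"))
  expect_equal(clustered_mean(c(m1 = 1.0, m2 = 0.5, m3 = 0.8), cl), 0.775)
  # all singletons: plain mean; one cluster: within-cluster mean
  cls <- cluster_members(c("A", "B", "C"), "ccd_identity",
                         ids = c("m1", "m2", "m3"))
  expect_equal(clustered_mean(c(m1 = 0.2, m2 = 0.4, m3 = 0.9), cls),
               mean(c(0.2, 0.4, 0.9)))
  cl1 <- cluster_members(c("A", "A"), "ccd_identity", ids = c("m1", "m2"))
  expect_equal(clustered_mean(c(m1 = 0.2, m2 = 0.8), cl1), 0.5)
  # permutation invariance in member order
  expect_equal(clustered_mean(c(m3 = 0.8, m1 = 1.0, m2 = 0.5), cl), 0.775)
  # unclustered member is an error
  expect_error(clustered_mean(c(m1 = 1, zz = 0), cl), "missing")
})
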