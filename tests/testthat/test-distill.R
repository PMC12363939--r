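test_that("internal-coordinate placement realizes the requested geometry", {
  g <- ideal_geometry()
  bb <- place_chain_internal(g, 5)
  get <- function(i, nm) as.numeric(bb[bb$res == i & bb$atom_name == nm,
                                       c("x", "y", "z")])
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  for (i in 1:5) {
    expect_equal(sqrt(sum((get(i, "N") - get(i, "CA"))^2)), g$len_n_ca,
                 tolerance = 1e-3)
    expect_equal(sqrt(sum((get(i, "CA") - get(i, "C"))^2)), g$len_ca_c,
                 tolerance = 1e-3)
    expect_equal(ang(get(i, "N"), get(i, "CA"), get(i, "C")), g$ang_n_ca_c,
                 tolerance = 1e-3)
    if (i < 5) {
      expect_equal(sqrt(sum((get(i, "C") - get(i + 1, "N"))^2)), g$len_c_n,
                   tolerance = 1e-3)
      expect_equal(ang(get(i, "CA"), get(i, "C"), get(i + 1, "N")),
                   g$ang_ca_c_n, tolerance = 1e-3)
      expect_equal(ang(get(i, "C"), get(i + 1, "N"), get(i + 1, "CA")),
                   g$ang_c_n_ca, tolerance = 1e-3)
      # torsions at the requested 180
      expect_equal(abs(measure_torsion(get(i, "C"), get(i + 1, "N"),
                                       get(i + 1, "CA"), get(i + 1, "C"))),
                   180, tolerance = 1e-3)
    }
  }
  # two runs, same inputs: identical coordinates
  expect_identical(bb, place_chain_internal(g, 5))
  # colinear anchor is rejected
  expect_error(place_chain_internal(g, 2, anchor = rbind(c(0, 0, 0),
                                                         c(1, 0, 0),
                                                         c(2, 0, 0))),
               "colinear")
})

test_that("the fully extended chain steps ~3.80 A per residue, oracle-checked", {
  g <- ideal_geometry()
  bb <- place_chain_internal(g, 2)
  ca <- as.matrix(bb[bb$atom_name == "CA", c("x", "y", "z")])
  d <- sqrt(sum((ca[1, ] - ca[2, ])^2))
  # closed-form chain arithmetic: lay the five bonded atoms in a plane with
  # all-trans torsions and read off the CA(i)..CA(i+1) distance
  rad <- function(x) x * pi / 180
  pts <- matrix(0, 4, 2)
  pts[1, ] <- c(0, 0)                       # CA(i)
  theta <- 0
  lens <- c(g$len_ca_c, g$len_c_n, g$len_n_ca)
  angs <- c(g$ang_ca_c_n, g$ang_c_n_ca)
  for (k in 1:3) {
    pts[k + 1, ] <- pts[k, ] + lens[k] * c(cos(theta), sin(theta))
    if (k < 3) theta <- theta + (pi - rad(angs[k])) * (-1)^(k + 1)
  }
  oracle <- sqrt(sum((pts[4, ] - pts[1, ])^2))
  expect_equal(d, oracle, tolerance = 1e-9)
  expect_lt(abs(d - 3.80), 0.05)
})

test_that("disordered tails grow from anchors without touching resolved atoms", {
  n <- 14
  tor <- data.frame(phi = rep(-57, n), psi = rep(-47, n), omega = rep(180, n))
  tp <- make_toy_peptide(strrep("A", n), torsions = tor)
  st <- mark_unresolved(tp$state, 10:14)
  before <- st$table$atoms
  ext <- extend_disordered_regions(st, seed = 3)
  a <- ext$table$atoms
  bb_tail <- a$res_index %in% 10:14 & a$atom_name %in% c("N", "CA", "C", "O")
  expect_true(all(is.finite(a$x[bb_tail])))
  expect_false(any(a$is_resolved[a$res_index %in% 10:14]))
  expect_true(all(a$atom_uid[bb_tail] %in% ext$extras$imputed_extended))
  # resolved coordinates bit-identical
  idx <- before$is_resolved
  expect_identical(a$x[idx], before$x[idx])
  expect_identical(a$y[idx], before$y[idx])
  expect_identical(a$z[idx], before$z[idx])
  # chain continuity at the junction: C(9)-N(10) within 0.1 A of 1.329
  cx <- as.numeric(a[a$res_index == 9 & a$atom_name == "C", c("x", "y", "z")])
  nx <- as.numeric(a[a$res_index == 10 & a$atom_name == "N", c("x", "y", "z")])
  expect_lt(abs(sqrt(sum((cx - nx)^2)) - 1.329), 0.1)
  # idempotence
  ext2 <- extend_disordered_regions(ext, seed = 3)
  expect_identical(ext2$table$atoms, ext$table$atoms)
  # no placed backbone atom clashes with a resolved atom outside the anchor
  placed <- as.matrix(a[bb_tail, c("x", "y", "z")])
  res_xyz <- as.matrix(a[a$is_resolved & a$res_index < 9, c("x", "y", "z")])
  dmin <- min(apply(placed, 1, function(p)
    min(rowSums(sweep(res_xyz, 2, p)^2))))
  expect_gt(sqrt(dmin), 2.0)
})

test_that("N-terminal tails and internal gaps are also filled", {
  n <- 12
  tor <- data.frame(phi = rep(-57, n), psi = rep(-47, n), omega = rep(180, n))
  tp <- make_toy_peptide(strrep("A", n), torsions = tor)
  # N-terminal tail grows backward
  stN <- mark_unresolved(tp$state, 1:4)
  extN <- extend_disordered_regions(stN, seed = 5)
  aN <- extN$table$atoms
  expect_true(all(is.finite(aN$x[aN$res_index %in% 1:4 &
                                   aN$atom_name %in% c("N", "CA", "C", "O")])))
  c4 <- as.numeric(aN[aN$res_index == 4 & aN$atom_name == "C", c("x", "y", "z")])
  n5 <- as.numeric(aN[aN$res_index == 5 & aN$atom_name == "N", c("x", "y", "z")])
  expect_lt(abs(sqrt(sum((c4 - n5)^2)) - 1.329), 0.1)
  # internal gap grows from the N-side anchor
  stG <- mark_unresolved(tp$state, 6:8)
  extG <- extend_disordered_regions(stG, seed = 5)
  aG <- extG$table$atoms
  expect_true(all(is.finite(aG$x[aG$res_index %in% 6:8 &
                                   aG$atom_name %in% c("N", "CA", "C", "O")])))
  # a chain with no anchor at all is reported and skipped
  stX <- mark_unresolved(tp$state, 1:n)
  extX <- extend_disordered_regions(stX, seed = 5)
  expect_true(all(is.na(extX$table$atoms$x)))
  expect_true(any(grepl("no resolved anchor", unlist(extX$log))))
})

test_that("extended tails are more exposed than compact segments", {
  n <- 14
  tor <- data.frame(phi = rep(-57, n), psi = rep(-47, n), omega = rep(180, n))
  tp <- make_toy_peptide(strrep("A", n), torsions = tor)
  st <- mark_unresolved(tp$state, 10:14)
  ext <- extend_disordered_regions(st, seed = 3)
  # score exposure over all placed + resolved coordinates
  ext$table$atoms$is_resolved <- is.finite(ext$table$atoms$x)
  s <- per_atom_sasa(ext)
  tail_rasa <- mean_rasa(ext, data.frame(chain_id = "A", res_index = 10:14),
                         sasa = s)
  helix_rasa <- mean_rasa(ext, data.frame(chain_id = "A", res_index = 3:7),
                          sasa = s)
  expect_gt(tail_rasa, helix_rasa)
})
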