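test_that("signed angle hits the tetrahedral ideal and flips under reflection", {
  p <- tetrahedral_points()
  th <- chiral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  expect_equal(th, asin(sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(th, ideal_chiral_angle(), tolerance = 1e-12)
  # mirror: negate x
  m <- p; m[, 1] <- -m[, 1]
  expect_equal(chiral_angle(m[1, ], m[2, ], m[3, ], m[4, ]), -th,
               tolerance = 1e-12)
  # n1 in the plane of (center, n2, n3): zero
  expect_equal(chiral_angle(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0)),
               0, tolerance = 1e-12)
  # degenerate: n2, n3 colinear with center
  expect_error(chiral_angle(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("signed angle is invariant under 100 random proper isometries", {
  set.seed(11)
  p <- tetrahedral_points() + matrix(rnorm(12, sd = 0.1), 4)
  th0 <- chiral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  for (k in 1:100) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    q <- sweep(p %*% R, 2, t, "+")
    expect_equal(chiral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), th0,
                 tolerance = 1e-9)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(101)
  cc <- structure(list(center = 1L, ordered_neighbors = 2:4,
                       reference_sign = 1,
                       ideal_angle = ideal_chiral_angle()),
                  class = "ChiralCenter")
  h <- 1e-4
  worst <- 0
  for (k in 1:100) {
    xyz <- tetrahedral_points() * runif(1, 0.8, 1.6) +
      matrix(rnorm(12, sd = 0.15), 4)
    gf <- chiral_error_gradient(cc, xyz)
    fd <- matrix(0, 4, 3)
    E <- function(m) (chiral_angle(m[1, ], m[2, ], m[3, ], m[4, ]) -
                        cc$ideal_angle)^2
    # fourth-order central stencil at step h
    for (i in 1:4) for (j in 1:3) {
      f <- function(d) { m <- xyz; m[i, j] <- m[i, j] + d; E(m) }
      fd[i, j] <- (f(-2 * h) - 8 * f(-h) + 8 * f(h) - f(2 * h)) / (12 * h)
    }
    rel <- norm(gf$grad - fd, "F") / max(norm(fd, "F"), 1e-8)
    worst <- max(worst, rel)
    # translation invariance: the four gradients sum to zero
    expect_lt(max(abs(colSums(gf$grad))), 1e-10)
  }
  expect_lt(worst, 1e-5)
  # exactly at the ideal angle the gradient vanishes
  g0 <- chiral_error_gradient(cc, tetrahedral_points())
  expect_lt(max(abs(g0$grad)), 1e-12)
})

test_that("chiral centers are detected with correct branch logic", {
  dict <- builtin_components()
  tp <- make_toy_peptide("AG")
  found <- find_chiral_centers(tp$state, dict)
  a <- tp$state$table$atoms
  centers <- vapply(found$centers, `[[`, 1L, "center")
  names_found <- a$atom_name[match(centers, a$atom_uid)]
  res_found <- a$res_index[match(centers, a$atom_uid)]
  # ALA CA is a center (branches N, C, CB, implicit H); GLY CA is not
  expect_true(any(names_found == "CA" & res_found == 1))
  expect_false(any(res_found == 2))
  # the 3-stereocenter ligand yields exactly 3 centers
  trl <- component_state("TRL")
  found2 <- find_chiral_centers(trl, dict)
  expect_length(found2$centers, 3L)
  expect_equal(found2$n_ambiguous, 0L)
  a2 <- trl$table$atoms
  expect_setequal(a2$atom_name[match(vapply(found2$centers, `[[`, 1L, "center"),
                                     a2$atom_uid)], c("C2", "C3", "C4"))
  # every center carries the ideal magnitude with its reference sign
  for (cc in c(found$centers, found2$centers))
    expect_equal(abs(cc$ideal_angle), ideal_chiral_angle(), tolerance = 1e-12)
})

test_that("structure inversion is an isometric involution that flips all centers", {
  dict <- builtin_components()
  trl <- component_state("TRL")
  inv <- invert_structure(trl)
  # pairwise distances unchanged
  d0 <- dist(coords_matrix(trl$table))
  d1 <- dist(coords_matrix(inv$table))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
  # double application restores coordinates exactly
  back <- invert_structure(inv)
  expect_identical(back$table$atoms$x, trl$table$atoms$x)
  # every stereocenter sign flips
  found <- find_chiral_centers(trl, dict)
  for (cc in found$centers) {
    x0 <- coords_matrix(trl$table, c(cc$center, cc$ordered_neighbors))
    x1 <- coords_matrix(inv$table, c(cc$center, cc$ordered_neighbors))
    expect_equal(sign(chiral_angle(x1[1, ], x1[2, ], x1[3, ], x1[4, ])),
                 -sign(chiral_angle(x0[1, ], x0[2, ], x0[3, ], x0[4, ])))
  }
})

test_that("inversion augmentation follows its Bernoulli rate", {
  tp <- make_toy_peptide("AAA")
  st <- tp$state
  draw <- function(p, seed) {
    out <- sample_inversion_augmentation(st, p = p, seed = seed)
    isTRUE(out$extras$inverted)
  }
  # p = 0: never inverted; p = 1: always
  expect_false(any(vapply(1:1000, function(s) draw(0, s), TRUE)))
  expect_true(all(vapply(1:100, function(s) draw(1, s), TRUE)))
  # p = 0.02 over 10000 seeded draws: within 3 sigma of 200
  n <- 10000
  count <- sum(vapply(seq_len(n), function(s) draw(0.02, s), TRUE))
  sigma <- sqrt(n * 0.02 * 0.98)
  expect_lt(abs(count - n * 0.02), 3 * sigma)
})

test_that("chiral-center accuracy uses cluster means", {
  dict <- builtin_components()
  tp <- make_toy_peptide("AACS", d_positions = 2)
  # perfect prediction
  acc <- chiral_center_accuracy(tp$state, tp$state, dict = dict)
  expect_equal(acc$overall, 1.0)
  expect_gt(acc$n_centers, 0)
  # fully mirrored prediction
  acc0 <- chiral_center_accuracy(invert_structure(tp$state), tp$state,
                                 dict = dict)
  expect_equal(acc0$overall, 0.0)
  # the cluster-mean arithmetic: {100%, 50%} and {80%} -> 0.775
  cl <- structure(list(membership = c(m1 = "c1", m2 = "c1", m3 = "c2"),
                       representatives = c(c1 = "m1", c2 = "m3")),
                  class = "ClusterAssignment")
  expect_equal(clustered_mean(c(m1 = 1.0, m2 = 0.5, m3 = 0.8), cl), 0.775)
  # a structure without centers raises a distinct error
  gly <- make_toy_peptide("GG")
  expect_error(chiral_center_accuracy(gly$state, gly$state, dict = dict),
               "no chiral centers")
})

test_that("L fixtures share one CA sign; D fixtures give the opposite", {
  dict <- builtin_components()
  sign_at_ca <- function(state, res) {
    found <- find_chiral_centers(state, dict)
    a <- state$table$atoms
    for (cc in found$centers) {
      if (a$res_index[match(cc$center, a$atom_uid)] == res &&
          a$atom_name[match(cc$center, a$atom_uid)] == "CA") {
        xyz <- coords_matrix(state$table, c(cc$center, cc$ordered_neighbors))
        return(sign(chiral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])))
      }
    }
    NA_real_
  }
  # all-L homopolymer: identical signs at every CA
  tpL <- make_toy_peptide("AAAA")
  sL <- vapply(1:4, function(r) sign_at_ca(tpL$state, r), 1)
  expect_length(unique(sL), 1L)
  # D at position 2: the (+,-,+) pattern relative to the all-L reference
  tpD <- make_toy_peptide("AAA", d_positions = 2)
  sD <- vapply(1:3, function(r) sign_at_ca(tpD$state, r), 1)
  expect_equal(sD[1], sD[3])
  expect_equal(sD[2], -sD[1])
  # serine behaves like alanine under the ranking rule
  tpS <- make_toy_peptide("SS", d_positions = 2)
  sS <- vapply(1:2, function(r) sign_at_ca(tpS$state, r), 1)
  expect_equal(sS[2], -sS[1])
})
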