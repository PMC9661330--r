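test_that("series solution matches the closed-form potential in an
          unbounded medium", {
  # with all harmonic gains set to 1 the series reduces to the expansion of
  # the infinite homogeneous-medium dipole potential, which has the exact
  # closed form q.(r - r0) / (4 pi sigma |r - r0|^3)
  sigma <- 0.33; R <- 92
  ehat <- symmetric_montage(16)
  for (pos in list(c(20, -30, 25), c(0, 55, -10), c(-40, 5, 40))) {
    V <- amypower:::dipole_potential(pos, ehat, R, sigma, rep(1, 300))
    direct <- sapply(1:3, function(j) {
      apply(ehat, 1, function(e) {
        r <- R * e - pos
        r[j] / (4 * pi * sigma * sum(r^2)^1.5)
      })
    })
    expect_lt(max(abs(V - direct)) / max(abs(direct)), 1e-8)
  }
})

test_that("homogeneous-sphere harmonic gains follow the analytic value", {
  # equal conductivities + insulating boundary: surface gain (2n+1)/n
  S <- amypower:::shell_transfer(c(80, 85, 92) / 92, rep(0.33, 3), 12)
  n <- 1:12
  expect_equal(S, (2 * n + 1) / n, tolerance = 1e-12)
})

test_that("head model validates its geometry", {
  expect_error(head_model(radii = c(80, 75, 92)), "increasing")
  expect_error(head_model(conductivities = c(0.3, -1, 0.3)), "positive")
  bad <- matrix(c(0, 0, 0), 1)
  expect_error(head_model(electrodes = bad), "origin")
  expect_error(make_leadfield(small_model(),
                              grid = rbind(c(0, 0, 85))),
               "outside the innermost shell")
})

test_that("every voxel's three orientation gain columns are independent", {
  lf <- small_leadfield()
  ranks <- apply(lf$gain, 1L, function(g) qr(t(g))$rank)
  expect_true(all(ranks == 3L))
})

test_that("gains are linear in the dipole moment", {
  lf <- small_leadfield()
  g <- lf$gain[10, , ]
  q <- c(0.3, -1.2, 0.5)
  expect_equal(as.vector((2 * q) %*% g), 2 * as.vector(q %*% g),
               tolerance = 1e-12)
  q2 <- c(1, 1, 0)
  expect_equal(as.vector((q + q2) %*% g),
               as.vector(q %*% g) + as.vector(q2 %*% g),
               tolerance = 1e-12)
})

test_that("mirror-symmetric dipoles give mirror-permuted topographies", {
  model <- small_model()
  lf <- small_leadfield()
  perm <- mirror_permutation(model$electrode_positions)
  pos <- c(25, 31, 17)
  S <- amypower:::shell_transfer(model$radii / model$radii[3],
                                 model$conductivities, 60)
  V <- amypower:::dipole_potential(pos, model$electrode_positions,
                                   model$radii[3], model$conductivities[1],
                                   S)
  Vm <- amypower:::dipole_potential(pos * c(-1, 1, 1),
                                    model$electrode_positions,
                                    model$radii[3],
                                    model$conductivities[1], S)
  # mirroring position and moment: x-moment flips sign, y/z unchanged
  expect_lt(max(abs(V[perm, 1] + Vm[, 1])), 1e-6 * max(abs(V)))
  expect_lt(max(abs(V[perm, 2] - Vm[, 2])), 1e-6 * max(abs(V)))
  expect_lt(max(abs(V[perm, 3] - Vm[, 3])), 1e-6 * max(abs(V)))
})

test_that("lattice adjacency links exactly the 6 face neighbours", {
  ijk <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  adj <- lattice_adjacency(ijk)
  center <- which(ijk[, 1] == 2 & ijk[, 2] == 2 & ijk[, 3] == 2)
  expect_length(adj[[center]], 6L)
  corner <- which(ijk[, 1] == 1 & ijk[, 2] == 1 & ijk[, 3] == 1)
  expect_length(adj[[corner]], 3L)
  # symmetry
  for (v in seq_along(adj)) {
    for (nb in adj[[v]]) expect_true(v %in% adj[[nb]])
  }
})

test_that("the default grid labels both planted ROIs", {
  lf <- small_leadfield()
  expect_gt(sum(lf$roi == "mid_frontal"), 0)
  expect_gt(sum(lf$roi == "posterior"), 0)
  expect_true(all(sqrt(rowSums(lf$grid^2)) < small_model()$radii[1]))
})
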