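test_that("curve resampling spaces points equally by arc length", {
  # straight segment oversampled at 9 interior points -> quartiles
  line <- cbind(seq(0, 1, length.out = 11), 0, 0)
  out <- resample_curve(line, 5)
  expect_equal(out[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(out[, 2], rep(0, 5))

  # right-angle polyline of total length 2: middle point lands on the corner
  bend <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  out2 <- resample_curve(bend, 3)
  expect_equal(out2[2, ], c(1, 0, 0))
  expect_equal(out2[1, ], c(0, 0, 0))
  expect_equal(out2[3, ], c(1, 1, 0))

  # idempotence on already-uniform input
  u <- cbind(seq(0, 2, length.out = 7), seq(0, 1, length.out = 7), 0)
  expect_lt(max(abs(resample_curve(u, 7) - u)), 1e-12)

  expect_error(resample_curve(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), 3),
               "duplicate")
})

test_that("Procrustes distance is a similarity-invariant metric", {
  sh <- random_shape(10, 1)
  expect_lt(procrustes_distance(sh, transformed_copy(sh, 2)), 1e-10)

  for (s in 1:100) {
    a <- random_shape(6, 300 + s); b <- random_shape(6, 600 + s)
    expect_lt(abs(procrustes_distance(a, b) - procrustes_distance(b, a)),
              1e-12)
  }

  expect_error(procrustes_distance(random_shape(5, 1), random_shape(6, 1)),
               "mismatch")
})

test_that("Procrustes distance matches the rotation-grid-search oracle", {
  eq <- planar_triangle(c(0, 0, 1, 0, 0.5, sqrt(3) / 2))
  iso <- planar_triangle(c(0, 0, 1, 0, 0.5, 0.05))  # nearly degenerate
  expect_lt(abs(procrustes_distance(eq, iso) -
                  oracle_planar_procrustes(eq, iso)), 1e-6)
  for (s in 1:5) {
    set.seed(s)
    a <- planar_triangle(rnorm(8)); b <- planar_triangle(rnorm(8))
    expect_lt(abs(procrustes_distance(a, b) - oracle_planar_procrustes(a, b)),
              1e-6)
  }
})

test_that("Procrustes distance satisfies the triangle inequality locally", {
  base <- random_shape(12, 7)
  for (s in 1:40) {
    set.seed(1000 + s)
    a <- base + matrix(rnorm(36, 0, 0.1), 12, 3)
    b <- base + matrix(rnorm(36, 0, 0.1), 12, 3)
    c_ <- base + matrix(rnorm(36, 0, 0.1), 12, 3)
    dab <- procrustes_distance(a, b)
    dbc <- procrustes_distance(b, c_)
    dac <- procrustes_distance(a, c_)
    if (max(dab, dbc, dac) < 0.3)
      expect_lte(dac, dab + dbc + 1e-8)
  }
})

test_that("GPA removes similarity transforms and is order-invariant", {
  sh <- random_shape(9, 5)
  arr <- array(NA_real_, c(2, 9, 3))
  arr[1, , ] <- sh
  arr[2, , ] <- transformed_copy(sh, 6)
  al <- gpa_align(arr)
  expect_lt(max(abs(al$aligned[1, , ] - al$aligned[2, , ])), 1e-9)
  expect_lt(procrustes_distance(al$aligned[1, , ], al$aligned[2, , ]), 1e-9)

  # alignment invariants: centered, unit size, consensus = mean
  s <- simulate_dataset(n_tips = 10, n_landmarks = 12, seed = 2)
  al2 <- gpa_align(s$landmarks)
  for (i in 1:10) {
    expect_lt(sqrt(sum(colMeans(al2$aligned[i, , ])^2)), 1e-10)
    expect_lt(abs(sqrt(sum(al2$aligned[i, , ]^2)) - 1), 1e-10)
  }
  expect_lt(max(abs(al2$consensus - apply(al2$aligned, c(2, 3), mean))),
            1e-10)

  perm <- c(4, 1, 9, 7, 2, 10, 3, 5, 8, 6)
  al3 <- gpa_align(s$landmarks$coords[perm, , ])
  expect_lt(procrustes_distance(al3$consensus, al2$consensus), 1e-8)

  degen <- array(1, c(2, 5, 3))
  degen[2, , ] <- random_shape(5, 3)
  expect_error(gpa_align(degen), "s1")
})

test_that("semilandmark sliding lowers the Procrustes sum of squares", {
  s <- simulate_dataset(n_tips = 12, n_landmarks = 16, seed = 8)
  ds <- s$landmarks
  # jitter semilandmarks along their curve
  sl <- sliding_indices(ds)
  expect_gt(length(sl), 0)
  set.seed(4)
  for (i in seq_len(dim(ds$coords)[1])) {
    cv <- ds$curves[[1]]$ids
    for (jj in 2:(length(cv) - 1)) {
      tg <- ds$coords[i, cv[jj + 1], ] - ds$coords[i, cv[jj - 1], ]
      ds$coords[i, cv[jj], ] <- ds$coords[i, cv[jj], ] +
        runif(1, -0.2, 0.2) * tg
    }
  }
  al_fix <- gpa_align(ds, slide = FALSE)
  al_sl <- gpa_align(ds, slide = TRUE)
  expect_lte(morphoshift:::gpa_objective(al_sl),
             morphoshift:::gpa_objective(al_fix))
})

test_that("species consensus averages specimens and symmetrizes pairs", {
  # one specimen: consensus equals the specimen
  arr <- array(NA_real_, c(3, 8, 3))
  for (i in 1:3) arr[i, , ] <- transformed_copy(random_shape(8, 40 + i), i)
  al <- gpa_align(arr)
  cons1 <- species_consensus(al, c("a", "b", "b"))
  expect_equal(cons1["a", , ], al$aligned[1, , ])
  expect_equal(cons1["b", , ],
               (al$aligned[2, , ] + al$aligned[3, , ]) / 2)

  # hand-computed average of 4 specimens
  arr4 <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  al4 <- gpa_align(arr4)
  cons4 <- species_consensus(al4, rep("x", 4))
  expect_equal(cons4["x", , ], unname(apply(al4$aligned, c(2, 3), mean)))

  # mirror-image pair symmetrizes exactly
  tp <- morphoshift:::default_template(12)
  sh <- tp$shape + matrix(rnorm(36, 0, 0.05), 12, 3)
  pl <- morphoshift:::fit_plane(sh[tp$midline, , drop = FALSE])
  msh <- morphoshift:::reflect_across_plane(sh, pl)
  msh2 <- msh
  msh2[tp$pairs[, 1], ] <- msh[tp$pairs[, 2], ]
  msh2[tp$pairs[, 2], ] <- msh[tp$pairs[, 1], ]
  arr2 <- array(NA_real_, c(2, 12, 3))
  arr2[1, , ] <- sh; arr2[2, , ] <- msh2
  al2 <- gpa_align(arr2)
  cons <- species_consensus(al2, rep("m", 2), bilateral_pairs = tp$pairs,
                            midline = tp$midline)
  m <- cons["m", , ]
  pl2 <- morphoshift:::fit_plane(m[tp$midline, , drop = FALSE])
  refl <- morphoshift:::reflect_across_plane(m, pl2)
  expect_lt(max(abs(m[tp$pairs[, 1], ] - refl[tp$pairs[, 2], ])), 1e-10)
})
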