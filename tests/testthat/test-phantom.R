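test_that("noise-free phantom voxels equal their layer means exactly", {
  spec <- tiny_phantom_spec(speckle_shape = Inf, additive_sd = 0,
                            n_shadows = 0)
  ph <- generate_phantom(spec)
  expect_true(all(ph$volume$intensity %in% spec$layer_means))
  # layer membership consistent with the ground-truth surfaces
  zt <- ph$truth$z
  x <- 3L; y <- 2L
  for (k in seq_len(11)) {
    zk <- zt[x, y, k]
    if (zk + 2L <= spec$dims[3] && (k == 11 || zt[x, y, k + 1] > zk))
      expect_equal(ph$volume$intensity[x, y, zk + 2L],
                   spec$layer_means[k + 1L])
  }
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_phantom(tiny_phantom_spec(seed = 7L))
  b <- generate_phantom(tiny_phantom_spec(seed = 7L))
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$z, b$truth$z)
  c <- generate_phantom(tiny_phantom_spec(seed = 8L))
  expect_false(identical(a$volume$intensity, c$volume$intensity))
})

test_that("invalid phantom specs fail before sampling", {
  expect_error(tiny_phantom_spec(pit_depth_mm = 0.5), "past its successor")
  expect_error(phantom_spec(dims = c(2, 2, 2)), ">= 4")
  expect_error(phantom_spec(base_depths_mm = c(0.1, 0.1, 0.2)),
               "strictly increasing")
  expect_error(tiny_phantom_spec(shadow_attenuation = 0), "attenuation")
  expect_error(tiny_phantom_spec(speckle_shape = -1), "speckle_shape")
})

test_that("ground-truth surfaces keep the ordering invariant and stay in range", {
  for (seed in 1:5) {
    ph <- generate_phantom(tiny_phantom_spec(seed = seed))
    z <- ph$truth$z
    for (k in 1:10) expect_true(all(z[, , k + 1] >= z[, , k]))
    expect_true(all(z >= 0 & z < tiny_phantom_spec()$dims[3]))
  }
})

test_that("ground-truth GCC thins to near zero at the pit and not at the ring", {
  spec <- phantom_spec(speckle_shape = Inf, additive_sd = 0, n_shadows = 0)
  ph <- generate_phantom(spec)
  gcc <- layer_thickness(ph$truth, 1, 4, spec$spacing[3])
  xs <- (seq_len(spec$dims[1]) - 0.5) * spec$spacing[1]
  ys <- (seq_len(spec$dims[2]) - 0.5) * spec$spacing[2]
  r <- sqrt(outer((xs - spec$pit_center_mm[1])^2,
                  (ys - spec$pit_center_mm[2])^2, `+`))
  base_gcc <- (spec$base_depths_mm[4] - spec$base_depths_mm[1]) * 1000
  # closed form at the center: residual fraction of the base thickness
  wmax <- spec$pit_depth_mm /
    (spec$base_depths_mm[6] - spec$base_depths_mm[1])
  ctr <- which(r == min(r), arr.ind = TRUE)[1, ]
  expect_lt(gcc$t[ctr[1], ctr[2]], (1 - wmax) * base_gcc + 3 * spec$spacing[3] * 1000)
  expect_lt(gcc$t[ctr[1], ctr[2]], 0.2 * base_gcc)  # "near zero"
  ring <- abs(r - 1.5) < 0.1   # on the 3-mm circle, outside the pit
  expect_equal(mean(gcc$t[ring]), base_gcc,
               tolerance = 2 * spec$spacing[3] * 1000 / base_gcc)
})

test_that("vessel shadows attenuate columns only below the NFL-GCL surface", {
  spec <- tiny_phantom_spec(speckle_shape = Inf, additive_sd = 0,
                            n_shadows = 2L, shadow_attenuation = 0.5)
  ph <- generate_phantom(spec)
  clean <- generate_phantom(tiny_phantom_spec(speckle_shape = Inf,
                                              additive_sd = 0, n_shadows = 0))
  ratio <- ph$volume$intensity / pmax(clean$volume$intensity, 1e-9)
  shadowed <- apply(ratio < 0.75, 1, any)
  expect_gt(sum(shadowed), 0)
  for (x in which(shadowed)) {
    z2 <- ph$truth$z[x, 1, 2]
    expect_true(all(ratio[x, 1, seq_len(z2 + 1L)] > 0.99))
  }
})

test_that("surface_error matches direct per-column computation", {
  ph <- generate_phantom(tiny_phantom_spec())
  expect_true(all(surface_error(ph$truth, ph$truth)$mae_vox == 0))

  shifted <- ph$truth
  shifted$z <- ph$truth$z + 2L
  err <- surface_error(surface_set(shifted$z), ph$truth, sz = 0.0026)
  expect_equal(err$mae_vox, rep(2, 11))
  expect_equal(err$rmse_vox, rep(2, 11))
  expect_equal(err$mae_um, rep(2 * 0.0026 * 1000, 11))

  # randomized case against a brute-force loop over columns
  set.seed(42)
  est <- ph$truth
  est$z <- est$z + array(sample(-1:3, length(est$z), TRUE), dim = dim(est$z))
  est$z <- pmax(est$z, 0L)
  for (k in 2:11) est$z[, , k] <- pmax(est$z[, , k], est$z[, , k - 1])
  err <- surface_error(surface_set(est$z), ph$truth)
  for (k in c(1L, 5L, 11L)) {
    acc <- 0; acc2 <- 0; n <- 0
    for (x in seq_len(dim(est$z)[1])) for (y in seq_len(dim(est$z)[2])) {
      d <- est$z[x, y, k] - ph$truth$z[x, y, k]
      acc <- acc + abs(d); acc2 <- acc2 + d^2; n <- n + 1
    }
    expect_equal(err$mae_vox[k], acc / n)
    expect_equal(err$rmse_vox[k], sqrt(acc2 / n))
  }
})
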