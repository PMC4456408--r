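test_that("the fovea is found at the apex of a paraboloid pit", {
  nx <- 40L; ny <- 30L
  sp <- c(6 / nx, 6 / ny, 0.0026)
  x0 <- 3.1; y0 <- 2.8
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  ilm <- outer(xs, ys, function(x, y)
    round(60 - 40 * ((x - x0)^2 + (y - y0)^2)))
  ctr <- find_fovea(ilm, sp, smooth_radius = 0L)
  expect_lt(abs(ctr[1] - x0), sp[1] / 2 + 1e-9)
  expect_lt(abs(ctr[2] - y0), sp[2] / 2 + 1e-9)
})

test_that("a flat ILM falls back to the search-window centroid", {
  sp <- c(0.2, 0.2, 0.0026)
  ilm <- matrix(17L, 30, 30)
  ctr <- find_fovea(ilm, sp, smooth_radius = 0L, search_radius_mm = 1.0)
  xs <- (seq_len(30) - 0.5) * 0.2
  inw <- xs[abs(xs - 3) <= 1.0]
  expect_equal(ctr, c(mean(inw), mean(inw)))
})

test_that("foveal localization tolerates speckle on the ILM", {
  hits <- 0L
  for (seed in 1:20) {
    spec <- phantom_spec(seed = seed)
    depths <- phantom_surface_depths(spec)
    ilm <- round(depths[, , 1] / spec$spacing[3])
    noisy <- ilm + matrix(sample(-3:3, length(ilm), TRUE), nrow(ilm))
    ctr <- find_fovea(noisy, spec$spacing)
    err_px <- abs(ctr - spec$pit_center_mm) / spec$spacing[1:2]
    if (all(err_px <= 2)) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("sector assignment matches the ETDRS geometry case by case", {
  sp <- c(0.05, 0.05, 0.0026)
  n <- 160L
  grid <- etdrs_grid(c(4, 4), "OD", "y0")
  lab <- assign_sectors(grid, c(n, n), sp)
  px <- function(x_mm, y_mm) lab[round(x_mm / 0.05 + 0.5), round(y_mm / 0.05 + 0.5)]
  expect_equal(px(4.025, 4.025), "Cen")          # at the center
  expect_equal(px(4.025, 3.025), "Sin")          # 1 mm toward superior (y0)
  expect_equal(px(4.025, 5.025), "Iin")
  expect_equal(px(4.025, 2.025), "Sout")
  expect_equal(px(2.025, 4.025), "Nout")         # OD: nasal is -x
  expect_equal(px(5.025, 4.025), "Tin")
  expect_true(is.na(px(7.025, 4.025)))           # r > 3 mm
  # laterality flips nasal/temporal only
  lab_os <- assign_sectors(etdrs_grid(c(4, 4), "OS", "y0"), c(n, n), sp)
  expect_equal(lab_os[round(2.025 / 0.05 + 0.5), round(4.025 / 0.05 + 0.5)], "Tout")
  expect_equal(lab_os[round(4.025 / 0.05 + 0.5), round(3.025 / 0.05 + 0.5)], "Sin")
})

test_that("the nine sectors exactly partition the 6-mm disc", {
  sp <- c(0.06, 0.08, 0.0026)
  dims <- c(120L, 90L)
  grid <- etdrs_grid(c(3.6, 3.6), "OD")
  lab <- assign_sectors(grid, dims, sp)
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- (seq_len(dims[2]) - 0.5) * sp[2]
  r <- sqrt(outer((xs - 3.6)^2, (ys - 3.6)^2, `+`))
  expect_true(all(is.na(lab[r > 3.0])))
  expect_true(all(!is.na(lab[r <= 3.0])))
  counts <- table(lab)
  expect_setequal(names(counts), SECTOR <- c("Cen", "Sin", "Nin", "Iin",
                                             "Tin", "Sout", "Nout", "Iout", "Tout"))
  expect_equal(sum(counts), sum(r <= 3.0))
})

test_that("sector areas approach the analytic ratios as pixels shrink", {
  sp <- c(0.01, 0.01, 0.0026)
  dims <- c(700L, 700L)
  lab <- assign_sectors(etdrs_grid(c(3.5, 3.5), "OD"), dims, sp)
  counts <- table(lab)
  cen <- counts[["Cen"]]
  inner <- sum(counts[c("Sin", "Nin", "Iin", "Tin")])
  outer_ <- sum(counts[c("Sout", "Nout", "Iout", "Tout")])
  expect_equal(inner / cen, 2 / 0.25, tolerance = 0.01)
  expect_equal(outer_ / cen, 6.75 / 0.25, tolerance = 0.01)
  # quadrants of a ring are equal up to discretization
  expect_equal(counts[["Sin"]] / counts[["Tin"]], 1, tolerance = 0.01)
})

test_that("sector means behave on constant, symmetric and random maps", {
  sp <- c(0.05, 0.05, 0.0026)
  dims <- c(160L, 160L)
  grid <- etdrs_grid(c(4, 4), "OD")
  lab <- assign_sectors(grid, dims, sp)

  tab <- sector_means(matrix(250, dims[1], dims[2]), lab)
  expect_true(all(abs(tab$mean_um - 250) < 1e-12))

  # radially symmetric map: the four inner quadrants agree
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  radial <- outer(xs, xs, function(x, y) 200 + 30 * sqrt((x - 4)^2 + (y - 4)^2))
  tab <- sector_means(radial, lab)
  inner4 <- tab$mean_um[tab$sector %in% c("Sin", "Nin", "Iin", "Tin")]
  expect_lt(diff(range(inner4)), 0.5)

  # Ave is the pixel-count-weighted mean of the nine sector means
  set.seed(9)
  rnd <- matrix(runif(prod(dims), 150, 350), dims[1], dims[2])
  tab <- sector_means(rnd, lab)
  nine <- tab[tab$sector != "Ave", ]
  expect_equal(tab$mean_um[tab$sector == "Ave"],
               sum(nine$mean_um * nine$n_pixels) / sum(nine$n_pixels))
})

test_that("sectors falling outside the footprint are flagged missing", {
  sp <- c(0.2, 0.2, 0.0026)
  lab <- assign_sectors(etdrs_grid(c(0.5, 0.5), "OD"), c(20L, 20L), sp)
  tab <- sector_means(matrix(100, 20, 20), lab)
  expect_true(any(tab$n_pixels == 0))
  expect_true(all(is.na(tab$mean_um[tab$n_pixels == 0])))
})
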