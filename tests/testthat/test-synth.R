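test_that("simulated pedigrees have the forced family structure", {
  ped <- simulate_pedigree(2, 1, 0, seed = 1)
  expect_equal(nrow(ped), 3L)
  off <- ped[ped$generation == "F1", ]
  expect_setequal(c(off$sire, off$dam), c("FND0001", "FND0002"))

  ped <- simulate_pedigree(2, 1, 3, seed = 1)
  chain <- ped[!is.na(ped$sire) & ped$sire == ped$dam, ]
  expect_equal(nrow(chain), 3L)          # F2, F3, F4 each selfed once
  expect_equal(chain$generation, c("F2", "F3", "F4"))
  expect_equal(attr(ped, "line_ids"), "L00001_F4")

  expect_identical(simulate_pedigree(8, 5, 2, seed = 42),
                   simulate_pedigree(8, 5, 2, seed = 42))
  expect_error(simulate_pedigree(1, 1, 0, seed = 1), "n_founders")
  expect_error(simulate_pedigree(4, 2, -1, seed = 1), "selfing")
})

test_that("breeding values have the architecture's variance and correlation", {
  # zero-heritability trait is exactly zero
  arch0 <- genetic_architecture(h2 = c(0, 0.3, 0.3))
  ped <- simulate_pedigree(10, 50, 1, seed = 2)
  bv0 <- simulate_breeding_values(ped, arch0, seed = 3)
  expect_equal(unname(bv0[, "yield"]), rep(0, nrow(bv0)))

  # unrelated founders: sample variance near h2 * sigma_p^2
  founders <- as_pedigree(data.frame(id = sprintf("F%05d", 1:10000),
                                     sire = NA, dam = NA))
  arch <- genetic_architecture(h2 = c(0.25, 0.3, 0.3),
                               pheno_sd = c(200, 0.05, 6))
  bv <- simulate_breeding_values(founders, arch, seed = 4)
  expect_lt(abs(var(bv[, "yield"]) / (0.25 * 200^2) - 1), 0.05)

  # perfect genetic correlation carries through the sampler
  gc1 <- matrix(1, 2, 2)
  arch1 <- genetic_architecture(trait_names = c("t1", "t2"),
                                h2 = c(0.5, 0.5), genetic_corr = gc1,
                                pheno_sd = c(1, 10), trait_means = c(0, 0))
  f2 <- as_pedigree(data.frame(id = sprintf("F%04d", 1:5000),
                               sire = NA, dam = NA))
  bv1 <- simulate_breeding_values(f2, arch1, seed = 5)
  expect_gt(cor(bv1[, 1], bv1[, 2]), 0.99)

  # gene-drop and Cholesky samplers agree in law: matched variance of
  # line-level values on a small pedigree
  ped2 <- simulate_pedigree(6, 40, 2, seed = 6)
  b_gd <- simulate_breeding_values(ped2, arch, seed = 7)
  b_ch <- simulate_breeding_values(ped2, arch, seed = 7,
                                   method = "cholesky")
  lines <- attr(ped2, "line_ids")
  expect_equal(dim(b_gd), dim(b_ch))
  A <- build_a_matrix(ped2)
  # empirical covariance across traits scaled by theory stays of order 1
  expect_lt(abs(var(b_gd[lines, "yield"]) /
                  (0.25 * 200^2 * mean(diag(A)[lines])) - 1), 0.6)

  expect_error(genetic_architecture(genetic_corr = matrix(c(1, 2, 2, 1),
                                                          2, 2),
                                    trait_names = c("a", "b"),
                                    h2 = c(0.5, 0.5), pheno_sd = c(1, 1),
                                    trait_means = c(0, 0)),
               "positive semidefinite")
})

test_that("field layouts assign every cell once with replicated checks", {
  lay <- field_layout(sprintf("L%04d", 1:500), c("CK1", "CK2"),
                      n_cols = 25, check_spacing = 12)
  plots <- lay$plots
  expect_equal(nrow(plots), lay$n_rows * lay$n_cols)
  expect_false(anyDuplicated(plots[, c("field_row", "field_col")]) > 0)
  tab <- table(plots$line_id)
  expect_true(all(tab[c("CK1", "CK2")] >= 2))
  expect_true(all(tab[setdiff(names(tab), c("CK1", "CK2"))] == 1))
})

test_that("trial phenotypes decompose into mean, BV, spatial and residual", {
  ped <- simulate_pedigree(8, 60, 1, seed = 8)
  arch <- genetic_architecture(h2 = c(1, 0.5, 0.5))
  bv <- simulate_breeding_values(ped, arch, seed = 9)
  lay <- field_layout(attr(ped, "line_ids"), c("FND0001", "FND0002"),
                      n_cols = 8)
  # noise-free limit: h2 = 1, no spatial, zero residual floor
  ph <- simulate_trial(lay, bv, arch, spatial_sd = 0, seed = 10,
                       residual_floor = 0)
  expect_equal(ph$yield - arch$trait_means["yield"],
               unname(bv[ph$line_id, "yield"]), ignore_attr = TRUE)

  expect_identical(simulate_trial(lay, bv, arch, seed = 11),
                   simulate_trial(lay, bv, arch, seed = 11))
  expect_error(simulate_trial(lay, bv, arch,
                              spatial_sd = c(700, 0.001, 1), seed = 1),
               "exceeds")
})

test_that("spatial surfaces induce positive neighbor correlation", {
  ped <- simulate_pedigree(8, 400, 0, seed = 12)
  arch <- genetic_architecture(h2 = c(0.2, 0.2, 0.2))
  bv <- simulate_breeding_values(ped, arch, seed = 13)
  lay <- field_layout(attr(ped, "line_ids"), c("FND0001", "FND0002"),
                      n_cols = 20)
  rhos <- vapply(1:20, function(r) {
    ph <- simulate_trial(lay, bv, arch,
                         spatial_sd = c(400, 0.02, 3), seed = 100 + r)
    build_spatial_R(ph, "yield")$neighbor_rho
  }, numeric(1))
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.9)
})

test_that("growth curves are logistic and monotone over the schedule", {
  expect_equal(growth_curve(45, 0.8, rate = 0.2, midpoint = 45), 0.4)
  expect_equal(growth_curve(60, 0.8, rate = 50, midpoint = 30), 0.8,
               tolerance = 1e-12)
  cv <- growth_curve(sampling_dates(), 0.9)
  expect_true(all(diff(cv) > 0))
  expect_error(growth_curve(30, 0), "cover_max")
  # schedule rescaling hits the requested ACC
  tc <- true_cover_schedule(c(0.1, 0.25), sampling_dates())
  expect_equal(unname(rowMeans(tc)), c(0.1, 0.25))
})

test_that("rendered images honor the requested cover and ground truth", {
  for (cv in c(0, 0.4, 1)) {
    img <- simulate_plot_image(cv, image_px = c(64, 96), seed = 20)
    expect_equal(mean(img$mask), cv, tolerance = 0.001)
    expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  }
  # no green-dominant pixels on a bare-soil image
  img0 <- simulate_plot_image(0, image_px = c(64, 96), seed = 21)
  px <- img0$pixels
  expect_true(all(px[, , 1] >= px[, , 2]))
  # full canopy: mask saturates
  img1 <- simulate_plot_image(1, image_px = c(32, 32), seed = 22)
  expect_true(all(img1$mask))
  # replicates share the target cover but differ in pixels
  imgs <- simulate_plot_images(matrix(0.4, 1, 1, dimnames = list("P1", NULL)),
                               dates = 30, image_px = c(48, 48),
                               n_replicate_images = 2, seed = 23)
  expect_equal(mean(imgs[[1]]$mask), mean(imgs[[2]]$mask),
               tolerance = 0.001)
  expect_false(identical(imgs[[1]]$pixels, imgs[[2]]$pixels))
  expect_error(simulate_plot_image(1.2), "cover")
})

test_that("image PNG round trip preserves pixels and manifest indexing", {
  dir <- tempfile(); dir.create(dir)
  covers <- matrix(c(0.2, 0.5), 1, 2, dimnames = list("P9", NULL))
  man <- simulate_plot_images(covers, dates = c(15, 29),
                              image_px = c(24, 32),
                              n_replicate_images = 1, seed = 30, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  img <- read_plot_image(file.path(dir, man$path[1]),
                         plot_id = man$plot_id[1], dap = man$dap[1])
  expect_equal(dim(img$pixels), c(24L, 32L, 3L))
  mask <- png::readPNG(file.path(dir, man$mask_path[1]))
  expect_equal(mean(mask > 0.5), man$true_cover[1], tolerance = 0.01)
})
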