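test_that("gibbs posterior mean matches the direct MME solution", {
  d <- make_pr_dataset(n_crosses = 60, selfing = 0, seed = 21)
  sa2 <- 0.3 * 600^2; se2 <- 0.7 * 600^2
  fit <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 30000,
                      burnin = 1000, thin = 20,
                      fix_variances = c(sigma_a2 = sa2, sigma_e2 = se2),
                      seed = 22)
  mme <- oracle_mme(d$pheno$yield, d$pheno$line_id, d$ainv, sa2, se2)
  g <- blup(fit, all = TRUE)
  expect_gt(cor(g, mme$g[names(g)]), 0.999)
  expect_lt(sqrt(mean((g - mme$g[names(g)])^2)) / sd(mme$g), 0.05)
})

test_that("chains are reproducible by seed", {
  d <- make_pr_dataset(n_crosses = 40, selfing = 0, seed = 23)
  f1 <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 300, burnin = 50,
                     seed = 77)
  f2 <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 300, burnin = 50,
                     seed = 77)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$blup, f2$blup)
  f3 <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 300, burnin = 50,
                     seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("null simulation yields near-zero heritability", {
  # no additive signal on a replicated design: within-line replication
  # pins the residual variance, so sigma_a2 must collapse toward zero
  ped <- as_pedigree(data.frame(id = sprintf("L%04d", 1:2500),
                                sire = NA, dam = NA))
  set.seed(31)
  ph <- data.frame(line_id = rep(ped$id, each = 4),
                   yield = rnorm(10000, 100, 10))
  fit <- animal_model(yield ~ 1, ph, a_inverse(ped), niter = 6000,
                      burnin = 1000, seed = 32)
  expect_lt(fit$h2, 0.05)
})

test_that("heritability is the posterior mean of the per-draw ratio", {
  d <- make_pr_dataset(n_crosses = 40, selfing = 0, seed = 33)
  fit <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 500, burnin = 100,
                      seed = 34)
  expect_equal(heritability(fit),
               mean(fit$draws$sigma_a2 /
                      (fit$draws$sigma_a2 + fit$draws$sigma_e2)))
  expect_gte(heritability(fit), 0)
  expect_lte(heritability(fit), 1)
  # symmetric draws give exactly one half
  mock <- fit
  mock$draws <- data.frame(sigma_a2 = c(1, 2), sigma_e2 = c(1, 2))
  mock$draws$h2 <- with(mock$draws, sigma_a2 / (sigma_a2 + sigma_e2))
  expect_equal(heritability(mock), 0.5)
})

test_that("BLUPs shrink phenotypic deviations on unreplicated data", {
  # unrelated lines with known variances: the BLUP is exactly the
  # regressed phenotypic deviation, so it can never exceed it
  ped <- as_pedigree(data.frame(id = sprintf("L%03d", 1:300),
                                sire = NA, dam = NA))
  set.seed(35)
  ph <- data.frame(line_id = ped$id, yield = rnorm(300, 50, 10))
  fit <- animal_model(yield ~ 1, ph, a_inverse(ped), niter = 4000,
                      burnin = 500,
                      fix_variances = c(sigma_a2 = 30, sigma_e2 = 70),
                      seed = 36)
  dev <- ph$yield - mean(ph$yield)
  g <- blup(fit)[ph$line_id]
  tol <- 0.05 * sd(ph$yield)
  expect_true(all(abs(g) <= abs(dev) + tol))
  # near-zero mean of the genetic effects
  expect_lt(abs(mean(blup(fit, all = TRUE))),
            0.05 * sd(blup(fit, all = TRUE)))
})

test_that("split R-hat flags convergence on the reference scenario", {
  d <- make_pr_dataset(n_crosses = 120, selfing = 1, seed = 37)
  fit <- animal_model(yield ~ 1, d$pheno, d$ainv, seed = 38)  # defaults
  expect_lt(fit$diagnostics[["rhat_sigma_a2"]], 1.1)
  expect_lt(fit$diagnostics[["rhat_sigma_e2"]], 1.1)
})

test_that("covariate fits behave like the plain model when uninformative", {
  d <- make_pr_dataset(n_crosses = 150, selfing = 0, seed = 41)
  set.seed(42)
  d$pheno$noise_cov <- rnorm(nrow(d$pheno))
  plain <- animal_model(yield ~ 1, d$pheno, d$ainv, niter = 2000,
                        burnin = 400, seed = 43)
  withc <- fit_trait_with_covariate(d$pheno, d$ainv, "yield", "noise_cov",
                                    niter = 2000, burnin = 400, seed = 43)
  beta <- colMeans(withc$coef_draws)[["noise_cov"]]
  beta_sd <- apply(withc$coef_draws, 2, sd)[["noise_cov"]]
  expect_lt(abs(beta), 2 * beta_sd)
  expect_gt(cor(blup(plain), blup(withc)[names(blup(plain))]), 0.98)

  # smoothed copy of the response soaks up residual variance
  d$pheno$smooth <- fitted(stats::loess(yield ~ field_row + field_col,
                                        data = d$pheno, span = 0.3))
  withs <- animal_model(yield ~ smooth, d$pheno, d$ainv, niter = 2000,
                        burnin = 400, seed = 44)
  expect_lt(withs$sigma_e2, plain$sigma_e2)
})

test_that("ACC-adjusted yield BLUPs correlate negatively with ACC BLUPs", {
  # a highly heritable canopy trait genetically correlated with yield,
  # plus a shared field trend: conditioning yield on ACC then removes the
  # common signal and flips the BLUP correlation negative
  cors <- vapply(1:3, function(r) {
    ped <- simulate_pedigree(20, 400, 2, seed = 45 + r)
    arch <- genetic_architecture(h2 = c(0.23, 0.6, 0.36))
    bv <- simulate_breeding_values(ped, arch, seed = 146 + r)
    lay <- field_layout(attr(ped, "line_ids"), c("FND0001", "FND0002"),
                        n_cols = 20)
    ph <- simulate_trial(lay, bv, arch, spatial_sd = c(420, 0.028, 2),
                         seed = 247 + r)
    ainv <- a_inverse(ped)
    f_acc <- animal_model(acc ~ 1, ph, ainv, niter = 2000, burnin = 400,
                          seed = 48 + r)
    f_ya <- animal_model(yield ~ acc, ph, ainv, niter = 2000, burnin = 400,
                         seed = 49 + r)
    blup_correlations(list(ACC = f_acc,
                           `Yield|ACC` = f_ya))["ACC", "Yield|ACC"]
  }, numeric(1))
  expect_lt(mean(cors), 0)
})

test_that("blup correlations match a two-pass covariance oracle", {
  set.seed(51)
  a <- setNames(rnorm(50), sprintf("L%02d", 1:50))
  b <- setNames(rnorm(50), sprintf("L%02d", 1:50))
  m <- blup_correlations(list(A = a, B = b, nA = -a))
  expect_equal(m["A", "A"], 1)
  expect_equal(m["A", "nA"], -1)
  two_pass <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(m["A", "B"], two_pass, tolerance = 1e-12)
})

test_that("spatial R reflects the simulated field structure", {
  # independent field: neighbor correlation near zero
  ped <- simulate_pedigree(10, 900, 0, seed = 52)
  arch <- genetic_architecture(h2 = c(0.0001, 0.3, 0.3))
  bv <- simulate_breeding_values(ped, arch, seed = 53)
  lay <- field_layout(attr(ped, "line_ids"), c("FND0001", "FND0002"),
                      n_cols = 30)
  ph0 <- simulate_trial(lay, bv, arch, spatial_sd = 0, seed = 54)
  sr0 <- build_spatial_R(ph0, "yield")
  expect_lt(abs(sr0$neighbor_rho), 0.08)

  # strong trend: clearly positive
  ph1 <- simulate_trial(lay, bv, arch, spatial_sd = c(550, 0.04, 5),
                        seed = 55)
  sr1 <- build_spatial_R(ph1, "yield")
  expect_gt(sr1$neighbor_rho, 0.3)

  # definiteness always holds after shrinkage
  ev <- min(eigen(as.matrix(sr1$R), symmetric = TRUE,
                  only.values = TRUE)$values)
  expect_gte(ev, 1e-6 - 1e-10)

  # correlated-residual fit runs and stays deterministic
  sub <- ph1[ph1$field_row <= 6, ]
  srs <- build_spatial_R(sub, "yield")
  fa <- animal_model(yield ~ 1, sub, a_inverse(ped), R = srs,
                     niter = 300, burnin = 50, seed = 56)
  fb <- animal_model(yield ~ 1, sub, a_inverse(ped), R = srs,
                     niter = 300, burnin = 50, seed = 56)
  expect_identical(fa$draws, fb$draws)
})
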