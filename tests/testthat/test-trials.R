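test_that("REML fit agrees with lme4 on a two-location trial", {
  skip_if_not_installed("lme4")
  set.seed(71)
  g <- setNames(rnorm(60), sprintf("G%03d", 1:60))
  dat <- simulate_yield_trial(names(g), g, mu = 10, n_loc = 2, n_rep = 2,
                              block_size = 10,
                              vc = list(loc = 0.5, rep = 0.2, block = 0.1,
                                        gxl = 0.3, e = 1), seed = 72)
  fit <- trial_model(yield ~ 1, dat)
  lf <- lme4::lmer(
    yield ~ (1 | line_id) + (1 | location) + (1 | rep:location) +
      (1 | block:rep:location) + (1 | line_id:location),
    data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(fit$varcomp[["genotype"]], ref[["line_id"]],
               tolerance = 1e-3)
  expect_equal(fit$varcomp[["residual"]], ref[["Residual"]],
               tolerance = 1e-3)
  expect_equal(fit$varcomp[["gxl"]], ref[["line_id:location"]],
               tolerance = 5e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  # genotype BLUPs agree too
  re <- lme4::ranef(lf)$line_id
  expect_gt(cor(fit$genotype_eff[rownames(re)], re[[1]]), 0.9999)
})

test_that("balanced one-way fit matches closed-form ANOVA estimators", {
  set.seed(73)
  k <- 30; r <- 4
  g <- rnorm(k, 0, 2)
  y <- rep(g, each = r) + rnorm(k * r, 0, 1)
  dat <- data.frame(line_id = rep(sprintf("g%02d", 1:k), each = r),
                    location = "L1", rep = 1L, yield = y)
  fit <- suppressWarnings(trial_model(yield ~ 1, dat))
  a <- anova(stats::lm(y ~ factor(dat$line_id)))
  expect_equal(fit$varcomp[["genotype"]], (a[1, 3] - a[2, 3]) / r,
               tolerance = 1e-6)
  expect_equal(fit$varcomp[["residual"]], a[2, 3], tolerance = 1e-6)
})

test_that("restricted likelihood at the optimum beats random admissible points", {
  set.seed(74)
  g <- setNames(rnorm(40), sprintf("G%02d", 1:40))
  dat <- simulate_yield_trial(names(g), g, mu = 5, n_loc = 2, n_rep = 2,
                              block_size = 8, seed = 75)
  fit <- trial_model(yield ~ 1, dat)
  refit_at <- function(gam) {
    # evaluate the profiled restricted log-likelihood at fixed ratios
    n <- nrow(dat)
    Zs <- list(
      stats::model.matrix(~ 0 + factor(dat$line_id)),
      stats::model.matrix(~ 0 + factor(dat$location)),
      stats::model.matrix(~ 0 + factor(paste(dat$location, dat$rep))),
      stats::model.matrix(~ 0 + factor(paste(dat$location, dat$rep,
                                             dat$block))),
      stats::model.matrix(~ 0 + factor(paste(dat$line_id, dat$location))))
    V <- diag(n)
    for (j in seq_along(Zs)) V <- V + gam[j] * tcrossprod(Zs[[j]])
    ch <- chol(V)
    X <- matrix(1, n, 1)
    W <- backsolve(ch, cbind(dat$yield, X), transpose = TRUE)
    xtvx <- crossprod(W[, 2]); xtvy <- crossprod(W[, 2], W[, 1])
    beta <- xtvy / xtvx
    q <- sum(W[, 1]^2) - beta * xtvy
    se2 <- q / (n - 1)
    -0.5 * ((n - 1) * log(se2) + 2 * sum(log(diag(ch))) + log(xtvx) +
              (n - 1) * (1 + log(2 * pi)))
  }
  for (r in 1:20) {
    gam <- exp(runif(5, log(0.01), log(5)))
    expect_gte(fit$logLik, as.numeric(refit_at(gam)) - 1e-6)
  }
})

test_that("null genotype signal gives a vanishing genetic component", {
  set.seed(76)
  g0 <- setNames(rep(0, 100), sprintf("G%03d", 1:100))
  dat <- simulate_yield_trial(names(g0), g0, mu = 0, n_loc = 2, n_rep = 3,
                              vc = list(loc = 0.3, rep = 0.1, block = 0.05,
                                        gxl = 0, e = 1), seed = 77)
  fit <- trial_model(yield ~ 1, dat)
  expect_lt(fit$varcomp[["genotype"]], 0.05 * fit$varcomp[["residual"]])
})

test_that("adjusted means are mu + g with the expected equivariances", {
  set.seed(78)
  g <- setNames(rnorm(50, 0, 2), sprintf("G%02d", 1:50))
  dat <- simulate_yield_trial(names(g), g, mu = 100, n_loc = 2, n_rep = 2,
                              seed = 79)
  fit <- trial_model(yield ~ 1, dat)
  am <- adjusted_means(fit)
  expect_equal(am$adjusted, unname(fit$mu + fit$genotype_eff[am$line_id]))
  # shift equivariance
  dat2 <- dat; dat2$yield <- dat2$yield + 500
  am2 <- adjusted_means(trial_model(yield ~ 1, dat2))
  expect_equal(am2$adjusted, am$adjusted + 500, tolerance = 1e-6)
  # shrinkage of random-genotype means vs raw line means
  raw <- tapply(dat$yield, dat$line_id, mean)
  expect_lt(var(am$adjusted), var(raw[am$line_id]))
  # near-zero mean genetic effects
  expect_lt(abs(mean(fit$genotype_eff)), 0.05 * sd(fit$genotype_eff))

  # degenerate single-genotype design: adjusted equals the raw mean
  d1 <- data.frame(line_id = "G1", location = "L1", rep = 1:6,
                   yield = rnorm(6, 3, 1))
  f1 <- suppressWarnings(trial_model(yield ~ 1, d1))
  expect_equal(adjusted_means(f1)$adjusted, mean(d1$yield),
               tolerance = 1e-6)
})

test_that("covariate adjustment for maturity behaves as constructed", {
  set.seed(81)
  g <- setNames(rnorm(60, 0, 2), sprintf("G%02d", 1:60))
  r8 <- setNames(rnorm(60, 105, 4), names(g))
  # null covariate: means essentially unchanged
  dat0 <- simulate_yield_trial(names(g), g, mu = 50, n_loc = 2, n_rep = 2,
                               r8_values = r8, r8_slope = 0, seed = 82)
  m_plain <- adjusted_means(trial_model(yield ~ 1, dat0))
  m_adj <- yield_given_r8(dat0)$means
  expect_gt(cor(m_plain$adjusted, m_adj$adjusted), 0.98)

  # response a pure linear function of the measured maturity: the
  # covariate absorbs everything and genotype means collapse to mu
  dat1 <- dat0
  dat1$r8 <- r8[dat1$line_id]
  dat1$yield <- 50 + 3 * (dat1$r8 - mean(r8))
  m1 <- suppressWarnings(yield_given_r8(dat1)$means)
  expect_lt(sd(m1$adjusted), 0.05 * sd(3 * r8))
  expect_equal(mean(m1$adjusted), 50, tolerance = 0.1)

  # slope recovery within 10%
  dat2 <- simulate_yield_trial(names(g), g, mu = 50, n_loc = 2, n_rep = 2,
                               vc = list(loc = 0.5, rep = 0.2, block = 0.1,
                                         gxl = 0.1, e = 1),
                               r8_values = r8, r8_slope = 2, seed = 83)
  f2 <- yield_given_r8(dat2)$fit
  expect_equal(unname(f2$beta[["r8"]]), 2, tolerance = 0.2)
})

test_that("fixed- and random-genotype fits rank genotypes alike", {
  set.seed(84)
  g <- setNames(rnorm(60, 0, 5), sprintf("G%02d", 1:60))  # high h2
  dat <- simulate_yield_trial(names(g), g, mu = 20, n_loc = 2, n_rep = 2,
                              vc = list(loc = 0.2, rep = 0.1, block = 0.05,
                                        gxl = 0.1, e = 1), seed = 85)
  fr <- trial_model(yield ~ 1, dat, genotype = "random")
  ff <- trial_model(yield ~ 1, dat, genotype = "fixed")
  common <- names(fr$genotype_eff)
  expect_gt(cor(rank(fr$genotype_eff[common]), rank(ff$genotype_eff[common]),
                method = "spearman"), 0.95)
  # both track the true values
  expect_gt(cor(fr$genotype_eff[names(g)], g), 0.9)
})

test_that("welch comparisons match the textbook formula and edge cases", {
  set.seed(86)
  vals <- setNames(c(rnorm(25, 10, 1), rnorm(25, 12, 2)),
                   sprintf("L%02d", 1:50))
  memb <- list(A = names(vals)[1:25], B = names(vals)[26:50])
  cmp <- compare_categories(vals, memb)
  o <- oracle_welch(vals[1:25], vals[26:50])
  expect_equal(cmp$t, o$t, tolerance = 1e-12)
  expect_equal(cmp$df, o$df, tolerance = 1e-12)
  expect_equal(cmp$p, o$p, tolerance = 1e-12)

  # identical samples: t = 0, p = 1, ns
  same <- compare_categories(vals, list(A = names(vals)[1:25],
                                        B = names(vals)[1:25]))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")

  # clear separation is detected with the right stars
  det <- 0
  for (r in 1:40) {
    x <- setNames(c(rnorm(50, 0, 1), rnorm(50, 2, 1)),
                  sprintf("M%03d", 1:100))
    cc <- compare_categories(x, list(lo = names(x)[1:50],
                                     hi = names(x)[51:100]))
    det <- det + (cc$p < 0.001)
  }
  expect_gte(det / 40, 0.95)
  expect_equal(p_stars_vec <- canopysel:::p_stars(c(0.2, 0.04, 0.008,
                                                    5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("top-rank attribution reproduces a constructed fixture", {
  vals <- c(L1 = 10, L2 = 9, L3 = 8, L4 = 7)
  out <- combine_categories(list(Yield = c("L1", "L3"),
                                 ACC = c("L2", "L3"),
                                 `Yield|ACC` = c("L3")))
  at <- top_rank_attribution(vals, out, k = 3)
  expect_equal(at$line_id, c("L1", "L2", "L3"))
  expect_equal(at$categories,
               c("Yield", "ACC", "Yield+ACC+Yield|ACC"))
  s <- attr(at, "summary")
  expect_equal(unname(s), c(1L, 1L, 1L))
  expect_equal(sum(s), 3L)

  # every line in all categories carries all labels; partition always sums
  out2 <- combine_categories(list(A = names(vals), B = names(vals)))
  at2 <- top_rank_attribution(vals, out2, k = 4, yield_category = "A")
  expect_true(all(at2$categories == "A+B"))
  expect_equal(sum(attr(at2, "summary")), 4L)
})

test_that("equal-heritability, perfectly correlated traits give no category differences", {
  # with genetic correlation 1 and equal heritabilities, the two selection
  # routes pick nearly the same material, so adjusted means cannot differ
  set.seed(88)
  n_sig <- 0; n_rep <- 8
  for (r in 1:n_rep) {
    n <- 400
    ids <- sprintf("L%04d", 1:n)
    g <- rnorm(n, 0, 1)                      # shared genetic value
    y1 <- g + rnorm(n, 0, sqrt(1 / 0.3 - 1)) # trait A phenotype, h2 = 0.3
    y2 <- g + rnorm(n, 0, sqrt(1 / 0.3 - 1)) # trait B phenotype, h2 = 0.3
    sel <- list(Yield = ids[order(-y1)][1:36],
                ACC = ids[order(-y2)][1:36])
    out <- combine_categories(sel)
    gv <- setNames(5 * g, ids)[out$union_selected]
    dat <- simulate_yield_trial(out$union_selected, gv, mu = 100,
                                n_loc = 2, n_rep = 2,
                                vc = list(loc = 1, rep = 0.5, block = 0.2,
                                          gxl = 0.5, e = 25),
                                seed = 880 + r)
    cmp <- compare_categories(adjusted_means(trial_model(yield ~ 1, dat)),
                              out)
    n_sig <- n_sig + any(cmp$p <= 0.05)
  }
  expect_lte(n_sig, 1)   # no-significant-difference in >= 90% of replicates
})
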