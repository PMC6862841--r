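#' Default configuration for a synthetic selection experiment
#'
#' Scenario parameters for [run_selection_experiment()]: population sizes,
#' genetic architecture, imaging settings, animal-model chain settings,
#' selection fractions and yield-trial design. Values are deliberately
#' smaller than a full breeding program so a complete run stays
#' interactive; all of them can be overridden via the `config` argument or
#' a YAML file.
#'
#' @return A nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 20150525L,
    pedigree = list(n_founders = 30L, n_crosses = 150L,
                    selfing_generations = 3L),
    architecture = list(
      trait_names = c("yield", "acc", "r8"),
      h2 = c(0.23, 0.06, 0.36),
      pheno_sd = c(600, 0.05, 6),
      trait_means = c(3500, 0.25, 105),
      genetic_corr_acc_yield = 0.87,
      genetic_corr_yield_r8 = 0.3,
      genetic_corr_acc_r8 = 0.0),
    layout = list(n_cols = 20L, check_spacing = 15L, n_checks = 2L),
    trial = list(spatial_sd = c(120, 0.005, 0.5)),
    imaging = list(dates = "early", image_px = c(24L, 48L),
                   n_replicate_images = 2L, n_bins = 256L,
                   guard_cutoff = 0.1),
    model = list(niter = 1500L, burnin = 300L, thin = 3L,
                 spatial = "correlation"),
    selection = list(fraction = 0.09),
    yield_trial = list(n_loc = 2L, n_rep = 2L, block_size = 8L,
                       vc = list(loc = 10000, rep = 4000, block = 2000,
                                 gxl = 6000, e = 90000),
                       top_k = 10L)
  )
}

#' Read a YAML scenario configuration
#'
#' Reads a YAML file and merges it over [default_config()] (shallow merge
#' per section).
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (nm in names(user[[section]])) {
        cfg[[section]][[nm]] <- user[[section]][[nm]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

config_architecture <- function(cfg) {
  a <- cfg$architecture
  gc <- diag(3)
  dimnames(gc) <- list(a$trait_names, a$trait_names)
  gc["yield", "acc"] <- gc["acc", "yield"] <- a$genetic_corr_acc_yield
  gc["yield", "r8"] <- gc["r8", "yield"] <- a$genetic_corr_yield_r8
  gc["acc", "r8"] <- gc["r8", "acc"] <- a$genetic_corr_acc_r8
  genetic_architecture(trait_names = a$trait_names, h2 = a$h2,
                       genetic_corr = gc, pheno_sd = a$pheno_sd,
                       trait_means = a$trait_means)
}

#' Run a complete synthetic selection experiment
#'
#' Executes every stage of the pipeline on generated data with known
#' ground truth: (1) pedigree, breeding values and a progeny-row field
#' trial; (2) plot imagery for each sampling date and extraction of
#' average canopy coverage via Excess Green + Otsu; (3) Gibbs animal-model
#' fits for yield, ACC, yield-given-ACC and R8, with BLUP correlations and
#' heritabilities; (4) truncation selection per category with overlap
#' accounting and an early/late maturity split against a check; (5) a
#' simulated multi-location preliminary yield trial of the selected lines
#' fitted by REML, adjusted means (raw and maturity-adjusted), Welch
#' comparisons of the selection categories, and top-rank attribution in an
#' advanced-trial (fixed genotype) fit.
#'
#' All randomness derives from `config$seed`, so rerunning with the same
#' configuration reproduces every output file byte for byte.
#'
#' @param config Configuration list (see [default_config()]) or a path to
#'   a YAML file.
#' @param outdir Optional directory; when given, every stage writes its
#'   output tables (CSV) and a `runlog.yaml` there.
#' @return Invisibly, a list with all intermediate and final objects.
#' @export
run_selection_experiment <- function(config = default_config(),
                                     outdir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  seed <- as.integer(cfg$seed)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  wr <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE,
                       quote = FALSE)
    }
  }

  ## 1. population and field trial -------------------------------------
  arch <- config_architecture(cfg)
  ped <- simulate_pedigree(cfg$pedigree$n_founders, cfg$pedigree$n_crosses,
                           cfg$pedigree$selfing_generations, seed = seed)
  line_ids <- attr(ped, "line_ids")
  bv <- simulate_breeding_values(ped, arch, seed = seed + 1L)
  check_ids <- ped$id[is.na(ped$sire)][seq_len(cfg$layout$n_checks)]
  lay <- field_layout(line_ids, check_ids, n_cols = cfg$layout$n_cols,
                      check_spacing = cfg$layout$check_spacing)
  pheno <- simulate_trial(lay, bv, arch, spatial_sd = cfg$trial$spatial_sd,
                          seed = seed + 2L)
  wr(as.data.frame(ped), "pedigree.csv")

  ## 2. imagery and ACC extraction --------------------------------------
  dates <- sampling_dates(cfg$imaging$dates)
  acc_target <- pmin(pmax(pheno$acc, 0), 0.95 * mean(
    growth_curve(dates, 1)))
  covers <- true_cover_schedule(acc_target, dates)
  rownames(covers) <- pheno$plot_id
  imgs <- simulate_plot_images(covers, dates,
                               image_px = cfg$imaging$image_px,
                               n_replicate_images =
                                 cfg$imaging$n_replicate_images,
                               seed = seed + 3L)
  cov_tab <- coverage_table(imgs, n_bins = cfg$imaging$n_bins,
                            guard_cutoff = cfg$imaging$guard_cutoff)
  acc_tab <- acc_table(cov_tab)
  pheno$acc_measured <- acc_tab$acc[match(pheno$plot_id, acc_tab$plot_id)]
  wr(cov_tab, "coverage.csv")
  wr(merge(acc_tab, pheno[, c("plot_id", "line_id")], by = "plot_id"),
     "acc.csv")
  wr(pheno[, c("plot_id", "line_id", "is_check", "field_row", "field_col",
               "yield", "acc_measured", "r8")], "phenotypes.csv")

  ## 3. animal-model evaluation -----------------------------------------
  ainv <- a_inverse(ped)
  mchain <- cfg$model
  fit1 <- function(f, s) {
    animal_model(f, pheno, ainv, spatial = mchain$spatial,
                 niter = mchain$niter, burnin = mchain$burnin,
                 thin = mchain$thin, seed = s)
  }
  fits <- list(
    Yield = fit1(yield ~ 1, seed + 10L),
    ACC = fit1(acc_measured ~ 1, seed + 11L),
    `Yield|ACC` = fit1(yield ~ acc_measured, seed + 12L),
    R8 = fit1(r8 ~ 1, seed + 13L))
  blup_cor <- blup_correlations(fits)
  varcomp <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(trait = nm, sigma_a2 = f$sigma_a2, sigma_e2 = f$sigma_e2,
               h2 = f$h2, rhat_sigma_a2 = f$diagnostics[["rhat_sigma_a2"]],
               stringsAsFactors = FALSE)
  }))
  blup_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    b <- blup(fits[[nm]])
    b <- b[line_ids]
    data.frame(line_id = names(b), trait = nm, blup = as.numeric(b),
               rank = rank(-b, ties.method = "min"),
               stringsAsFactors = FALSE)
  }))
  wr(varcomp, "varcomp.csv")
  wr(blup_tab, "blups.csv")
  wr(data.frame(trait = rownames(blup_cor), round(blup_cor, 4)),
     "blup_correlations.csv")

  ## 4. selection --------------------------------------------------------
  frac <- cfg$selection$fraction
  sel <- lapply(fits[c("Yield", "ACC", "Yield|ACC")], function(f)
    select_top(blup(f)[line_ids], frac))
  outcome <- combine_categories(sel)
  r8_pred <- predict(fits$R8, lines = c(line_ids, check_ids))
  check_r8 <- r8_pred[[check_ids[1]]]
  el <- split_early_late(outcome$union_selected, r8_pred, check_r8)
  memb <- outcome$membership
  memb$maturity <- ifelse(memb$line_id %in% el$early, "early", "late")
  wr(memb, "selection.csv")
  wr(data.frame(combination = names(outcome$overlap_counts),
                n = as.integer(outcome$overlap_counts)), "overlap.csv")

  ## 5. yield trials of the selected lines -------------------------------
  yt <- cfg$yield_trial
  trial_results <- list()
  comparisons <- list()
  attributions <- list()
  for (grp in c("early", "late")) {
    ids <- el[[grp]]
    if (length(ids) < 4L) next
    gvals <- bv[ids, "yield"]
    r8vals <- arch$trait_means["r8"] + bv[ids, "r8"]
    dat <- simulate_yield_trial(ids, gvals, mu = arch$trait_means["yield"],
                                n_loc = yt$n_loc, n_rep = yt$n_rep,
                                block_size = yt$block_size, vc = yt$vc,
                                r8_values = r8vals, r8_slope = 0,
                                seed = seed + 20L +
                                  (grp == "late"))
    fit_p <- trial_model(yield ~ 1, dat, genotype = "random")
    am <- adjusted_means(fit_p)
    adj_r8 <- yield_given_r8(dat, genotype = "random")
    cmp <- tryCatch(compare_categories(am, outcome),
                    error = function(e) NULL)
    fit_a <- trial_model(yield ~ 1, dat, genotype = "fixed")
    attr_tab <- top_rank_attribution(adjusted_means(fit_a), outcome,
                                     k = yt$top_k)
    trial_results[[grp]] <- list(pyt = fit_p, means = am,
                                 means_given_r8 = adj_r8$means,
                                 ayt = fit_a)
    comparisons[[grp]] <- cmp
    attributions[[grp]] <- attr_tab
    wr(am, sprintf("pyt_%s_means.csv", grp))
    wr(adj_r8$means, sprintf("pyt_%s_means_given_r8.csv", grp))
    if (!is.null(cmp)) {
      cmp_df <- as.data.frame(cmp)
      cmp_df$maturity <- grp
      wr(cmp_df, sprintf("comparisons_%s.csv", grp))
    }
    at_df <- as.data.frame(attr_tab)
    at_df$maturity <- grp
    wr(at_df, sprintf("attribution_%s.csv", grp))
  }

  if (!is.null(outdir)) {
    yaml::write_yaml(list(config = cfg,
                          n_lines = length(line_ids),
                          n_plots = nrow(pheno),
                          n_selected = length(outcome$union_selected)),
                     file.path(outdir, "runlog.yaml"))
  }
  invisible(list(config = cfg, arch = arch, ped = ped, bv = bv,
                 layout = lay, pheno = pheno, coverage = cov_tab,
                 acc = acc_tab, fits = fits, blup_correlations = blup_cor,
                 varcomp = varcomp, outcome = outcome, early_late = el,
                 trials = trial_results, comparisons = comparisons,
                 attributions = attributions))
}
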