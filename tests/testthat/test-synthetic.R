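test_that("proteome generation is a pure function of the spec", {
  sp <- proteome_spec(n_proteins = 800, cv = 0.1, n_replicates = 2, seed = 17)
  a <- gen_proteome(sp)
  b <- gen_proteome(sp)
  expect_identical(a$table$ibaq, b$table$ibaq)
  expect_identical(a$table$lfq, b$table$lfq)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("RNG streams are split: noise level does not alter sector assignment", {
  sp0 <- proteome_spec(n_proteins = 800, cv = 0, n_replicates = 1, seed = 23)
  sp1 <- proteome_spec(n_proteins = 800, cv = 0.2, n_replicates = 1, seed = 23)
  a <- gen_proteome(sp0)
  b <- gen_proteome(sp1)
  expect_identical(a$truth$sector_of, b$truth$sector_of)
  expect_identical(a$truth$regulon, b$truth$regulon)
  expect_identical(a$table$proteins$mw_kda, b$table$proteins$mw_kda)
})

test_that("noiseless proteomes reproduce the configured sector fractions exactly", {
  sp <- proteome_spec(cv = 0, n_replicates = 1, seed = 7)
  out <- gen_proteome(sp)
  alloc <- compute_mass_fractions(out$table)
  expect_true(max(abs(colSums(alloc$mass_fraction) - 1)) <= 1e-9)

  sf <- sector_fractions(alloc, truth_catalog(out))
  truth <- out$truth$sector_fractions
  for (cond in unique(truth$condition)) {
    grp <- paste("wild_type", cond, sep = "|")
    est <- sf[sf$group == grp, ]
    tr <- truth[truth$condition == cond, ]
    m <- match(est$sector, tr$sector)
    expect_true(max(abs(est$mean_fraction - tr$fraction[m])) <= 1e-9)
  }
  # baseline fractions equal the spec's phi for every named sector
  base <- truth[truth$condition == "baseline", ]
  m <- match(sp$sectors$name, base$sector)
  expect_equal(base$fraction[m], sp$sectors$phi, tolerance = 1e-12)
})

test_that("induction preset reallocates mass from ribosome to stress response", {
  sp <- proteome_spec(cv = 0, n_replicates = 1, seed = 3)
  tr <- gen_proteome(sp)$truth$sector_fractions
  g <- function(cond, sec) tr$fraction[tr$condition == cond & tr$sector == sec]
  expect_gt(g("relA_OE_30uM", "stress_response"), g("baseline", "stress_response"))
  expect_lt(g("relA_OE_30uM", "ribosome"), g("baseline", "ribosome"))
  # rpoS is pinned at its observed 5-fold induction
  gt <- gen_proteome(sp)$truth$genes
  rp <- gt[gt$gene_name == "rpoS" & gt$condition == "relA_OE_30uM", ]
  expect_equal(rp$fold_vs_ref, 5, tolerance = 1e-9)
})

test_that("rpoS-null proteomes delete rpoS and attenuate regulon induction", {
  sp <- proteome_spec(strains = c("wild_type", "rpoS_null"), cv = 0,
                      n_replicates = 1, seed = 5)
  out <- gen_proteome(sp)
  tab <- out$table
  rp <- out$truth$rpos_locus_tag
  null_cols <- tab$samples$strain == "rpoS_null"
  expect_true(all(tab$ibaq[rp, null_cols] == 0))
  expect_true(all(tab$ibaq[rp, !null_cols] > 0))

  gt <- out$truth$genes
  reg <- gt$locus_tag %in% out$truth$regulon & gt$condition == "relA_OE_30uM"
  f_wt <- gt$fold_vs_ref[reg & gt$strain == "wild_type"]
  f_nl <- gt$fold_vs_ref[reg & gt$strain == "rpoS_null"]
  expect_equal(f_wt, rep(3, length(f_wt)), tolerance = 1e-9)
  expect_equal(f_nl, 1 + sp$alpha * (f_wt - 1), tolerance = 1e-9)
})

test_that("regulon attenuation is recoverable from noisy replicates (20 seeds)", {
  ahat <- vapply(1:20, function(s) {
    sp <- preset("proteome_induction")
    sp$seed <- as.integer(s)
    out <- gen_proteome(sp)
    tab <- out$table
    fw <- fold_changes(tab, pick_samples(tab, "wild_type", "relA_OE_30uM"),
                       pick_samples(tab, "wild_type", "baseline"))
    fn <- fold_changes(tab, pick_samples(tab, "rpoS_null", "relA_OE_30uM"),
                       pick_samples(tab, "rpoS_null", "baseline"))
    rf <- regulon_activation_folds(fw, fn, out$truth$regulon)
    expect_equal(nrow(rf$missing), 0)
    stats::median((rf$folds$fold_null - 1) / (rf$folds$fold_wt - 1))
  }, numeric(1))
  expect_lt(abs(mean(ahat) - 0.5), 0.03)
})

test_that("generated growth curves honor their piecewise specification", {
  # degenerate piecewise: lag 0 and equal rates give a single exponential
  sp <- curve_spec(lambda_pre = 0.6, lambda_post = 0.6, od0 = 0.05, lag_h = 0,
                   t_transition = 1, dt = 0.1, horizon = 4, cv = 0)
  cv <- gen_growth_curve(sp)
  expect_equal(cv$od600, 0.05 * exp(0.6 * cv$time_h), tolerance = 1e-12)

  # noiseless spec round-trips through the fitting machinery
  sp2 <- curve_spec(lambda_pre = 0.95, lambda_post = 0.4, od0 = 0.1,
                    lag_h = 1.5, t_transition = 0, dt = 0.1, horizon = 8,
                    cv = 0)
  cv2 <- gen_growth_curve(sp2)
  lr <- lag_time(cv2)  # od_ini carried by the generator
  expect_equal(lr$t_lag, 1.5, tolerance = 1e-6)
  expect_equal(lr$fit$lambda, 0.4, tolerance = 1e-9)

  expect_error(curve_spec(lambda_pre = 1, lag_h = 5, t_transition = 1,
                          horizon = 4), "horizon shorter")
})

test_that("generated viability curves decay exponentially and round-trip", {
  flat <- gen_viability(rate = 0, t_grid = seq(0, 3, 0.5))
  expect_equal(relative_viability(flat)$rel_viability, rep(1, 7))

  cv <- gen_viability(rate = 0.42, t_grid = seq(0, 5, 0.5), cv = 0)
  expect_equal(death_rate(cv)$rate, 0.42, tolerance = 1e-10)
  expect_error(gen_viability(rate = 1, t_grid = numeric(0)), "empty time grid")
})
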