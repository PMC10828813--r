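test_that("mass fractions follow iBAQ x MW normalization (hand oracle)", {
  # iBAQ (10, 20, 30) with MW (50, 25, 10) kDa -> masses (500, 500, 300)
  tab <- make_tab(ibaq = matrix(c(10, 20, 30), ncol = 1), mw = c(50, 25, 10))
  alloc <- compute_mass_fractions(tab)
  expect_equal(unname(alloc$ibaq_mass[, 1]), c(500, 500, 300))
  expect_equal(unname(alloc$mass_fraction[, 1]), c(5 / 13, 5 / 13, 3 / 13))

  # single protein: fraction 1 whatever the intensity
  one <- make_tab(ibaq = matrix(42, ncol = 1), mw = 7)
  expect_equal(unname(compute_mass_fractions(one)$mass_fraction[, 1]), 1)

  # all-zero sample column is a degenerate-sample error naming the sample
  bad <- make_tab(ibaq = matrix(c(1, 2, 0, 0), ncol = 2), mw = c(1, 1))
  expect_error(compute_mass_fractions(bad), "zero total iBAQ mass.*s2")
})

test_that("fractions sum to 1 and are invariant to per-sample rescaling (property)", {
  set.seed(101)
  for (i in 1:20) {
    tab <- random_tab(n = sample(10:80, 1), m = sample(2:5, 1))
    alloc <- compute_mass_fractions(tab)
    expect_true(max(abs(colSums(alloc$mass_fraction) - 1)) <= 1e-9)

    scaled <- tab
    scale_by <- stats::runif(n_samples(tab), 0.001, 1000)
    scaled$ibaq <- sweep(tab$ibaq, 2, scale_by, "*")
    alloc2 <- compute_mass_fractions(scaled)
    rel <- abs(alloc2$mass_fraction - alloc$mass_fraction) /
      pmax(alloc$mass_fraction, .Machine$double.xmin)
    expect_true(max(rel) <= 1e-12)
  }
})

test_that("sector fractions aggregate mass by gene set with replicate statistics", {
  # 4 proteins of equal mass; two disjoint sectors covering half the mass each
  tab <- make_tab(ibaq = matrix(rep(1, 8), ncol = 2),
                  mw = rep(10, 4), tags = paste0("b000", 1:4))
  alloc <- compute_mass_fractions(tab)
  halves <- sector_catalog(list(first = c("b0001", "b0002"),
                                second = c("b0003", "b0004")), disjoint = TRUE)
  sf <- sector_fractions(alloc, halves, groups = c("g", "g"))
  expect_equal(sf$mean_fraction, c(0.5, 0.5))
  expect_equal(sum(sf$mean_fraction), 1)
  expect_equal(sf$n_replicates, c(2L, 2L))
  expect_equal(sf$sd_fraction, c(0, 0))

  whole <- sector_catalog(list(all = paste0("b000", 1:4)))
  expect_equal(sector_fractions(alloc, whole)$mean_fraction,
               rep(1, 2), tolerance = 1e-12)

  expect_warning(
    sf0 <- sector_fractions(alloc, sector_catalog(list(ghost = "b9999"))),
    "matched no detected proteins")
  expect_equal(sf0$mean_fraction, rep(0, 2))
  expect_equal(sf0$n_genes_matched, rep(0L, 2))
})

test_that("fold changes are ratios of replicate-group means with NA sentinel", {
  lfq <- matrix(c(10, 0, 5,   12, 0, 5,   20, 3, 0,  24, 5, 0), ncol = 4)
  tab <- make_tab(ibaq = lfq + 1, lfq = lfq, mw = rep(1, 3))
  fc <- fold_changes(tab, c("s3", "s4"), c("s1", "s2"))
  expect_equal(fc$fold[1], 22 / 11)           # mean(20,24)/mean(10,12)
  expect_true(fc$undefined[2] && is.na(fc$fold[2]))  # absent in denominator
  expect_equal(fc$fold[3], 0)                 # absent in numerator: fold 0

  idm <- fold_changes(tab, c("s1", "s2"), c("s1", "s2"))
  expect_equal(idm$fold[!idm$undefined], rep(1, 2))

  expect_error(fold_changes(tab, character(0), "s1"), "empty sample group")
  expect_error(fold_changes(tab, "zz", "s1"), "unknown sample id")
})

test_that("regulon activation folds pair backgrounds and report missing genes", {
  mk <- function(tags, folds, undef = rep(FALSE, length(tags))) {
    tibble::tibble(locus_tag = tags, gene_name = tags,
                   mean_a = 1, mean_b = 1, fold = folds,
                   undefined = undef, basis = "lfq_relative")
  }
  wt <- mk(c("b1", "b2", "b3"), c(4, 3, 2))
  nl <- mk(c("b1", "b2"), c(2, NA), undef = c(FALSE, TRUE))
  out <- regulon_activation_folds(wt, nl, c("b1", "b2", "b3"))
  expect_equal(out$folds$locus_tag, "b1")
  expect_equal(out$folds$attenuation, 2)  # wt 4 / null 2
  expect_setequal(out$missing$locus_tag, c("b2", "b3"))
  expect_error(regulon_activation_folds(wt, nl, character(0)), "empty regulon")
})

test_that("heatmap rows are z-scored, constants dropped, hand oracle matches", {
  lfq <- matrix(c(1, 3, 7,  2, 3, 7,  4, 3, 2,  8, 3, 1), ncol = 4)
  tab <- make_tab(ibaq = lfq + 1, lfq = lfq, mw = rep(1, 3))
  expect_message(z <- heatmap_matrix(tab), "dropped 1 zero-variance rows")
  expect_equal(nrow(z), 2)  # constant protein absent
  expect_true(max(abs(rowMeans(z))) < 1e-9)
  expect_true(max(abs(apply(z, 1, stats::sd) - 1)) < 1e-9)

  # independent arithmetic for row 1: pseudocount = min nonzero / 2 = 0.5
  lg <- log2(c(1, 2, 4, 8) + 0.5)
  expect_equal(unname(z[1, ]), (lg - mean(lg)) / stats::sd(lg))

  two <- make_tab(ibaq = matrix(c(1, 2), ncol = 1), mw = c(1, 1))
  expect_error(heatmap_matrix(two), ">= 2 samples")
})

test_that("seesaw: raising one sector's fold depresses the remaining fractions", {
  base_spec <- function(stress_fold) {
    proteome_spec(
      n_proteins = 300,
      sectors = tibble::tibble(
        name = c("ribosome", "stress_response"),
        n_genes = c(60, 60), phi = c(0.4, 0.1)),
      conditions = list(
        baseline = list(),
        induced = list(sector_folds = c(stress_response = stress_fold))),
      regulon_size = 0, cv = 0, n_replicates = 1, seed = 99)
  }
  frac_others <- function(stress_fold) {
    out <- gen_proteome(base_spec(stress_fold))
    tr <- out$truth$sector_fractions
    sum(tr$fraction[tr$condition == "induced" & tr$sector != "stress_response"])
  }
  f <- vapply(c(1, 2, 4, 8), frac_others, numeric(1))
  expect_true(all(diff(f) < 0))  # strictly decreasing
})
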