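#' Specification of a synthetic bacterial proteome
#'
#' Describes a ground-truth proteome with functional-sector structure for the
#' generator [gen_proteome()]. Each sector has a gene count and a baseline
#' mass fraction phi; the unassigned remainder of genes and mass goes to an
#' `other` sector. Conditions modify sectors by multiplicative folds, with
#' optional per-gene overrides and a regulon whose induction is partially
#' RpoS-dependent (attenuation `alpha` in the rpoS-null background).
#'
#' @param n_proteins Number of proteins (default 2500, the scale of a
#'   high-coverage E. coli label-free experiment).
#' @param sectors Data frame with columns `name`, `n_genes`, `phi`
#'   (baseline mass fractions, summing to <= 1).
#' @param conditions Named list of condition effects; the first entry is the
#'   reference (baseline) condition. Each entry is a list with optional
#'   `sector_folds` (named numeric, default 1), `overrides` (named by gene
#'   name, observed fold pinned post-renormalization) and `regulon_fold`
#'   (observed induction fold of regulon genes).
#' @param strains Subset of `c("wild_type", "rpoS_null")`.
#' @param regulon_size Number of stress-response genes forming the
#'   RpoS regulon (excludes rpoS itself).
#' @param alpha Retention factor of regulon induction in the rpoS-null
#'   background, in (0, 1]: a regulon gene with observed fold f in wild type
#'   has fold `1 + alpha * (f - 1)` in the null strain.
#' @param cv Replicate coefficient of variation of the multiplicative
#'   lognormal noise (default 0.1).
#' @param n_replicates Replicates per (strain, condition) group.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins = 2500,
                          sectors = default_sectors(),
                          conditions = default_conditions(),
                          strains = "wild_type",
                          regulon_size = 60,
                          alpha = 0.5,
                          cv = 0.1,
                          n_replicates = 3,
                          seed = 1L) {
  sectors <- tibble::as_tibble(sectors)
  stopifnot(all(c("name", "n_genes", "phi") %in% names(sectors)))
  if (sum(sectors$phi) > 1 + 1e-12) {
    stop("spec error: sector baseline fractions sum to more than 1")
  }
  if (sum(sectors$n_genes) > n_proteins) {
    stop("spec error: sector gene counts exceed `n_proteins`")
  }
  if (length(conditions) < 1 || is.null(names(conditions))) {
    stop("`conditions` must be a non-empty named list; first entry is the reference")
  }
  for (cnd in conditions) {
    if (!is.null(cnd$sector_folds) && any(cnd$sector_folds <= 0)) {
      stop("spec error: sector folds must be > 0")
    }
  }
  if (!(alpha > 0 && alpha <= 1)) stop("spec error: `alpha` must be in (0, 1]")
  if (cv < 0) stop("spec error: `cv` must be >= 0")
  strains <- match.arg(strains, c("wild_type", "rpoS_null"), several.ok = TRUE)
  structure(
    list(n_proteins = as.integer(n_proteins), sectors = sectors,
         conditions = conditions, strains = strains,
         regulon_size = as.integer(regulon_size), alpha = alpha,
         cv = cv, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "proteome_spec"
  )
}

#' Default functional sectors of a minimal-medium E. coli proteome
#'
#' Baseline mass fractions chosen as typical of exponential growth in glucose
#' minimal medium: a large translation apparatus, a fully induced amino-acid
#' biosynthesis sector, and a small basal stress-response sector. The
#' remainder (~33% of mass) is assigned to `other`.
#'
#' @return Tibble with `name`, `n_genes`, `phi`.
#' @export
default_sectors <- function() {
  tibble::tribble(
    ~name,                     ~n_genes, ~phi,
    "ribosome",                60,       0.18,
    "ribosome_affiliated",     40,       0.08,
    "aa_biosynthesis",         150,      0.12,
    "aa_peptide_transporters", 150,      0.08,
    "nucleotide_biosynthesis", 60,       0.05,
    "motility",                50,       0.02,
    "porin",                   10,       0.02,
    "stress_response",         120,      0.03,
    "glycolysis",              25,       0.05,
    "tca_cycle",               25,       0.04
  )
}

#' Default condition effects: baseline vs moderate (p)ppGpp induction
#'
#' The induced condition emulates moderate alarmone overproduction
#' (constitutive synthetase, low inducer): ribosome and translation-affiliated
#' sectors down, nucleotide biosynthesis and motility down, porins slightly
#' up, stress response up ~3-fold, with the master stress sigma factor rpoS
#' pinned at an observed 5-fold induction and regulon genes at 3-fold.
#'
#' @return Named list of condition effects (first entry = reference).
#' @export
default_conditions <- function() {
  list(
    baseline = list(),
    relA_OE_30uM = list(
      sector_folds = c(ribosome = 0.5, ribosome_affiliated = 0.6,
                       nucleotide_biosynthesis = 0.6, motility = 0.4,
                       porin = 1.3, stress_response = 3),
      overrides = c(rpoS = 5),
      regulon_fold = 3
    )
  )
}

# Deterministic per-sample noise seed, kept well inside 32-bit range.
sample_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(idx)) %% 2147483647)
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Ground-truth condition fractions. q0: baseline fractions (sum 1) of the
# genes present in this strain. `fold_sector`: per-gene compositional folds;
# `pinned`: named numeric of observed folds fixed post-renormalization.
condition_fractions <- function(q0, fold_sector, pinned_idx, pinned_fold) {
  stopifnot(length(pinned_idx) == length(pinned_fold))
  s_o <- sum(pinned_fold * q0[pinned_idx])
  if (s_o >= 1) stop("spec error: pinned observed folds claim >= 100% of proteome mass")
  free <- setdiff(seq_along(q0), pinned_idx)
  s_f <- sum(fold_sector[free] * q0[free])
  q <- numeric(length(q0))
  q[pinned_idx] <- pinned_fold * q0[pinned_idx]
  q[free] <- (1 - s_o) / s_f * fold_sector[free] * q0[free]
  q
}

#' Generate a synthetic proteome with known ground truth
#'
#' Deterministic given the spec (including its seed). Construction: genes are
#' randomly assigned to sectors; within-sector baseline mass weights are
#' drawn lognormally and scaled so each sector sums to its phi; per
#' condition, compositional sector folds are applied and the proteome
#' renormalized to sum 1 (this renormalization produces the seesaw
#' coupling), while per-gene overrides and regulon genes are pinned at their
#' *observed* folds; in the rpoS-null strain the rpoS gene is deleted and
#' regulon folds f are attenuated to `1 + alpha * (f - 1)`; per replicate,
#' i.i.d. multiplicative lognormal noise (mean 1, given CV) is applied and
#' fractions renormalized; intensities are emitted as iBAQ ~ fraction / MW
#' and LFQ ~ fraction with molecular weights drawn lognormally (median
#' 35 kDa, sigma_log 0.4). Intensity scale constants are arbitrary: every
#' downstream statistic is scale-invariant.
#'
#' RNG streams are split per component (assignment, weights, per-sample
#' noise), so changing the noise CV does not alter the gene-sector
#' assignment at a fixed seed.
#'
#' @param spec A [proteome_spec()].
#' @return An object of class `synthetic_proteome`: list with `table` (an
#'   [abundance_table()]) and `truth`, the ground-truth sidecar: `genes`
#'   (per strain/condition true fractions and folds vs the reference
#'   condition), `sector_fractions`, `regulon` (locus tags), `alpha`,
#'   `rpos_locus_tag` and the spec itself.
#' @export
gen_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  n <- spec$n_proteins
  sectors <- spec$sectors
  phi_other <- 1 - sum(sectors$phi)
  n_other <- n - sum(sectors$n_genes)
  sec_names <- c(sectors$name, "other")
  sec_sizes <- c(sectors$n_genes, n_other)
  sec_phi <- c(sectors$phi, phi_other)

  # stream 1: gene-sector assignment + regulon membership
  set.seed(spec$seed)
  perm <- sample.int(n)
  sector_of <- character(n)
  sector_of[perm] <- rep(sec_names, times = sec_sizes)
  locus <- sprintf("b%04d", seq_len(n))
  gene_name <- paste0("y", locus)
  stress_idx <- which(sector_of == "stress_response")
  if (length(stress_idx) == 0) stop("spec error: no stress_response sector genes")
  rpos_idx <- stress_idx[1]
  gene_name[rpos_idx] <- "rpoS"
  # give rpoS its canonical K-12 locus tag when free
  canon <- "b2741"
  if (!(locus[rpos_idx] == canon)) {
    holder <- match(canon, locus)
    if (is.na(holder)) {
      locus[rpos_idx] <- canon
    } else {
      locus[holder] <- locus[rpos_idx]
      locus[rpos_idx] <- canon
    }
  }
  reg_pool <- setdiff(stress_idx, rpos_idx)
  regulon_idx <- sort(sample(reg_pool, min(spec$regulon_size, length(reg_pool))))

  # stream 2: baseline weights and molecular weights
  set.seed(spec$seed + 1L)
  w <- stats::rlnorm(n, 0, 1)
  mw <- stats::rlnorm(n, log(35), 0.4)
  q0_all <- numeric(n)
  for (s in seq_along(sec_names)) {
    idx <- which(sector_of == sec_names[s])
    if (length(idx) > 0 && sec_phi[s] > 0) {
      q0_all[idx] <- w[idx] / sum(w[idx]) * sec_phi[s]
    }
  }

  ref_cond <- names(spec$conditions)[1]
  truth_genes <- list()
  truth_sectors <- list()
  samples <- list()
  ibaq_cols <- list()
  lfq_cols <- list()
  sidx <- 0L

  for (strain in spec$strains) {
    present <- if (strain == "rpoS_null") setdiff(seq_len(n), rpos_idx)
               else seq_len(n)
    q0 <- q0_all[present] / sum(q0_all[present])
    q_by_cond <- list()
    for (cond in names(spec$conditions)) {
      eff <- spec$conditions[[cond]]
      sf <- rep(1, length(present))
      if (!is.null(eff$sector_folds)) {
        hit <- match(sector_of[present], names(eff$sector_folds))
        sf[!is.na(hit)] <- eff$sector_folds[hit[!is.na(hit)]]
      }
      pin_idx <- integer(0)
      pin_fold <- numeric(0)
      if (!is.null(eff$regulon_fold) && eff$regulon_fold != 1) {
        ri <- match(regulon_idx, present)
        ri <- ri[!is.na(ri)]
        f <- rep(eff$regulon_fold, length(ri))
        if (strain == "rpoS_null") f <- 1 + spec$alpha * (f - 1)
        pin_idx <- c(pin_idx, ri)
        pin_fold <- c(pin_fold, f)
      }
      if (!is.null(eff$overrides)) {
        for (gn in names(eff$overrides)) {
          gi <- match(match(gn, gene_name), present)
          if (is.na(gi)) next  # e.g. rpoS in the null strain
          o <- eff$overrides[[gn]]
          drop_prior <- pin_idx != gi
          pin_idx <- c(pin_idx[drop_prior], gi)
          pin_fold <- c(pin_fold[drop_prior], o)
        }
      }
      q <- condition_fractions(q0, sf, pin_idx, pin_fold)
      q_by_cond[[cond]] <- q
      truth_genes[[paste(strain, cond)]] <- tibble::tibble(
        strain = strain, condition = cond,
        locus_tag = locus[present], gene_name = gene_name[present],
        sector = sector_of[present], mass_fraction = q,
        fold_vs_ref = q / q_by_cond[[ref_cond]]
      )
      truth_sectors[[paste(strain, cond)]] <- tibble::tibble(
        strain = strain, condition = cond,
        sector = sec_names,
        fraction = vapply(sec_names, function(sn)
          sum(q[sector_of[present] == sn]), numeric(1), USE.NAMES = FALSE)
      )
      for (rep_i in seq_len(spec$n_replicates)) {
        sidx <- sidx + 1L
        set.seed(sample_seed(spec$seed, sidx))
        sl <- lognormal_sdlog(spec$cv)
        noise <- stats::rlnorm(length(present), -sl^2 / 2, sl)
        qn <- q * noise
        qn <- qn / sum(qn)
        ib <- numeric(n)
        lf <- numeric(n)
        ib[present] <- 1e10 * qn / mw[present]
        lf[present] <- 1e9 * qn
        ibaq_cols[[sidx]] <- ib
        lfq_cols[[sidx]] <- lf
        samples[[sidx]] <- tibble::tibble(
          sample_id = paste(strain, cond, rep_i, sep = "."),
          strain = strain, condition = cond, replicate = rep_i
        )
      }
    }
  }

  tab <- abundance_table(
    proteins = tibble::tibble(
      protein_id = paste0("SYN_", toupper(locus)),
      locus_tag = locus, gene_name = gene_name, mw_kda = mw),
    samples = dplyr::bind_rows(samples),
    ibaq = do.call(cbind, ibaq_cols),
    lfq = do.call(cbind, lfq_cols)
  )
  structure(
    list(table = tab,
         truth = list(
           genes = dplyr::bind_rows(truth_genes),
           sector_fractions = dplyr::bind_rows(truth_sectors),
           sector_of = stats::setNames(sector_of, locus),
           regulon = locus[regulon_idx],
           rpos_locus_tag = locus[rpos_idx],
           alpha = spec$alpha,
           reference_condition = ref_cond,
           spec = spec)),
    class = "synthetic_proteome"
  )
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat("<synthetic_proteome>\n")
  print(x$table)
  invisible(x)
}

#' Sector catalog derived from a synthetic proteome's ground truth
#'
#' @param synth A [gen_proteome()] result.
#' @return A disjoint [sector_catalog()] mapping each sector to its locus
#'   tags.
#' @export
truth_catalog <- function(synth) {
  stopifnot(inherits(synth, "synthetic_proteome"))
  so <- synth$truth$sector_of
  sector_catalog(split(names(so), so), disjoint = TRUE)
}

#' Specification of a synthetic growth / downshift curve
#'
#' Emulates exponential growth with an optional nutrient downshift: OD grows
#' at `lambda_pre` until `t_transition`, stays flat at the transition OD for
#' `lag_h` hours, then resumes exponentially at `lambda_post`. With
#' `t_transition = NA` the curve is a single exponential at `lambda_pre`.
#'
#' @param lambda_pre,lambda_post Growth rates, 1/h (natural log).
#' @param od0 OD600 at t = 0.
#' @param lag_h Lag duration after the transition, hours (>= 0).
#' @param t_transition Shift time, hours, or NA for a plain growth curve.
#' @param dt Sampling interval, hours.
#' @param horizon Last sampling time, hours.
#' @param cv Multiplicative lognormal OD noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @param strain,condition Metadata labels.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(lambda_pre, lambda_post = lambda_pre, od0 = 0.02,
                       lag_h = 0, t_transition = NA, dt = 1 / 6, horizon = 4,
                       cv = 0, seed = 1L, strain = NA_character_,
                       condition = NA_character_) {
  if (!all(is.finite(c(lambda_pre, lambda_post)))) stop("rates must be finite")
  if (lag_h < 0) stop("spec error: `lag_h` must be >= 0")
  if (od0 <= 0 || dt <= 0) stop("`od0` and `dt` must be > 0")
  if (!is.na(t_transition) && horizon < t_transition + lag_h) {
    stop("spec error: horizon shorter than transition + lag")
  }
  structure(list(lambda_pre = lambda_pre, lambda_post = lambda_post,
                 od0 = od0, lag_h = lag_h, t_transition = t_transition,
                 dt = dt, horizon = horizon, cv = cv, seed = as.integer(seed),
                 strain = strain, condition = condition),
            class = "curve_spec")
}

#' Generate a synthetic OD600 growth curve
#'
#' Deterministic given the spec and its seed. See [curve_spec()] for the
#' piecewise model. The true OD at the transition (`od_ini`, the quantity a
#' spectrophotometer reading right after the shift would give) is attached
#' to the returned curve.
#'
#' @param spec A [curve_spec()].
#' @return A [growth_curve()].
#' @export
gen_growth_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  t <- seq(0, spec$horizon, by = spec$dt)
  if (is.na(spec$t_transition)) {
    od <- spec$od0 * exp(spec$lambda_pre * t)
    od_ini <- NULL
    t_tr <- NULL
  } else {
    t_tr <- spec$t_transition
    od_ini <- spec$od0 * exp(spec$lambda_pre * t_tr)
    od <- ifelse(
      t < t_tr, spec$od0 * exp(spec$lambda_pre * t),
      ifelse(t <= t_tr + spec$lag_h, od_ini,
             od_ini * exp(spec$lambda_post * (t - t_tr - spec$lag_h))))
  }
  if (spec$cv > 0) {
    set.seed(spec$seed)
    sl <- lognormal_sdlog(spec$cv)
    od <- od * stats::rlnorm(length(od), -sl^2 / 2, sl)
  }
  growth_curve(t, od, strain = spec$strain, condition = spec$condition,
               t_transition = t_tr, od_ini = od_ini)
}

#' Generate a synthetic stress-survival curve
#'
#' Counts decay exponentially, `CFU/OD(t) = n0 * exp(-rate * t)`, with
#' optional multiplicative lognormal count noise. Deterministic per seed.
#'
#' @param rate Death rate, 1/h (>= 0; 0 gives a flat curve).
#' @param t_grid Sampling times (hours) starting at 0.
#' @param cv Count noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @param n0 Initial CFU/OD (arbitrary scale).
#' @param stressor,strain,condition Metadata labels.
#' @return A [viability_curve()].
#' @export
gen_viability <- function(rate, t_grid = seq(0, 6, by = 0.5), cv = 0,
                          seed = 1L, n0 = 1e9, stressor = NA_character_,
                          strain = NA_character_, condition = NA_character_) {
  if (length(t_grid) == 0) stop("spec error: empty time grid")
  if (rate < 0) stop("`rate` must be >= 0")
  counts <- n0 * exp(-rate * t_grid)
  if (cv > 0) {
    set.seed(seed)
    sl <- lognormal_sdlog(cv)
    counts <- counts * stats::rlnorm(length(counts), -sl^2 / 2, sl)
  }
  viability_curve(t_grid, counts, stressor = stressor, strain = strain,
                  condition = condition)
}
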