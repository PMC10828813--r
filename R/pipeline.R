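# End-to-end study runners: orchestrate the allocation chain
# (read -> mass fractions -> sectors -> folds -> regulon -> enrichment ->
# heatmap -> exports) and the phenotype chain (growth rates, downshift lags,
# survival), with a config copy, run log and machine-readable JSON summary
# written to the output directory.

log_line <- function(log_path, ...) {
  msg <- paste0(...)
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    manifest <- list(failed_stage = stage,
                     error = conditionMessage(e),
                     partial_outputs = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full proteome-allocation study
#'
#' Orchestrates a reproducible allocation analysis: load (or synthesize) an
#' abundance table, compute iBAQ-mass fractions, sector fractions, LFQ fold
#' changes between an induced and a reference group, regulon activation
#' folds across genetic backgrounds (when both are present), enrichment of
#' upregulated proteins, and the heatmap matrix. All tidy tables, a
#' proteomaps export of the first sample per group, a copy of the config and
#' a machine-readable JSON summary are written to `config$out_dir`. Rerunning
#' with the same config and seed reproduces the summary byte for byte.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `out_dir` (required); `seed` (default 1); `proteome` — either
#'   `list(preset = "proteome_induction")` or `list(path = <TSV>)`;
#'   `catalog` — path to a GMT file, or NULL to derive the sector catalog
#'   from the synthetic ground truth; `groups` — list with `numerator` and
#'   `denominator`, each `list(strain = , condition = )` (defaults: induced
#'   vs baseline wild type); `fold_threshold` (default 2).
#' @return The summary list, invisibly. Side effect: files under
#'   `config$out_dir`.
#' @export
run_allocation_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  seed <- config$seed %||% 1L
  log_line(log_path, "allocsaw ", as.character(utils::packageVersion("allocsaw")),
           " | allocation study | seed ", seed)

  loaded <- run_stage("load", out_dir, {
    pr <- config$proteome %||% list(preset = "proteome_induction")
    if (!is.null(pr$path)) {
      list(tab = read_abundance_table(pr$path, sample_info = pr$sample_info),
           synth = NULL)
    } else {
      sp <- preset(pr$preset %||% "proteome_induction")
      sp$seed <- as.integer(seed)
      synth <- gen_proteome(sp)
      list(tab = synth$table, synth = synth)
    }
  })
  tab <- loaded$tab
  synth <- loaded$synth
  log_line(log_path, "loaded ", n_proteins(tab), " proteins x ",
           n_samples(tab), " samples")

  catalog <- run_stage("catalog", out_dir, {
    if (!is.null(config$catalog)) {
      if (!file.exists(config$catalog)) {
        stop("sector catalog not found: ", config$catalog)
      }
      read_gmt(config$catalog)
    } else if (!is.null(synth)) {
      truth_catalog(synth)
    } else {
      stop("a `catalog` GMT path is required for non-synthetic input")
    }
  })

  alloc <- run_stage("mass_fractions", out_dir, compute_mass_fractions(tab))
  sectors <- run_stage("sector_fractions", out_dir,
                       sector_fractions(alloc, catalog))

  groups <- config$groups %||% list(
    numerator = list(strain = "wild_type", condition = "relA_OE_30uM"),
    denominator = list(strain = "wild_type", condition = "baseline"))
  pick_samples <- function(g) {
    sel <- tab$samples$strain == g$strain & tab$samples$condition == g$condition
    ids <- tab$samples$sample_id[sel & !is.na(sel)]
    if (length(ids) == 0) {
      stop("no samples match strain '", g$strain, "', condition '",
           g$condition, "'")
    }
    ids
  }
  folds <- run_stage("fold_changes", out_dir, {
    fold_changes(tab, pick_samples(groups$numerator),
                 pick_samples(groups$denominator), basis = "lfq_relative")
  })

  regulon_out <- NULL
  if (!is.null(synth) && "rpoS_null" %in% tab$samples$strain) {
    regulon_out <- run_stage("regulon_folds", out_dir, {
      null_num <- utils::modifyList(groups$numerator, list(strain = "rpoS_null"))
      null_den <- utils::modifyList(groups$denominator, list(strain = "rpoS_null"))
      fold_null <- fold_changes(tab, pick_samples(null_num),
                                pick_samples(null_den), basis = "lfq_relative")
      regulon_activation_folds(folds, fold_null, synth$truth$regulon)
    })
  }

  fold_threshold <- config$fold_threshold %||% 2
  enrich <- run_stage("enrichment", out_dir, {
    compared <- c(pick_samples(groups$numerator), pick_samples(groups$denominator))
    up <- select_regulated(folds, threshold = fold_threshold, direction = "up")
    hypergeom_enrichment(up, catalog, detected_universe(tab, compared))
  })
  hm <- run_stage("heatmap", out_dir, suppressMessages(heatmap_matrix(tab)))

  run_stage("exports", out_dir, {
    readr::write_csv(allocation_long(alloc),
                     file.path(out_dir, "allocation_long.csv"))
    readr::write_csv(sectors, file.path(out_dir, "sector_fractions.csv"))
    readr::write_csv(folds, file.path(out_dir, "fold_changes.csv"))
    readr::write_csv(enrich, file.path(out_dir, "enrichment.csv"))
    if (!is.null(regulon_out)) {
      readr::write_csv(regulon_out$folds, file.path(out_dir, "regulon_folds.csv"))
    }
    hm_df <- tibble::as_tibble(hm, rownames = "locus_tag")
    readr::write_csv(hm_df, file.path(out_dir, "heatmap_matrix.csv"))
    first_sample <- tab$samples$sample_id[1]
    write_proteomap_input(alloc, first_sample,
                          file.path(out_dir, paste0("proteomap_", first_sample, ".txt")))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  })

  summary <- run_stage("summary", out_dir, {
    rpos_row <- which(folds$gene_name == "rpoS")
    num_lab <- paste(groups$numerator$strain, groups$numerator$condition, sep = "|")
    den_lab <- paste(groups$denominator$strain, groups$denominator$condition, sep = "|")
    sector_means <- function(lab) {
      sub <- sectors[sectors$group == lab, ]
      stats::setNames(as.list(sub$mean_fraction), sub$sector)
    }
    list(
      schema_version = "1.0",
      package_version = as.character(utils::packageVersion("allocsaw")),
      seed = seed,
      n_proteins = n_proteins(tab),
      n_samples = n_samples(tab),
      fold_threshold = fold_threshold,
      groups = list(numerator = num_lab, denominator = den_lab),
      rpoS_fold = if (length(rpos_row) == 1) folds$fold[rpos_row] else NULL,
      sector_fractions = list(
        numerator = sector_means(num_lab),
        denominator = sector_means(den_lab)),
      n_upregulated = sum(!folds$undefined & folds$fold >= fold_threshold,
                          na.rm = TRUE),
      n_undefined_folds = sum(folds$undefined),
      top_enriched = utils::head(enrich$set_name, 3),
      top_enriched_q = utils::head(enrich$q_value, 3),
      n_heatmap_rows = nrow(hm),
      regulon_median_attenuation = if (!is.null(regulon_out))
        stats::median(regulon_out$folds$attenuation) else NULL
    )
  })
  write_summary_json(summary, file.path(out_dir, "summary.json"))
  log_line(log_path, "summary written: ", file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Run the growth-physiology study
#'
#' Fits exponential growth rates for a reference and an induced strain,
#' extracts nutrient-downshift lag times for paired (uninduced vs induced)
#' scenarios by the back-extrapolation procedure, and summarizes
#' stress-survival curves. Writes tidy CSVs, the config copy and a JSON
#' summary with per-group rates, the percent growth-rate decrease under
#' induction, per-scenario lags and lag ratios, and percent viability loss.
#'
#' @param config A list (or YAML path) with entries: `out_dir` (required);
#'   `seed` (default 1); `growth` — named list of growth presets (default
#'   wild type vs induced); `downshift` — character vector of scenarios
#'   (default all three); `viability` — character vector of viability
#'   presets; `loss_at_h` — time for percent-loss evaluation (default 4.5);
#'   `r2_min` (default 0.995).
#' @return The summary list, invisibly.
#' @export
run_phenotype_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  seed <- config$seed %||% 1L
  r2_min <- config$r2_min %||% 0.995
  log_line(log_path, "allocsaw ", as.character(utils::packageVersion("allocsaw")),
           " | phenotype study | seed ", seed)

  growth_cfg <- config$growth %||% list(wild_type = "growth_wt_minimal",
                                        relA_OE = "growth_relA_OE_30uM")
  if (length(growth_cfg) == 0) stop("validation error: empty growth curve set")
  rates <- run_stage("growth_rates", out_dir, {
    curves <- lapply(unname(growth_cfg), function(nm) {
      sp <- preset(nm)
      sp$seed <- as.integer(seed)
      gen_growth_curve(sp)
    })
    growth_rate_summary(curves, groups = names(growth_cfg))
  })

  scenarios <- config$downshift %||%
    c("NH4Cl_to_alanine", "NH4Cl_to_arginine", "glucose_to_alanine")
  lags <- run_stage("downshift_lags", out_dir, {
    rows <- lapply(scenarios, function(sc) {
      per_strain <- lapply(c("wt", "relA_OE"), function(st) {
        sp <- preset(sprintf("downshift_%s_%s", sc, st))
        sp$seed <- as.integer(seed)
        cv <- gen_growth_curve(sp)
        lr <- lag_time(cv, r2_min = r2_min)
        tibble::tibble(scenario = sc, strain = st, t_lag = lr$t_lag,
                       t_resume = lr$t_resume, lambda_post = lr$fit$lambda,
                       clamped = lr$clamped)
      })
      dplyr::bind_rows(per_strain)
    })
    dplyr::bind_rows(rows)
  })
  lag_ratios <- run_stage("lag_ratios", out_dir, {
    vapply(scenarios, function(sc) {
      sub <- lags[lags$scenario == sc, ]
      sub$t_lag[sub$strain == "wt"] / sub$t_lag[sub$strain == "relA_OE"]
    }, numeric(1))
  })

  via_cfg <- config$viability %||% c("viability_hyperosmotic_wt",
                                     "viability_hyperosmotic_relA_OE")
  loss_at <- config$loss_at_h %||% 4.5
  viab <- run_stage("viability", out_dir, {
    rows <- lapply(via_cfg, function(nm) {
      args <- preset(nm)
      args$seed <- as.integer(seed)
      cv <- do.call(gen_viability, args)
      dr <- suppressWarnings(death_rate(cv))
      tibble::tibble(preset = nm, strain = cv$strain, stressor = cv$stressor,
                     death_rate = dr$rate,
                     percent_loss = percent_loss(cv, loss_at),
                     loss_at_h = loss_at)
    })
    dplyr::bind_rows(rows)
  })

  run_stage("exports", out_dir, {
    readr::write_csv(rates, file.path(out_dir, "growth_rates.csv"))
    readr::write_csv(lags, file.path(out_dir, "downshift_lags.csv"))
    readr::write_csv(viab, file.path(out_dir, "viability.csv"))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  })

  summary <- run_stage("summary", out_dir, {
    lam <- stats::setNames(as.list(rates$mean_lambda), rates$group)
    decrease <- if (all(c("wild_type", "relA_OE") %in% rates$group)) {
      100 * (1 - lam$relA_OE / lam$wild_type)
    } else NULL
    list(
      schema_version = "1.0",
      package_version = as.character(utils::packageVersion("allocsaw")),
      seed = seed,
      growth_rates = lam,
      growth_rate_sd = stats::setNames(as.list(rates$sd_lambda), rates$group),
      percent_rate_decrease = decrease,
      lag_times = stats::setNames(as.list(lags$t_lag),
                                  paste(lags$scenario, lags$strain, sep = "|")),
      lag_ratios = as.list(lag_ratios),
      viability = stats::setNames(as.list(viab$percent_loss), viab$preset),
      death_rates = stats::setNames(as.list(viab$death_rate), viab$preset)
    )
  })
  write_summary_json(summary, file.path(out_dir, "summary.json"))
  log_line(log_path, "summary written: ", file.path(out_dir, "summary.json"))
  invisible(summary)
}
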