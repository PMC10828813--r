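#' Compute per-protein proteome mass fractions from iBAQ intensities
#'
#' iBAQ intensity is a proxy for protein copy number, so iBAQ x molecular
#' weight ("iBAQ mass") is a proxy for the total mass of each protein species.
#' Normalizing iBAQ mass by its per-sample sum gives the mass fraction of the
#' proteome allocated to each protein: for protein i in sample s,
#' \deqn{f_{is} = \mathrm{iBAQ}_{is} \cdot MW_i \;/\; \sum_j \mathrm{iBAQ}_{js} \cdot MW_j.}
#' Fractions sum to 1 per sample and are invariant under any positive
#' rescaling of a sample's iBAQ column.
#'
#' @param table An [abundance_table()].
#' @return An `allocation_table`: list with `locus_tags`, `samples`,
#'   `ibaq_mass` and `mass_fraction` matrices (proteins x samples).
#' @export
compute_mass_fractions <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  mass <- table$ibaq * table$proteins$mw_kda
  totals <- colSums(mass)
  if (any(totals <= 0)) {
    bad <- table$samples$sample_id[totals <= 0]
    stop("degenerate sample(s) with zero total iBAQ mass: ",
         paste(bad, collapse = ", "))
  }
  frac <- sweep(mass, 2, totals, "/")
  structure(
    list(locus_tags = table$proteins$locus_tag, samples = table$samples,
         ibaq_mass = mass, mass_fraction = frac),
    class = "allocation_table"
  )
}

#' @export
print.allocation_table <- function(x, ...) {
  cat(sprintf("<allocation_table> %d proteins x %d samples (fractions sum to 1 per sample)\n",
              length(x$locus_tags), nrow(x$samples)))
  invisible(x)
}

#' Tidy long-format view of an allocation table
#'
#' @param allocation An [compute_mass_fractions()] result.
#' @return Tibble with columns `locus_tag`, `sample_id`, `ibaq_mass`,
#'   `mass_fraction`.
#' @export
allocation_long <- function(allocation) {
  stopifnot(inherits(allocation, "allocation_table"))
  tibble::tibble(
    locus_tag = rep(allocation$locus_tags, times = nrow(allocation$samples)),
    sample_id = rep(allocation$samples$sample_id,
                    each = length(allocation$locus_tags)),
    ibaq_mass = as.vector(allocation$ibaq_mass),
    mass_fraction = as.vector(allocation$mass_fraction)
  )
}

# Default replicate grouping: one group per (strain, condition).
default_groups <- function(samples) {
  paste(ifelse(is.na(samples$strain), "", samples$strain),
        ifelse(is.na(samples$condition), "", samples$condition),
        sep = "|")
}

#' Aggregate mass fractions into functional proteome sectors
#'
#' A sector's fraction in a sample is the summed mass fraction of the
#' proteins whose locus tag belongs to the sector's gene set (absent tags
#' contribute 0). Fractions are then summarized as mean and SD across the
#' replicates of each (strain, condition) group; SD is 0 for singleton
#' groups. Sectors with no matched genes yield fraction 0 and a warning.
#'
#' @param allocation An allocation table from [compute_mass_fractions()].
#' @param catalog A [sector_catalog()].
#' @param groups Character vector assigning each sample to a replicate
#'   group; defaults to one group per (strain, condition).
#' @return Tibble with `sector`, `group`, `mean_fraction`, `sd_fraction`,
#'   `n_replicates`, `n_genes_matched`. The per-sample sector x sample
#'   fraction matrix is attached as attribute `"per_sample"`.
#' @export
sector_fractions <- function(allocation, catalog, groups = NULL) {
  stopifnot(inherits(allocation, "allocation_table"),
            inherits(catalog, "sector_catalog"))
  groups <- groups %||% default_groups(allocation$samples)
  if (length(groups) != nrow(allocation$samples)) {
    stop("`groups` must have one entry per sample")
  }
  tags <- allocation$locus_tags
  per_sample <- matrix(0, nrow = length(catalog$sets),
                       ncol = nrow(allocation$samples),
                       dimnames = list(names(catalog$sets),
                                       allocation$samples$sample_id))
  n_matched <- integer(length(catalog$sets))
  names(n_matched) <- names(catalog$sets)
  for (nm in names(catalog$sets)) {
    hit <- tags %in% catalog$sets[[nm]]
    n_matched[nm] <- sum(hit)
    if (!any(hit)) {
      warning("sector '", nm, "' matched no detected proteins")
      next
    }
    per_sample[nm, ] <- colSums(allocation$mass_fraction[hit, , drop = FALSE])
  }
  out <- lapply(unique(groups), function(g) {
    cols <- which(groups == g)
    sub <- per_sample[, cols, drop = FALSE]
    tibble::tibble(
      sector = rownames(per_sample),
      group = g,
      mean_fraction = unname(rowMeans(sub)),
      sd_fraction = if (length(cols) > 1) unname(apply(sub, 1, stats::sd)) else 0,
      n_replicates = length(cols),
      n_genes_matched = unname(n_matched)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "per_sample") <- per_sample
  res
}

#' Per-protein fold changes between two condition groups
#'
#' Computes, per protein, the ratio of replicate-group means between a
#' numerator and a denominator group. Relative comparisons conventionally use
#' LFQ intensity (`basis = "lfq_relative"`); absolute comparisons can use
#' iBAQ-derived mass fractions (`basis = "mass_fraction"`). Proteins
#' undetected (mean 0) in the denominator get `fold = NA` with
#' `undefined = TRUE` — never infinity.
#'
#' @param table An [abundance_table()].
#' @param group_a,group_b Character vectors of sample ids: numerator and
#'   denominator replicate groups.
#' @param basis `"lfq_relative"` (default) or `"mass_fraction"`.
#' @return Tibble with `locus_tag`, `gene_name`, `mean_a`, `mean_b`, `fold`,
#'   `undefined`, `basis`.
#' @export
fold_changes <- function(table, group_a, group_b,
                         basis = c("lfq_relative", "mass_fraction")) {
  stopifnot(inherits(table, "abundance_table"))
  basis <- match.arg(basis)
  sid <- table$samples$sample_id
  for (g in list(group_a, group_b)) {
    if (length(g) == 0) stop("grouping error: empty sample group")
    miss <- setdiff(g, sid)
    if (length(miss) > 0) {
      stop("grouping error: unknown sample id(s): ", paste(miss, collapse = ", "))
    }
  }
  m <- if (basis == "lfq_relative") table$lfq
       else compute_mass_fractions(table)$mass_fraction
  mean_a <- unname(rowMeans(m[, match(group_a, sid), drop = FALSE]))
  mean_b <- unname(rowMeans(m[, match(group_b, sid), drop = FALSE]))
  undefined <- mean_b <= 0
  fold <- ifelse(undefined, NA_real_, mean_a / mean_b)
  tibble::tibble(
    locus_tag = table$proteins$locus_tag,
    gene_name = table$proteins$gene_name,
    mean_a = mean_a, mean_b = mean_b,
    fold = fold, undefined = undefined, basis = basis
  )
}

#' Regulon activation folds across genetic backgrounds
#'
#' Pairs, for each gene of a regulon, its induction fold change in two
#' genetic backgrounds (e.g. wild type vs a regulator-null strain) and
#' reports the attenuation ratio (wild-type fold / null fold). Genes missing
#' or undefined in either table are listed separately, never silently
#' dropped.
#'
#' @param fold_wt,fold_null Fold-change tables from [fold_changes()],
#'   computed on the same basis.
#' @param regulon Character vector of regulon locus tags.
#' @return List with `folds` (tibble: `locus_tag`, `fold_wt`, `fold_null`,
#'   `attenuation`) and `missing` (tibble: `locus_tag`, `reason`).
#' @export
regulon_activation_folds <- function(fold_wt, fold_null, regulon) {
  regulon <- unique(tolower(trimws(regulon)))
  if (length(regulon) == 0) stop("validation error: empty regulon")
  if (!identical(unique(fold_wt$basis), unique(fold_null$basis))) {
    stop("fold tables must be computed on the same basis")
  }
  status <- function(tab, gene) {
    i <- match(gene, tab$locus_tag)
    if (is.na(i)) return(c(NA_real_, "absent"))
    if (isTRUE(tab$undefined[i])) return(c(NA_real_, "undefined fold"))
    c(tab$fold[i], "ok")
  }
  rows <- lapply(regulon, function(g) {
    wt <- status(fold_wt, g)
    nl <- status(fold_null, g)
    tibble::tibble(locus_tag = g,
                   fold_wt = as.numeric(wt[1]), fold_null = as.numeric(nl[1]),
                   wt_status = wt[2], null_status = nl[2])
  })
  all <- dplyr::bind_rows(rows)
  ok <- all$wt_status == "ok" & all$null_status == "ok"
  folds <- all[ok, c("locus_tag", "fold_wt", "fold_null")]
  folds$attenuation <- folds$fold_wt / folds$fold_null
  missing <- all[!ok, ]
  missing <- tibble::tibble(
    locus_tag = missing$locus_tag,
    reason = paste0("wild-type: ", missing$wt_status,
                    "; null: ", missing$null_status)
  )
  list(folds = folds, missing = missing)
}

#' Row-standardized expression matrix for heatmap display
#'
#' Log-transforms LFQ intensities with a scale-adaptive pseudocount (half the
#' smallest nonzero intensity in the matrix) and z-scores each protein across
#' samples (row mean 0, SD 1). Proteins undetected everywhere or constant
#' across samples are dropped (a message reports the count). Row and column
#' order follow the input and are deterministic.
#'
#' @param table An [abundance_table()] with at least 2 samples.
#' @param groups Optional group labels (recorded as the `"groups"` attribute).
#' @return Numeric matrix, rows = locus tags, columns = sample ids.
#' @export
heatmap_matrix <- function(table, groups = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$samples) < 2) {
    stop("validation error: need >= 2 samples for a heatmap matrix")
  }
  lfq <- table$lfq
  detected <- rowSums(lfq) > 0
  lfq <- lfq[detected, , drop = FALSE]
  nz <- lfq[lfq > 0]
  if (length(nz) == 0) stop("validation error: no detected proteins")
  pseudo <- min(nz) / 2
  lg <- log2(lfq + pseudo)
  rsd <- apply(lg, 1, stats::sd)
  flat <- rsd == 0
  if (any(flat)) {
    message(sprintf("heatmap_matrix: dropped %d zero-variance rows", sum(flat)))
  }
  lg <- lg[!flat, , drop = FALSE]
  z <- (lg - rowMeans(lg)) / rsd[!flat]
  attr(z, "groups") <- groups %||% default_groups(table$samples)
  attr(z, "pseudocount") <- pseudo
  z
}

#' Write a proteomaps input file for one sample
#'
#' Writes the two-column tab-separated file consumed by the proteomaps
#' website: locus tag and that sample's iBAQ-mass fraction, no header, rows
#' in descending value order (ties broken lexicographically by tag), LF line
#' endings.
#'
#' @param allocation An allocation table from [compute_mass_fractions()].
#' @param sample_id Sample to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteomap_input <- function(allocation, sample_id, path) {
  stopifnot(inherits(allocation, "allocation_table"))
  j <- match(sample_id, allocation$samples$sample_id)
  if (is.na(j)) stop("unknown sample_id: ", sample_id)
  val <- allocation$mass_fraction[, j]
  tags <- allocation$locus_tags
  ord <- order(-val, tags, method = "radix")
  lines <- paste(tags[ord],
                 vapply(val[ord], format, character(1), digits = 15,
                        scientific = FALSE, trim = TRUE),
                 sep = "\t")
  con <- file(path, open = "wb")  # force LF endings on every platform
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, sep = "\n")
  invisible(path)
}
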