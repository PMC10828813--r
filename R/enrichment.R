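#' Select regulated genes from a fold-change table
#'
#' Picks the genes whose fold change crosses a symmetric threshold:
#' `fold >= threshold` for `direction = "up"`, `fold <= 1/threshold` for
#' `"down"`. Genes with an undefined fold (undetected denominator) are
#' excluded and counted in the `"n_excluded"` attribute. The returned list is
#' sorted, so it is stable under permutation of the input rows.
#'
#' @param folds A fold-change table from [fold_changes()].
#' @param threshold Fold threshold, must be > 1.
#' @param direction `"up"` or `"down"`.
#' @return Sorted character vector of locus tags.
#' @export
select_regulated <- function(folds, threshold = 2, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1) {
    stop("parameter error: `threshold` must be a single number > 1")
  }
  defined <- !folds$undefined & !is.na(folds$fold)
  hit <- if (direction == "up") folds$fold >= threshold
         else folds$fold <= 1 / threshold
  genes <- sort(folds$locus_tag[defined & hit])
  attr(genes, "n_excluded") <- sum(!defined)
  genes
}

#' Hypergeometric over-representation test against a gene-set catalog
#'
#' For each set in the catalog, tests whether the gene list overlaps the set
#' more than expected under random draws from the universe, using the
#' one-sided upper-tail hypergeometric probability
#' \deqn{p = P(X \ge k) = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}}
#' with `N` the universe size, `K` the in-universe set size, `n` the list
#' size and `k` the observed overlap. Benjamini-Hochberg q-values are
#' computed across all sets of the catalog. The universe should be the
#' detected proteome of the compared samples (see [detected_universe()]),
#' not the whole genome, to avoid detection bias.
#'
#' @param gene_list Character vector of locus tags (genes outside the
#'   universe are dropped with a warning).
#' @param catalog A [sector_catalog()].
#' @param universe Character vector of locus tags defining the sampling
#'   universe.
#' @return Tibble sorted by `q_value` then `p_value`, with columns
#'   `set_name`, `universe_size`, `set_size`, `list_size`, `overlap`,
#'   `p_value`, `q_value`.
#' @export
hypergeom_enrichment <- function(gene_list, catalog, universe) {
  stopifnot(inherits(catalog, "sector_catalog"))
  universe <- unique(tolower(trimws(universe)))
  if (length(universe) == 0) stop("validation error: empty universe")
  gene_list <- unique(tolower(trimws(gene_list)))
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) outside the universe dropped from the list")
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(catalog$sets), function(nm) {
    in_univ <- intersect(catalog$sets[[nm]], universe)
    K <- length(in_univ)
    k <- length(intersect(gene_list, in_univ))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, universe_size = N, set_size = K,
                   list_size = n, overlap = k, p_value = p)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$q_value, res$p_value, res$set_name), ]
}

#' Detected-proteome universe for enrichment testing
#'
#' Returns the locus tags detected (intensity > 0 on the chosen basis) in at
#' least one of the given samples — the default enrichment universe.
#'
#' @param table An [abundance_table()].
#' @param sample_ids Samples to consider (default: all).
#' @param basis `"lfq"` or `"ibaq"`.
#' @return Character vector of locus tags.
#' @export
detected_universe <- function(table, sample_ids = NULL, basis = c("lfq", "ibaq")) {
  basis <- match.arg(basis)
  m <- if (basis == "lfq") table$lfq else table$ibaq
  sample_ids <- sample_ids %||% table$samples$sample_id
  j <- match(sample_ids, table$samples$sample_id)
  if (anyNA(j)) stop("unknown sample id(s)")
  table$proteins$locus_tag[rowSums(m[, j, drop = FALSE]) > 0]
}
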