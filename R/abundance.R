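#' Construct a protein abundance table
#'
#' The central container for label-free proteomics data: per-protein
#' identifiers and molecular weights together with iBAQ and LFQ intensity
#' matrices over a set of samples. iBAQ intensity is a proxy for protein copy
#' number, LFQ intensity for relative abundance across samples; both are
#' nonnegative, with 0 meaning "not detected" (no imputation is performed).
#'
#' Locus tags are the primary join key and are case-normalized to lower case;
#' gene names are display-only (they are not unique in bacterial annotation,
#' locus tags are).
#'
#' @param proteins Data frame with columns `protein_id`, `locus_tag`,
#'   `gene_name`, `mw_kda` (molecular weight in kilodaltons, > 0).
#' @param samples Data frame with columns `sample_id`, `strain`, `condition`,
#'   `replicate`. `sample_id` must be unique, as must the
#'   (strain, condition, replicate) triple.
#' @param ibaq,lfq Numeric matrices, proteins x samples, finite and >= 0.
#' @return An object of class `abundance_table`: a list with elements
#'   `proteins` (tibble), `samples` (tibble), `ibaq`, `lfq` (matrices with
#'   locus tags as row names and sample ids as column names).
#' @export
abundance_table <- function(proteins, samples, ibaq, lfq) {
  proteins <- tibble::as_tibble(proteins)
  samples <- tibble::as_tibble(samples)
  req_p <- c("protein_id", "locus_tag", "gene_name", "mw_kda")
  if (!all(req_p %in% names(proteins))) {
    stop("`proteins` must have columns: ", paste(req_p, collapse = ", "))
  }
  req_s <- c("sample_id", "strain", "condition", "replicate")
  for (col in setdiff(req_s, names(samples))) samples[[col]] <- NA
  proteins$locus_tag <- tolower(trimws(proteins$locus_tag))

  dup <- unique(proteins$locus_tag[duplicated(proteins$locus_tag)])
  if (length(dup) > 0) {
    stop("duplicate locus tags after case normalization: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  if (any(!is.finite(proteins$mw_kda)) || any(proteins$mw_kda <= 0)) {
    stop("`mw_kda` must be finite and > 0 for every retained protein")
  }
  ibaq <- as.matrix(ibaq)
  lfq <- as.matrix(lfq)
  if (!identical(dim(ibaq), dim(lfq)) ||
      nrow(ibaq) != nrow(proteins) || ncol(ibaq) != nrow(samples)) {
    stop("`ibaq` and `lfq` must both be [n_proteins x n_samples] matrices")
  }
  for (m in list(ibaq, lfq)) {
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("intensities must be finite and >= 0 (encode missing values as 0)")
    }
  }
  if (anyDuplicated(samples$sample_id)) stop("`sample_id` values must be unique")
  triple <- samples[, c("strain", "condition", "replicate")]
  complete <- stats::complete.cases(triple)
  if (anyDuplicated(triple[complete, ])) {
    stop("(strain, condition, replicate) triples must be unique")
  }
  dimnames(ibaq) <- dimnames(lfq) <- list(proteins$locus_tag, samples$sample_id)
  structure(
    list(proteins = proteins, samples = samples, ibaq = ibaq, lfq = lfq),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d proteins x %d samples\n",
              nrow(x$proteins), nrow(x$samples)))
  cat("samples:", paste(utils::head(x$samples$sample_id, 8), collapse = ", "),
      if (nrow(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of proteins / samples in an abundance table
#' @param table An [abundance_table()].
#' @return Integer count.
#' @export
n_proteins <- function(table) nrow(table$proteins)

#' @rdname n_proteins
#' @export
n_samples <- function(table) nrow(table$samples)

# Default column mapping for the MaxQuant proteinGroups dialect. A generic
# TSV can be read by overriding any entry.
default_col_map <- function() {
  list(
    protein_id = c("Majority protein IDs", "Protein IDs"),
    gene_name = "Gene names",
    locus_tag = "Locus tag",
    mw_kda = "Mol. weight [kDa]",
    ibaq_prefix = "iBAQ ",
    lfq_prefix = "LFQ intensity "
  )
}

#' Read a protein abundance table from a tab-separated file
#'
#' Reads the MaxQuant `proteinGroups.txt` dialect (or a mapped generic TSV)
#' into an [abundance_table()]. Sample identities are parsed from the
#' suffixes of the per-sample intensity columns (`"iBAQ <sample>"`,
#' `"LFQ intensity <sample>"`), in file order. Rows flagged as contaminants or
#' decoys (any identifier token prefixed `CON__` or `REV__`) are dropped, as
#' are rows with a missing molecular weight (a message reports the counts;
#' the counts are also attached as the `"dropped"` attribute).
#'
#' Missing intensity cells are encoded as 0 ("not detected").
#'
#' @param path Path to a tab-separated file with a header row.
#' @param id_policy Which identifier becomes the primary key: `"locus_tag"`
#'   (default; requires a locus-tag column) or `"gene_name"` (first
#'   gene-name token, lower-cased).
#' @param col_map Named list overriding entries of the default MaxQuant
#'   column mapping (`protein_id`, `gene_name`, `locus_tag`, `mw_kda`,
#'   `ibaq_prefix`, `lfq_prefix`).
#' @param sample_info Optional data frame (`sample_id`, `strain`, `condition`,
#'   `replicate`) supplying sample metadata. Without it, sample ids of the
#'   form `<strain>.<condition>.<replicate>` are parsed; anything else gets
#'   `condition = sample_id`, `replicate = 1`.
#' @return A validated [abundance_table()].
#' @export
read_abundance_table <- function(path, id_policy = c("locus_tag", "gene_name"),
                                 col_map = NULL, sample_info = NULL) {
  id_policy <- match.arg(id_policy)
  cm <- utils::modifyList(default_col_map(), as.list(col_map %||% list()))
  # base reader: strtod parsing is correctly rounded, so full-precision
  # intensities survive a write/read round trip bit for bit
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           quote = "", stringsAsFactors = FALSE)

  pick <- function(cands, what, required = TRUE) {
    hit <- cands[cands %in% names(raw)]
    if (length(hit) == 0) {
      if (required) stop("format error: missing required column '",
                         cands[[1]], "' (", what, ")")
      return(NULL)
    }
    hit[[1]]
  }
  mw_col <- pick(cm$mw_kda, "molecular weight")
  pid_col <- pick(cm$protein_id, "protein identifiers")
  gene_col <- pick(cm$gene_name, "gene names", required = FALSE)

  ibaq_cols <- grep(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                     cm$ibaq_prefix), "(.+)$"),
                    names(raw), value = TRUE)
  ibaq_cols <- setdiff(ibaq_cols, paste0(cm$ibaq_prefix, "peptides"))
  lfq_cols <- grep(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                    cm$lfq_prefix), "(.+)$"),
                   names(raw), value = TRUE)
  if (length(ibaq_cols) == 0) stop("format error: no 'iBAQ <sample>' columns found")
  if (length(lfq_cols) == 0) {
    stop("format error: no '", cm$lfq_prefix, "<sample>' columns found")
  }
  sample_ids <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                     cm$ibaq_prefix)), "", ibaq_cols)
  lfq_ids <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                  cm$lfq_prefix)), "", lfq_cols)
  if (!setequal(sample_ids, lfq_ids)) {
    stop("format error: iBAQ and LFQ sample sets differ: ",
         paste(symdiff_chr(sample_ids, lfq_ids), collapse = ", "))
  }
  lfq_cols <- paste0(cm$lfq_prefix, sample_ids)  # align to iBAQ file order

  pid <- as.character(raw[[pid_col]])
  is_con <- vapply(strsplit(pid, ";", fixed = TRUE), function(tok) {
    any(startsWith(tok, "CON__") | startsWith(tok, "REV__"))
  }, logical(1))
  mw <- suppressWarnings(as.numeric(raw[[mw_col]]))
  missing_mw <- !is_con & (is.na(mw) | mw <= 0)
  keep <- !is_con & !missing_mw
  if (sum(is_con) > 0 || sum(missing_mw) > 0) {
    message(sprintf("read_abundance_table: dropped %d contaminant/decoy and %d missing-MW rows",
                    sum(is_con), sum(missing_mw)))
  }
  raw <- raw[keep, , drop = FALSE]
  mw <- mw[keep]
  pid <- pid[keep]

  gene_name <- if (is.null(gene_col)) rep("", nrow(raw)) else {
    g <- as.character(raw[[gene_col]])
    ifelse(is.na(g), "", g)
  }
  if (id_policy == "locus_tag") {
    lt_col <- pick(cm$locus_tag, "locus tags")
    locus_tag <- as.character(raw[[lt_col]])
  } else {
    locus_tag <- vapply(strsplit(gene_name, ";", fixed = TRUE),
                        function(x) x[[1]] %||% "", character(1))
    if (any(locus_tag == "" | is.na(locus_tag))) {
      stop("validation error: id_policy 'gene_name' requires a non-empty gene name for every row")
    }
  }

  num_mat <- function(cols) {
    m <- vapply(cols, function(cl) {
      v <- suppressWarnings(as.numeric(raw[[cl]]))
      v[is.na(v)] <- 0
      v
    }, numeric(nrow(raw)))
    if (nrow(raw) == 1) m <- matrix(m, nrow = 1)
    m
  }

  samples <- if (!is.null(sample_info)) {
    si <- tibble::as_tibble(sample_info)
    si[match(sample_ids, si$sample_id), , drop = FALSE]
  } else {
    parse_sample_ids(sample_ids)
  }

  tab <- abundance_table(
    proteins = tibble::tibble(protein_id = pid, locus_tag = locus_tag,
                              gene_name = gene_name, mw_kda = mw),
    samples = samples,
    ibaq = num_mat(ibaq_cols),
    lfq = num_mat(lfq_cols)
  )
  attr(tab, "dropped") <- list(contaminants = sum(is_con),
                               missing_mw = sum(missing_mw))
  tab
}

# "strain.condition.rep" -> metadata; otherwise condition = sample_id.
parse_sample_ids <- function(sample_ids) {
  m <- regmatches(sample_ids,
                  regexec("^(.+)\\.(.+)\\.([0-9]+)$", sample_ids))
  parsed <- lapply(seq_along(sample_ids), function(i) {
    g <- m[[i]]
    if (length(g) == 4) {
      tibble::tibble(sample_id = sample_ids[i], strain = g[2],
                     condition = g[3], replicate = as.integer(g[4]))
    } else {
      tibble::tibble(sample_id = sample_ids[i], strain = NA_character_,
                     condition = sample_ids[i], replicate = 1L)
    }
  })
  dplyr::bind_rows(parsed)
}

#' Write an abundance table as a MaxQuant-style TSV
#'
#' Serializes an [abundance_table()] in the same dialect that
#' [read_abundance_table()] consumes (including a `Locus tag` column), so a
#' write/read round trip preserves all retained values.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  out <- tibble::tibble(
    `Majority protein IDs` = table$proteins$protein_id,
    `Gene names` = table$proteins$gene_name,
    `Locus tag` = table$proteins$locus_tag,
    `Mol. weight [kDa]` = table$proteins$mw_kda
  )
  num17 <- function(x) sprintf("%.17g", x)  # shortest-safe full precision
  out$`Mol. weight [kDa]` <- num17(out$`Mol. weight [kDa]`)
  for (i in seq_len(nrow(table$samples))) {
    sid <- table$samples$sample_id[i]
    out[[paste0("iBAQ ", sid)]] <- num17(table$ibaq[, i])
    out[[paste0("LFQ intensity ", sid)]] <- num17(table$lfq[, i])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))
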