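# Small in-code fixtures shared across test files.

# Minimal abundance table: one sample per column, condition = sample id.
make_tab <- function(ibaq, lfq = ibaq, mw = rep(1, nrow(as.matrix(ibaq))),
                     tags = sprintf("b%04d", seq_len(nrow(as.matrix(ibaq)))),
                     genes = paste0("g", seq_along(tags))) {
  ibaq <- as.matrix(ibaq)
  lfq <- as.matrix(lfq)
  sids <- paste0("s", seq_len(ncol(ibaq)))
  abundance_table(
    proteins = tibble::tibble(protein_id = toupper(tags), locus_tag = tags,
                              gene_name = genes, mw_kda = mw),
    samples = tibble::tibble(sample_id = sids, strain = NA_character_,
                             condition = sids, replicate = 1L),
    ibaq = ibaq, lfq = lfq
  )
}

# Random valid abundance table for property-style tests.
random_tab <- function(n = 50, m = 4) {
  ibaq <- matrix(stats::rlnorm(n * m, 10, 1), n, m)
  ibaq[sample(length(ibaq), round(0.05 * length(ibaq)))] <- 0
  make_tab(ibaq, lfq = matrix(stats::rlnorm(n * m, 12, 1), n, m),
           mw = stats::rlnorm(n, log(35), 0.4))
}

# MaxQuant-dialect TSV written to a temp file; returns the path.
write_toy_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

toy_tsv_df <- function() {
  tibble::tibble(
    `Majority protein IDs` = c("P1", "CON__P00761", "P2", "P3"),
    `Gene names` = c("aceA", "trypsin", "rpoS", "ftsZ"),
    `Locus tag` = c("b4015", "con1", "b2741", "b0095"),
    `Mol. weight [kDa]` = c(47.5, 24.4, 37.9, NA),
    `iBAQ A1` = c(100, 5, 200, 50),
    `iBAQ A2` = c(110, 6, 190, 60),
    `LFQ intensity A1` = c(1e6, 1e3, 2e6, 5e5),
    `LFQ intensity A2` = c(1.1e6, 1e3, 1.9e6, 6e5)
  )
}

pick_samples <- function(tab, strain, condition) {
  sel <- tab$samples$strain == strain & tab$samples$condition == condition
  tab$samples$sample_id[sel]
}
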