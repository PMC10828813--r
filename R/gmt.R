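#' Construct a sector catalog (named gene sets)
#'
#' A catalog maps sector or regulon names to sets of locus tags. Catalogs may
#' be declared as a partition (`disjoint = TRUE`), in which case pairwise
#' intersections must be empty; annotation-derived catalogs (e.g. GO groups)
#' overlap by construction and keep the default `disjoint = FALSE`.
#'
#' @param sets Named list of character vectors of locus tags. Members are
#'   case-normalized to lower case and deduplicated.
#' @param disjoint Is this catalog intended as a partition?
#' @return An object of class `sector_catalog` with elements `sets` and
#'   `disjoint`.
#' @export
sector_catalog <- function(sets, disjoint = FALSE) {
  if (length(sets) > 0 &&
      (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set must have a non-empty name")
  }
  sets <- lapply(sets, function(x) unique(tolower(trimws(as.character(x)))))
  if (isTRUE(disjoint) && length(sets) > 1) {
    nm <- names(sets)
    for (i in seq_along(sets)[-1]) {
      for (j in seq_len(i - 1)) {
        ov <- intersect(sets[[i]], sets[[j]])
        if (length(ov) > 0) {
          stop("catalog declared disjoint but sets '", nm[j], "' and '",
               nm[i], "' share members: ",
               paste(utils::head(ov, 5), collapse = ", "))
        }
      }
    }
  }
  structure(list(sets = sets, disjoint = isTRUE(disjoint)),
            class = "sector_catalog")
}

#' @export
print.sector_catalog <- function(x, ...) {
  cat(sprintf("<sector_catalog> %d sets%s\n", length(x$sets),
              if (x$disjoint) " (disjoint)" else ""))
  for (nm in utils::head(names(x$sets), 12)) {
    cat(sprintf("  %s: %d members\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' case-normalized and deduplicated within each set; blank lines are ignored;
#' an empty file yields an empty catalog.
#'
#' @param path Path to a GMT file.
#' @param disjoint Declare the catalog as a partition (validated).
#' @return A [sector_catalog()]. Set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path, disjoint = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  descs <- character(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    sets[[fields[1]]] <- fields[-(1:2)]
    descs[fields[1]] <- fields[2]
  }
  cat_out <- sector_catalog(sets, disjoint = disjoint)
  attr(cat_out, "descriptions") <- descs
  cat_out
}

#' Write a sector catalog to a GMT file
#'
#' @param catalog A [sector_catalog()].
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(catalog, "descriptions")
  lines <- vapply(names(catalog$sets), function(nm) {
    desc <- descriptions[nm]
    if (is.null(desc) || is.na(desc)) desc <- nm
    paste(c(nm, desc, catalog$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
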