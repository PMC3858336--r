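#' Read a blood-count CSV
#'
#' Expected header: `animal_id,genotype,experiment_id[,strain,age_months],
#' <phenotype...>`.  Phenotype columns must parse as numbers; malformed
#' values are reported with their row numbers rather than coerced to NA.
#'
#' @param path file path.
#' @return a `blood_counts` data frame.
#' @export
read_counts_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  required <- c("animal_id", "genotype", "experiment_id")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$animal_id)) {
    stop("duplicate animal_id: ",
         paste(unique(d$animal_id[duplicated(d$animal_id)]), collapse = ", "),
         call. = FALSE)
  }
  meta <- c(required, intersect(c("strain", "age_months"), names(d)))
  pheno <- setdiff(names(d), meta)
  if (length(pheno) == 0) stop("no phenotype column found", call. = FALSE)
  for (col in c(pheno, intersect("age_months", names(d)))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    d[[col]] <- v
  }
  attr(d, "log_base") <- "e"
  class(d) <- c("blood_counts", "data.frame")
  d
}

#' Write a blood-count dataset as CSV
#' @param dataset a `blood_counts` data frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write GCT 1.2 expression matrices
#'
#' GCT 1.2: line 1 `#1.2`, line 2 `<n_genes>\t<n_samples>`, then a
#' tab-separated table with `Name`, `Description` and one column per
#' sample.  The declared dimensions are validated against the body.
#'
#' @param path file path.
#' @return for `read_gct`, a numeric matrix (genes x samples) with the
#'   probe descriptions in `attr(, "description")`.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
    stop("not a GCT 1.2 file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  body <- utils::read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2]) {
    stop(sprintf("GCT dimension mismatch: declared %d x %d, found %d x %d",
                 dims[1], dims[2], nrow(body), ncol(body) - 2L),
         call. = FALSE)
  }
  m <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in GCT body", call. = FALSE)
  rownames(m) <- body[[1]]
  attr(m, "description") <- body[[2]]
  m
}

#' @rdname read_gct
#' @param expr an [expr_matrix()] or numeric matrix with dimnames.
#' @export
write_gct <- function(expr, path) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  body <- data.frame(Name = rownames(m), Description = "na",
                     m, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CLS class-label files
#'
#' Categorical CLS: line 1 `<n> <n_classes> 1`, line 2 `# <name...>`,
#' line 3 the space-separated labels (names or 0-based indices).
#'
#' @param path file path.
#' @return for `read_cls`, a character vector of class labels.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated CLS file", call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  names_line <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(labels) != hdr[1]) {
    stop("CLS declares ", hdr[1], " samples but lists ", length(labels),
         call. = FALSE)
  }
  if (all(grepl("^[0-9]+$", labels))) {
    labels <- names_line[as.integer(labels) + 1L]
  } else if (!all(labels %in% names_line)) {
    stop("unknown class label(s) in CLS: ",
         paste(setdiff(labels, names_line), collapse = ", "), call. = FALSE)
  }
  labels
}

#' @rdname read_cls
#' @param labels character vector of class labels.
#' @export
write_cls <- function(labels, path) {
  lev <- unique(labels)
  writeLines(c(paste(length(labels), length(lev), 1),
               paste("#", paste(lev, collapse = " ")),
               paste(match(labels, lev) - 1L, collapse = " ")),
             path)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are removed with a warning; empty set
#' lines are an error.
#'
#' @param path file path.
#' @return for `read_gmt`, a named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line ", i, " has no genes (set '", f[1], "')", call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene id(s) in set '", f[1], "' removed",
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a design mapping (role -> genotype label) from YAML or JSON
#'
#' The file must provide entries for all four roles `WT0`, `CM1`, `CP2`,
#' `TH3`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an [epistasis_design()].
#' @export
read_design_yaml <- function(path) {
  d <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  roles <- c("WT0", "CM1", "CP2", "TH3")
  missing_roles <- setdiff(roles, names(d))
  if (length(missing_roles)) {
    stop("design file missing role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  epistasis_design(WT0 = d$WT0, CM1 = d$CM1, CP2 = d$CP2, TH3 = d$TH3)
}

#' Write the sample-annotation table of an expression matrix as TSV
#' @param expr an [expr_matrix()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(expr, path) {
  utils::write.table(expr$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
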