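#' Construct and validate an expression matrix
#'
#' The shared container for one ome's feature-by-sample measurements.
#' Transcript matrices hold nonnegative integer read counts with no missing
#' cells (a zero is a true zero). Protein matrices hold nonnegative
#' intensities in which `NA` marks "not detected" — absence of an
#' intensity-based MS measurement, not a zero.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param ome `"transcript"` or `"protein"`.
#' @param feature_length_bp optional named (or positionally matched) positive
#'   integer vector of feature lengths in base pairs; required for FPKM,
#'   transcripts only.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `ome`, `feature_length_bp`.
#' @export
expression_matrix <- function(values, ome = c("transcript", "protein"),
                              feature_length_bp = NULL) {
  ome <- match.arg(ome)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (ome == "transcript") {
    if (anyNA(values)) stop("missing values are not permitted in a transcript matrix")
    if (any(values < 0)) stop("negative counts")
    if (any(values != round(values))) stop("transcript counts must be integers")
  } else {
    if (any(values < 0, na.rm = TRUE)) stop("negative intensities")
  }
  if (!is.null(feature_length_bp)) {
    if (ome != "transcript") stop("feature lengths apply to transcript matrices only")
    if (length(feature_length_bp) != nrow(values)) {
      stop("feature_length_bp must have one entry per feature")
    }
    if (anyNA(feature_length_bp) || any(feature_length_bp <= 0)) {
      stop("feature lengths must be positive")
    }
    feature_length_bp <- stats::setNames(as.numeric(feature_length_bp),
                                         rownames(values))
  }
  structure(list(values = values, ome = ome,
                 feature_length_bp = feature_length_bp),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples",
              x$ome, nrow(x$values), ncol(x$values)))
  if (x$ome == "protein") {
    cat(sprintf(", %.1f%% missing", 100 * mean(is.na(x$values))))
  }
  cat("\n")
  invisible(x)
}

#' Construct a case/control cohort design
#'
#' @param assignments named character vector mapping sample id to group,
#'   each group one of `"case"` or `"control"`.
#' @return object of class `cohort_design` (the validated named vector).
#' @export
cohort_design <- function(assignments) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by sample id")
  }
  assignments <- as.character(assignments) |>
    stats::setNames(names(assignments))
  if (!all(assignments %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  if (sum(assignments == "case") < 2 || sum(assignments == "control") < 2) {
    stop("need at least 2 samples per group")
  }
  structure(assignments, class = "cohort_design")
}

#' @rdname cohort_design
#' @param design a `cohort_design`.
#' @param group `"case"` or `"control"`.
#' @return `design_samples()`: the sample ids belonging to `group`.
#' @export
design_samples <- function(design, group) {
  names(design)[unclass(design) == group]
}

check_design_covers <- function(mat, design) {
  missing <- setdiff(colnames(mat$values), names(design))
  if (length(missing)) {
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a gene-set collection
#'
#' @param sets a list; each element a list with `name` (string), `category`
#'   (one of `"cellular_component"`, `"biological_process"`,
#'   `"functional_group"`) and `members` (character vector of feature ids).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  cats <- c("cellular_component", "biological_process", "functional_group")
  for (s in sets) {
    if (!all(c("name", "category", "members") %in% names(s))) {
      stop("each set needs name, category and members")
    }
    if (!s$category %in% cats) stop("unknown category: ", s$category)
    if (length(s$members) == 0) stop("set '", s$name, "' has no members")
  }
  key <- vapply(sets, function(s) paste(s$category, s$name), "")
  if (anyDuplicated(key)) stop("duplicate set names within a category")
  names(sets) <- vapply(sets, `[[`, "", "name")
  structure(sets, class = "gene_set_collection")
}

#' Read an expression matrix from TSV
#'
#' Layout: header row of sample ids; first column `feature_id`; optional
#' second column `length_bp` (transcripts only); remaining columns one per
#' sample. `NA` cells denote "not detected" and are permitted only for
#' proteins. Plain or gzipped files are accepted.
#'
#' @param path TSV (optionally `.gz`) file path.
#' @param ome `"transcript"` or `"protein"`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, ome = c("transcript", "protein")) {
  ome <- match.arg(ome)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  if (ncol(df) < 2) stop("expected feature_id plus at least one sample column")
  ids <- as.character(df[[1]])
  lengths <- NULL
  first_data <- 2L
  if (names(df)[2] == "length_bp") {
    lengths <- df[[2]]
    first_data <- 3L
  }
  vals <- as.matrix(df[, first_data:ncol(df), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  expression_matrix(vals, ome = ome, feature_length_bp = lengths)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; protein missing values are written
#' as `NA`, reals at full precision so that a round trip is exact.
#'
#' @param mat an `expression_matrix`.
#' @param path output file (".gz" suffix writes gzipped).
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(mat$feature_length_bp)) df$length_bp <- mat$feature_length_bp
  vals <- mat$values
  df <- cbind(df, as.data.frame(format(vals, digits = 17, trim = TRUE,
                                       scientific = FALSE)))
  names(df)[(ncol(df) - ncol(vals) + 1):ncol(df)] <- colnames(vals)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a cohort design TSV (`sample_id<TAB>group`)
#' @param path file path.
#' @return a [cohort_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("design file needs columns sample_id and group")
  }
  cohort_design(stats::setNames(df$group, df$sample_id))
}

#' @rdname read_design
#' @param design a `cohort_design`.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = names(design), group = unclass(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>member...`.
#' When the description equals a known category token
#' (`cellular_component`, `biological_process`, `functional_group`) it is
#' stored as the set's category; anything else is treated as
#' `functional_group`.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cats <- c("cellular_component", "biological_process", "functional_group")
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with empty member list: ", parts[1])
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("GMT line with empty member list: ", parts[1])
    list(name = parts[1],
         category = if (parts[2] %in% cats) parts[2] else "functional_group",
         members = unique(members))
  })
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1])
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param sets a `gene_set_collection`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$category, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write stage outputs as deterministic TSV tables plus a JSON run summary
#'
#' Each data frame in `results` is written as `<name>.tsv` with a header row
#' (an empty table yields a header-only file). A `summary.json` capturing
#' `params` (thresholds, seeds) is written alongside, under schema
#' `concordia_summary_v1`. Output is byte-identical for identical input.
#'
#' @param results named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param params named list of run parameters recorded in the summary.
#' @return invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir, params = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(is.list(results), !is.null(names(results)))
  paths <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    stopifnot(is.data.frame(df))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(format_table_for_output(df), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  summary <- list(schema = "concordia_summary_v1",
                  params = params,
                  tables = as.list(stats::setNames(
                    vapply(results, nrow, 0L), names(results))))
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}

# Full-precision, locale-independent numeric formatting for TSV output.
format_table_for_output <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17)
      }, "")
    }
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), "")
    }
  }
  df
}
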