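#' Assemble a run configuration
#'
#' All pipeline thresholds in one validated object. Defaults are the study's
#' printed constants: q-value threshold 0.05, transcript fold-change minimum
#' 2, direction cuts 1.1/0.9, per-group detection minimum 5, term-merge
#' Jaccard 0.5.
#'
#' @param alpha q-value significance threshold.
#' @param fc_min transcript linear fold-change threshold.
#' @param up_cut,down_cut direction-classification cuts.
#' @param min_detect per-group detection minimum for set-level analysis.
#' @param jaccard term-merge Jaccard threshold.
#' @param scenario a [synthetic_scenario()] to simulate from, or NULL when
#'   `inputs` point at files on disk.
#' @param inputs named list of paths (`counts`, `proteins`, `design`, `gmt`)
#'   read when no scenario is given.
#' @param out_dir output directory, or NULL to skip writing.
#' @param seed integer seed recorded in the summary and used by simulation.
#' @return object of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, fc_min = 2, up_cut = 1.1,
                       down_cut = 0.9, min_detect = 5, jaccard = 0.5,
                       scenario = NULL, inputs = NULL, out_dir = NULL,
                       seed = 1L) {
  stopifnot(alpha > 0, fc_min > 0, min_detect >= 0, jaccard > 0,
            up_cut > 1, down_cut < 1, down_cut > 0)
  if (is.null(scenario) && is.null(inputs)) {
    stop("either a scenario or input paths are required")
  }
  structure(list(alpha = alpha, fc_min = fc_min, up_cut = up_cut,
                 down_cut = down_cut, min_detect = min_detect,
                 jaccard = jaccard, scenario = scenario, inputs = inputs,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

read_pipeline_inputs <- function(inputs) {
  for (nm in c("counts", "proteins", "design", "gmt")) {
    if (is.null(inputs[[nm]])) stop("input stage failed: missing '", nm, "' path")
    if (!file.exists(inputs[[nm]])) {
      stop("input stage failed: file not found: ", inputs[[nm]])
    }
  }
  list(transcripts = read_expression_matrix(inputs$counts, "transcript"),
       proteins = read_expression_matrix(inputs$proteins, "protein"),
       design = read_design(inputs$design),
       sets = read_gmt(inputs$gmt))
}

stage <- function(name, expr) {
  message("[", name, "] started")
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  out
}

#' Run the full concordance pipeline
#'
#' simulate (or load) -> differential expression per ome -> binomial
#' over-representation of the up/down lists against the detected reference ->
#' functional-group concordance and coupling. Every stage is logged with its
#' row counts; when `out_dir` is set, all tables, a `summary.json` and a
#' markdown report are written and the run is byte-reproducible from the
#' same config and seed.
#'
#' @param config a [run_config()].
#' @return list with `de_transcript`, `de_protein`, `enrichment` (per ome and
#'   direction, raw + merged), `summary` ([build_summary()] output) and
#'   `data` (the input bundle).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- if (!is.null(config$scenario)) {
    stage("simulate", generate_cohort(config$scenario))
  } else {
    stage("load", read_pipeline_inputs(config$inputs))
  }
  message("  ", nrow(data$transcripts$values), " transcripts, ",
          nrow(data$proteins$values), " proteins, ",
          length(data$design), " samples, ", length(data$sets), " sets")

  de_t <- stage("diffexp_transcript",
                transcript_de(data$transcripts, data$design,
                              alpha = config$alpha, fc_min = config$fc_min))
  de_p <- stage("diffexp_protein",
                protein_de(data$proteins, data$design, alpha = config$alpha))
  message("  significant: ", sum(de_t$significant), " transcripts, ",
          sum(de_p$significant), " proteins")

  enr <- stage("enrichment", {
    one_ome <- function(de) {
      ref <- de$feature_id
      lapply(c(up = "up", down = "down"), function(dir) {
        ids <- de$feature_id[de$direction == dir]
        if (!length(ids)) {
          rows <- binomial_ora(character(0), ref, data$sets)
        } else {
          rows <- binomial_ora(ids, ref, data$sets)
        }
        list(rows = rows,
             merged = merge_redundant_terms(rows, config$jaccard))
      })
    }
    list(transcript = one_ome(de_t), protein = one_ome(de_p))
  })

  summary <- stage("concordance",
                   build_summary(de_t, de_p, data$sets,
                                 alpha = config$alpha,
                                 min_detect = config$min_detect))

  result <- list(de_transcript = de_t, de_protein = de_p, enrichment = enr,
                 summary = summary, data = data)
  if (!is.null(config$out_dir)) {
    stage("write", write_pipeline_outputs(result, config))
  }
  result
}

drop_members_col <- function(df) df[, setdiff(names(df), "members"),
                                    drop = FALSE]

write_pipeline_outputs <- function(result, config) {
  tables <- list(
    de_transcript = result$de_transcript,
    de_protein = result$de_protein,
    concordance_transcript = result$summary$concordance_transcript,
    concordance_protein = result$summary$concordance_protein,
    coupling = result$summary$coupling,
    global = result$summary$global)
  for (ome in names(result$enrichment)) {
    for (dir in names(result$enrichment[[ome]])) {
      tables[[paste("enrichment", ome, dir, sep = "_")]] <-
        drop_members_col(result$enrichment[[ome]][[dir]]$rows)
      tables[[paste("enrichment", ome, dir, "merged", sep = "_")]] <-
        result$enrichment[[ome]][[dir]]$merged
    }
  }
  params <- config[c("alpha", "fc_min", "up_cut", "down_cut", "min_detect",
                     "jaccard", "seed")]
  if (!is.null(config$scenario)) params$scenario_seed <- config$scenario$seed
  paths <- write_results_tables(tables, config$out_dir, params = params)
  report <- c("# Concordance pipeline report", "",
              "## Global direction summary", "",
              knit_table(result$summary$global), "",
              "## Functional-group concordance (transcripts)", "",
              knit_table(result$summary$concordance_transcript), "",
              "## Functional-group concordance (proteins)", "",
              knit_table(result$summary$concordance_protein), "",
              "## Transcript-protein coupling", "",
              knit_table(result$summary$coupling), "")
  writeLines(report, file.path(config$out_dir, "report.md"))
  invisible(paths)
}

# Minimal fixed-format markdown table (no dependency on knitr).
knit_table <- function(df) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      fmt[[j]] <- signif(fmt[[j]], 4)
    }
  }
  cells <- rbind(names(fmt), apply(fmt, 2, as.character))
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  append(rows, paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|"),
         after = 1)
}
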