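#' Score a cohort: MAPI plus keystone, merged with metadata
#'
#' Runs MAPI and keystone scoring over one cohort and joins the per-sample
#' metadata, producing the canonical score table used by the comparison
#' helpers and written by the pipeline.
#'
#' @param cohort A \code{cohort_table}.
#' @param aerotolerance An \code{aerotolerance_table}
#'   (default: bundled starter table).
#' @param panel Keystone panel binomials.
#' @param mapi_pseudocount,keystone_pseudocount See
#'   \code{\link{compute_mapi}} and \code{\link{keystone_zscores}}.
#' @return Data frame with columns \code{sample_id}, \code{mapi},
#'   \code{aero_mass}, \code{anaero_mass}, \code{unclassified_mass},
#'   \code{pseudocount_used}, \code{keystone}, \code{phenotype},
#'   \code{age}, \code{age_bin}, \code{gender}, \code{error}.
#' @export
score_cohort <- function(cohort,
                         aerotolerance = load_classification(),
                         panel = default_keystone_panel(),
                         mapi_pseudocount = 1e-6,
                         keystone_pseudocount = 1e-6) {
  stopifnot(inherits(cohort, "cohort_table"))
  scores <- mapi_batch(cohort, aerotolerance, mapi_pseudocount)
  ks <- keystone_batch(cohort, panel, keystone_pseudocount)
  scores$keystone <- ks$keystone[match(scores$sample_id, ks$sample_id)]
  md <- cohort$metadata
  idx <- match(scores$sample_id, md$sample_id)
  scores$phenotype <- md$phenotype[idx]
  scores$age <- md$age[idx]
  scores$age_bin <- if ("age_bin" %in% names(md)) md$age_bin[idx]
                    else age_bin(md$age[idx])
  scores$gender <- md$gender[idx]
  scores[c("sample_id", "mapi", "aero_mass", "anaero_mass",
           "unclassified_mass", "pseudocount_used", "keystone",
           "phenotype", "age", "age_bin", "gender", "error")]
}

#' Pipeline run configuration
#'
#' Either \code{input} (a list with \code{table}, \code{dialect},
#' \code{orientation} and optionally \code{metadata}) or \code{simulate}
#' (a \code{\link{sim_config}}) must be given. Referenced paths are
#' validated before any computation.
#'
#' @param input List describing an on-disk abundance table, or \code{NULL}.
#' @param simulate A \code{sim_config} to generate the cohort, or
#'   \code{NULL}.
#' @param aerotolerance_table Path to the classification TSV.
#' @param keystone_panel Path to a panel file, or \code{NULL} for the
#'   default six species.
#' @param lexicon Path to a condition-lexicon TSV, or \code{NULL} for the
#'   bundled terms.
#' @param mapi_pseudocount,keystone_pseudocount Pseudocounts.
#' @param compare_by Grouping field for the comparison stage.
#' @param compare_scheme \code{"omnibus"} or \code{"pairwise_fdr"}.
#' @param compare_value Score column compared (\code{"mapi"} or
#'   \code{"keystone"}).
#' @param out_dir Output directory (created if absent).
#' @return A validated \code{run_config}.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       aerotolerance_table = default_aerotolerance_path(),
                       keystone_panel = NULL, lexicon = NULL,
                       mapi_pseudocount = 1e-6, keystone_pseudocount = 1e-6,
                       compare_by = "phenotype", compare_scheme = "omnibus",
                       compare_value = "mapi", out_dir = "gutindices_run") {
  if (is.null(input) == is.null(simulate)) {
    gi_error("exactly one of input or simulate must be set", "config_error")
  }
  paths <- c(aerotolerance_table, keystone_panel, lexicon,
             if (!is.null(input)) c(input$table, input$metadata))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    gi_error(sprintf("missing input files: %s",
                     paste(missing, collapse = ", ")), "config_error")
  }
  structure(list(
    input = input, simulate = simulate,
    aerotolerance_table = aerotolerance_table,
    keystone_panel = keystone_panel, lexicon = lexicon,
    mapi_pseudocount = mapi_pseudocount,
    keystone_pseudocount = keystone_pseudocount,
    compare_by = compare_by, compare_scheme = compare_scheme,
    compare_value = compare_value, out_dir = out_dir
  ), class = "run_config")
}

format_score_table <- function(scores, digits = 6) {
  out <- scores
  for (col in c("mapi", "keystone")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         formatC(out[[col]], digits = digits, format = "f"))
  }
  out
}

#' Run the end-to-end pipeline
#'
#' Read or simulate a cohort, classify and score it, bin phenotypes from
#' reported conditions, run the configured comparison, and write four
#' outputs into \code{out_dir}: \code{scores.tsv}, \code{results.tsv},
#' \code{group_summary.tsv} and \code{run.log}. Outputs are written to
#' temporary files and renamed into place, so a failed run leaves no
#' partial outputs; reruns with identical config and inputs produce
#' byte-identical tables. The run log records the package version, a
#' config hash and sample exclusion counts.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the score table, the comparison results
#'   and the group summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      gi_error(sprintf("[%s] %s", name, conditionMessage(e)),
               "pipeline_error")
    })
  }
  cohort <- stage("read", {
    if (!is.null(config$simulate)) {
      generate_cohort(config$simulate)
    } else {
      ct <- read_abundance_table(config$input$table,
                                 dialect = config$input$dialect %||% "plain",
                                 orientation = config$input$orientation %||%
                                   "taxa_rows")
      if (!is.null(config$input$metadata)) {
        md <- read_metadata(config$input$metadata)
        ct$metadata <- validate_metadata(md, colnames(ct$abundance))
      }
      ct
    }
  })
  lex <- stage("lexicon", {
    if (is.null(config$lexicon)) condition_lexicon()
    else read_condition_lexicon(config$lexicon)
  })
  cohort <- stage("phenotype", annotate_cohort(cohort, lex, quiet = TRUE))
  aerotab <- stage("aerotolerance",
                   load_classification(config$aerotolerance_table))
  panel <- stage("panel", {
    if (is.null(config$keystone_panel)) default_keystone_panel()
    else read_keystone_panel(config$keystone_panel)
  })
  scores <- stage("score", score_cohort(
    cohort, aerotab, panel,
    mapi_pseudocount = config$mapi_pseudocount,
    keystone_pseudocount = config$keystone_pseudocount
  ))
  results <- stage("compare", compare_by_bins(
    scores, bin_field = config$compare_by, scheme = config$compare_scheme,
    value = config$compare_value, quiet = TRUE
  ))
  summaries <- stage("summary", group_summary(
    scores, bin_field = config$compare_by, value = config$compare_value
  ))

  stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_atomically <- function(df, name) {
      final <- file.path(config$out_dir, name)
      tmp <- paste0(final, ".tmp")
      utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      file.rename(tmp, final)
    }
    write_atomically(format_score_table(scores), "scores.tsv")
    write_atomically(results, "results.tsv")
    write_atomically(summaries, "group_summary.tsv")
    n_unknown <- sum(scores$phenotype == "unknown", na.rm = TRUE)
    n_failed <- sum(!is.na(scores$error))
    log_lines <- c(
      sprintf("gutindices %s",
              as.character(utils::packageVersion("gutindices"))),
      sprintf("config_hash: %s", config_hash(config)),
      sprintf("samples: %d", nrow(scores)),
      sprintf("excluded_unknown_phenotype: %d", n_unknown),
      sprintf("excluded_score_failures: %d", n_failed),
      sprintf("comparison: %s by %s on %s", config$compare_scheme,
              config$compare_by, config$compare_value)
    )
    final <- file.path(config$out_dir, "run.log")
    writeLines(log_lines, paste0(final, ".tmp"))
    file.rename(paste0(final, ".tmp"), final)
  })
  invisible(list(scores = scores, results = results, summaries = summaries))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
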