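#' Configuration for the end-to-end screening pipeline
#'
#' Exactly one input source must be given: `input` (a child-level
#' questionnaire file), `counts` (an aggregate condition-by-score table,
#' which skips the child-level stages), or `simulate` (a
#' [cohort_params()] object).
#'
#' @param input Path to a child-level file for [read_children()].
#' @param counts Path to a stratum count file for [read_stratum_table()].
#' @param simulate A [cohort_params()] object.
#' @param pretest Pretest DLD probability (default 0.12).
#' @param min_count Sparse-stratum collapsing threshold (default 5).
#' @param direction Stepwise direction (default "both").
#' @param seed Integer seed; overrides `simulate$seed` when simulating.
#' @param out_dir Output directory (created if absent).
#' @param formats Report formats, subset of c("csv", "json").
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, counts = NULL, simulate = NULL,
                            pretest = 0.12, min_count = 5L,
                            direction = "both", seed = 1L,
                            out_dir = tempfile("dldscreen_"),
                            formats = c("csv", "json")) {
  n_src <- sum(!is.null(input), !is.null(counts), !is.null(simulate))
  if (n_src != 1L) {
    stop("exactly one of input, counts or simulate must be given",
         call. = FALSE)
  }
  if (!(pretest > 0 && pretest < 1)) {
    stop("pretest must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(all(formats %in% c("csv", "json")))
  out <- list(input = input, counts = counts, simulate = simulate,
              pretest = pretest, min_count = as.integer(min_count),
              direction = direction, seed = as.integer(seed),
              out_dir = out_dir, formats = formats)
  class(out) <- "pipeline_config"
  out
}

.write_formats <- function(report, out_dir, stem, formats) {
  paths <- character()
  for (fmt in formats) {
    p <- file.path(out_dir, paste0(stem, ".", fmt))
    write_report(as.data.frame(report), p)
    paths <- c(paths, p)
  }
  paths
}

#' Run the full screening-utility pipeline
#'
#' Orchestrates the stages in analysis order: acquire a cohort (read,
#' simulate, or take aggregate counts), code risk perceptions and concern
#' scores, compare questions between conditions, select questions by
#' stepwise AIC, evaluate the selected model and the raw 0-4 score by
#' ROC, build the condition-by-score stratum table (collapsing sparse
#' strata), and report SSLRs with pretest-to-posttest probability
#' updates. With aggregate counts as input only the utility stage runs.
#' All outputs are written under `config$out_dir` along with a
#' `manifest.json` recording the seed, counts and exclusions; the same
#' config and seed always produce an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `comparison`, `model`, `roc_model`, `roc_score`,
#'   `utility`, `manifest`) and the written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  manifest <- list(seed = config$seed, pretest = config$pretest,
                   min_count = config$min_count,
                   package_version = as.character(
                     utils::packageVersion("dldscreen")))

  if (!is.null(config$counts)) {
    tab <- read_stratum_table(config$counts)
    tab <- collapse_sparse(tab, config$min_count)
    util <- utility_report(tab, pretest = config$pretest)
    files <- c(files, .write_formats(util, config$out_dir, "utility",
                                     config$formats))
    manifest$input <- config$counts
    manifest$n_dld <- tab$d_total; manifest$n_tld <- tab$t_total
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(utility = util, manifest = manifest,
                          files = c(files,
                                    file.path(config$out_dir,
                                              "manifest.json")))))
  }

  cohort <- if (!is.null(config$input)) {
    manifest$input <- config$input
    read_children(config$input)
  } else {
    sim <- config$simulate
    sim$seed <- config$seed
    manifest$input <- "simulated"
    generate_cohort(sim)
  }
  if (anyNA(cohort$condition)) {
    stop("pipeline stage 'code': condition must be known for every child",
         call. = FALSE)
  }
  coded <- code_records(cohort)
  files <- c(files, .write_formats(coded, config$out_dir, "children_coded",
                                   "csv"))
  manifest$n_children <- nrow(coded)
  manifest$n_score4_missing <- sum(is.na(coded$score4))

  comparison <- compare_questions(coded)
  files <- c(files, .write_formats(comparison, config$out_dir, "comparison",
                                   config$formats))

  Xq <- coded[, paste0("risk", 1:8)]
  keep <- stats::complete.cases(Xq)
  model <- stepwise_aic(coded$condition[keep], Xq[keep, , drop = FALSE],
                        direction = config$direction)
  manifest$selected_terms <- model$selected
  files <- c(files, .write_formats(
    if (length(model$selected)) model_report(model)
    else data.frame(term = "(Intercept)", beta = unname(model$beta)),
    config$out_dir, "model", config$formats))

  roc_model <- if (length(model$selected)) {
    roc_auc(model$fitted, coded$condition[keep])
  } else NULL
  keep4 <- !is.na(coded$score4)
  roc_score <- roc_auc(coded$score4[keep4], coded$condition[keep4])
  manifest$auc_model <- if (!is.null(roc_model)) roc_model$auc else NA
  manifest$auc_score4 <- roc_score$auc
  files <- c(files, .write_formats(roc_coordinates(roc_score),
                                   config$out_dir, "roc_score4", "csv"))
  if (!is.null(roc_model)) {
    files <- c(files, .write_formats(roc_coordinates(roc_model),
                                     config$out_dir, "roc_model", "csv"))
  }

  tab <- stratum_table_from_scores(coded$score4, coded$condition)
  tab <- collapse_sparse(tab, config$min_count)
  util <- utility_report(tab, pretest = config$pretest)
  files <- c(files, .write_formats(util, config$out_dir, "utility",
                                   config$formats))

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, comparison = comparison, model = model,
                 roc_model = roc_model, roc_score = roc_score,
                 utility = util, manifest = manifest,
                 files = c(files, mpath)))
}
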