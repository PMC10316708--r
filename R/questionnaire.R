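#' Parental linguistic concern questionnaire (PLCQ) schema
#'
#' The PLCQ consists of eight yes/no questions about a child's language.
#' An answer signals parental concern ("risk perception") when it is "yes"
#' for questions 1, 2, 4, 5, 7 and 8, and "no" for questions 3 and 6 (those
#' two are phrased positively, e.g. "Does your child talk as well as other
#' children of the same age?"). Questions 1, 2, 5 and 8 form the reduced
#' four-item concern score. The schema is shipped as a static file so that
#' column order in data files can never silently permute the coding rule.
#'
#' @return A data.frame with columns `question` (1-8), `column` (the header
#'   name expected in data files, `q1`..`q8`), `risk_when` ("yes" or "no"),
#'   `in_score4` (logical; membership in the reduced score) and `text`.
#' @export
plcq_schema <- function() {
  path <- system.file("extdata", "plcq_schema.csv", package = "dldscreen",
                      mustWork = TRUE)
  sch <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(sch$question, 1:8),
            all(sch$risk_when %in% c("yes", "no")))
  sch$in_score4 <- as.logical(sch$in_score4)
  sch
}

.plcq_risk_when <- function() plcq_schema()$risk_when

#' Names of the BECQ variables
#'
#' The biological and environmental conditions questionnaire (BECQ) holds
#' eleven variables: child sex, three binary problem flags (motor,
#' neurological, psychological), age of first words (months), maternal and
#' paternal education (years), family history of language problems,
#' preschool attendance (years), and daily social interaction, communicative
#' interaction and screen time (hours).
#'
#' @return Character vector `becq9`..`becq20`.
#' @export
becq_columns <- function() paste0("becq", 9:20)

# normalise a ternary answer vector to "yes"/"no"/NA
.normalize_answers <- function(answers) {
  if (is.logical(answers)) {
    return(ifelse(is.na(answers), NA_character_, ifelse(answers, "yes", "no")))
  }
  a <- tolower(trimws(as.character(answers)))
  a[a %in% c("", "na", "missing")] <- NA_character_
  a[a %in% c("y", "1", "true", "si", "sí")] <- "yes"
  a[a %in% c("n", "0", "false")] <- "no"
  bad <- !is.na(a) & !(a %in% c("yes", "no"))
  if (any(bad)) {
    stop("non-ternary PLCQ answer(s): ",
         paste(unique(answers[bad]), collapse = ", "), call. = FALSE)
  }
  a
}

#' Code the eight PLCQ answers as risk perceptions
#'
#' Applies the risk-perception rule: "yes" counts as risk for questions
#' 1, 2, 4, 5, 7, 8 and "no" counts as risk for questions 3 and 6. Missing
#' answers stay missing and never count as risk. The cumulative concern
#' scores are the number of risk perceptions over all eight questions
#' (`score8`) and over the reduced item set {1, 2, 5, 8} (`score4`).
#'
#' @param answers A length-8 vector of answers in question order 1-8:
#'   "yes"/"no" (case-insensitive; logical also accepted), with `NA` for a
#'   missing answer.
#' @return An object of class `risk_vector`: a list with `risk` (logical
#'   length 8, `NA` where the answer was missing), `score8`, `score4`, and
#'   `complete4`/`complete8` flags indicating that no contributing answer
#'   was missing.
#' @examples
#' code_risk(c("yes","yes","no","no","yes","yes","no","yes"))
#' @export
code_risk <- function(answers) {
  if (length(answers) != 8L) {
    stop("expected exactly 8 PLCQ answers, got ", length(answers),
         call. = FALSE)
  }
  a <- .normalize_answers(answers)
  risk_when <- .plcq_risk_when()
  risk <- ifelse(is.na(a), NA, a == risk_when)
  in4 <- plcq_schema()$in_score4
  out <- list(
    risk = risk,
    score8 = sum(risk, na.rm = TRUE),
    score4 = sum(risk[in4], na.rm = TRUE),
    complete8 = !anyNA(risk),
    complete4 = !anyNA(risk[in4])
  )
  class(out) <- "risk_vector"
  out
}

#' @export
print.risk_vector <- function(x, ...) {
  cat("PLCQ risk vector\n")
  cat("  risk perceptions:",
      paste(ifelse(is.na(x$risk), ".", ifelse(x$risk, "R", "-")),
            collapse = " "), "\n")
  cat("  score (0-8):", x$score8,
      if (!x$complete8) "[incomplete]" else "", "\n")
  cat("  score (0-4, items 1,2,5,8):", x$score4,
      if (!x$complete4) "[incomplete]" else "", "\n")
  invisible(x)
}

#' Code PLCQ answers for a whole cohort
#'
#' Vectorized risk coding over a cohort data.frame. Adds risk indicator
#' columns `risk1`..`risk8` plus the cumulative scores. Children with any
#' missing answer among items {1, 2, 5, 8} get `score4 = NA` (listwise
#' exclusion downstream); likewise `score8` for any missing answer.
#'
#' @param children A cohort data.frame with answer columns `q1`..`q8`
#'   (see [read_children()]).
#' @return The input data.frame with columns `risk1`..`risk8` (logical),
#'   `score4` and `score8` appended (`NA` when incomplete).
#' @export
code_records <- function(children) {
  sch <- plcq_schema()
  miss <- setdiff(sch$column, names(children))
  if (length(miss)) {
    stop("cohort is missing PLCQ columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  risk <- matrix(NA, nrow(children), 8L)
  for (i in 1:8) {
    a <- .normalize_answers(children[[sch$column[i]]])
    risk[, i] <- ifelse(is.na(a), NA, a == sch$risk_when[i])
  }
  colnames(risk) <- paste0("risk", 1:8)
  in4 <- sch$in_score4
  score8 <- ifelse(rowSums(is.na(risk)) > 0, NA_integer_, rowSums(risk))
  score4 <- ifelse(rowSums(is.na(risk[, in4, drop = FALSE])) > 0,
                   NA_integer_, rowSums(risk[, in4, drop = FALSE]))
  cbind(children, as.data.frame(risk), score4 = score4, score8 = score8)
}

#' Dichotomize a continuous variable at the within-age-group median
#'
#' Splits a per-child value into "less than or equal to the median" versus
#' "greater than the median" within each age group, the rule used for
#' preschool-attendance years (medians 1.5, 2.5 and 3.5 years for 4-, 5-
#' and 6-year-olds). A value exactly equal to the median goes to the
#' "<= median" class. Medians may be supplied or computed from the cohort.
#'
#' @param values Numeric vector, one value per child (`NA` = missing, the
#'   child is flagged missing and excluded downstream).
#' @param age_group Integer vector of the same length, values in {4, 5, 6}.
#' @param medians Optional named numeric vector of per-age cut points, e.g.
#'   `c("4" = 1.5, "5" = 2.5, "6" = 3.5)`. When `NULL`, the median of the
#'   non-missing values within each age group is used.
#' @return A factor with levels `c("le_median", "gt_median")` (`NA` where
#'   the value is missing), with the cut points in `attr(, "medians")`.
#' @export
dichotomize_by_age_median <- function(values, age_group, medians = NULL) {
  stopifnot(length(values) == length(age_group))
  age_group <- as.integer(age_group)
  ages <- sort(unique(age_group))
  if (is.null(medians)) {
    medians <- vapply(ages, function(a) {
      stats::median(values[age_group == a], na.rm = TRUE)
    }, numeric(1))
    names(medians) <- as.character(ages)
  }
  absent <- setdiff(as.character(ages), names(medians))
  if (length(absent)) {
    stop("no median defined for age group(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cut_at <- unname(medians[as.character(age_group)])
  out <- factor(ifelse(is.na(values), NA,
                       ifelse(values <= cut_at, "le_median", "gt_median")),
                levels = c("le_median", "gt_median"))
  attr(out, "medians") <- medians
  out
}

.child_columns <- function() {
  c("child_id", "age_group", "condition", paste0("q", 1:8), becq_columns())
}

#' Validate a cohort data.frame
#'
#' Checks the header contract (`child_id`, `age_group`, `condition`,
#' `q1`..`q8`, `becq9`..`becq20`), the age-group domain {4, 5, 6}, the
#' condition domain {DLD, TLD, NA} and nonnegative preschool years.
#'
#' @param children A cohort data.frame.
#' @return The validated data.frame, invisibly, with `condition` and
#'   answers normalised.
#' @export
validate_children <- function(children) {
  if (!is.data.frame(children) || nrow(children) == 0L) {
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  }
  miss <- setdiff(.child_columns(), names(children))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  children$age_group <- as.integer(children$age_group)
  if (!all(children$age_group %in% c(4L, 5L, 6L))) {
    stop("age_group must be 4, 5 or 6", call. = FALSE)
  }
  cond <- toupper(trimws(as.character(children$condition)))
  cond[cond %in% c("", "NA", "UNKNOWN")] <- NA_character_
  if (!all(is.na(cond) | cond %in% c("DLD", "TLD"))) {
    stop("condition must be DLD, TLD or missing", call. = FALSE)
  }
  children$condition <- cond
  for (cc in paste0("q", 1:8)) {
    children[[cc]] <- .normalize_answers(children[[cc]])
  }
  ps <- children$becq17
  if (any(!is.na(ps) & ps < 0)) {
    stop("becq17 (preschool years) must be nonnegative", call. = FALSE)
  }
  invisible(children)
}

#' Read a child-level questionnaire file
#'
#' Reads delimited text (comma or tab, autodetected from the header line)
#' with one row per child and the documented header contract: `child_id`,
#' `age_group`, `condition`, `q1`..`q8`, `becq9`..`becq20`.
#'
#' @param path Path to the file.
#' @return A validated cohort data.frame.
#' @export
read_children <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_children(df)
}

#' Write a cohort (optionally coded) to delimited text or JSON
#'
#' @param children A cohort data.frame, e.g. from [generate_cohort()] or
#'   [code_records()].
#' @param path Output path; a `.json` extension selects JSON, anything
#'   else comma-separated text.
#' @return `path`, invisibly.
#' @export
write_children <- function(children, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(children, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(children, path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}
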