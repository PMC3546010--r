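# End-to-end pipeline and reporting: episodes -> classify -> evaluate,
# plus a counts-only evaluation entry point. Every number in the report is
# produced by a concordance-module operation; the reporter only assembles.

#' Evaluate a single comparison from raw 2x2 counts
#'
#' Counts-only entry point: given the four cells of an algorithm-vs-physician
#' cross-classification, returns the derived agreement statistics. Useful for
#' evaluating published cross-tabulations without reconstructing a cohort.
#'
#' @inheritParams agreement_table
#' @return A list: `comparison`, `counts` (a, b, c, d, n),
#'   `percent_agreement` (fraction), `kappa`, `band` (Landis-Koch label).
#' @examples
#' evaluate_from_counts(7288, 276, 240, 1678)
#' @export
evaluate_from_counts <- function(a, b, c, d,
                                 comparison = "contamination_vs_bsi") {
  tab <- agreement_table(a, b, c, d, comparison)
  k <- cohen_kappa(tab)
  list(comparison = tab$comparison,
       counts = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                     n = tab$a + tab$b + tab$c + tab$d),
       percent_agreement = percent_agreement(tab),
       kappa = k,
       band = landis_koch(k))
}

#' Run the full classification and evaluation pipeline
#'
#' Executes episode building, classification, linkage, and concordance
#' evaluation on the four registry tables:
#' derive best-estimate-dates, build computer episodes from all study-window
#' cultures and reference episodes from the physician assessments, flag
#' incident reference episodes (using any lag-period cultures), classify the
#' computer episodes with the four rules, link reference to computer
#' episodes, and tabulate the four comparisons with percent agreement,
#' kappa, Landis-Koch band, and crude 30-day-mortality contrasts.
#'
#' @param cultures,contacts,assessments,followup Validated registry tables
#'   (see [read_registry_table()]), or paths to their CSV files.
#' @param lexicon An [organism_lexicon()].
#' @param windows Named list of window constants; defaults to the standard
#'   values (see [read_run_config()]).
#' @param study_start Optional `Date`; cultures before it are used only for
#'   the incident lookback, not for episode building.
#' @param output_dir Optional directory: writes `episodes.csv` (classified
#'   computer episodes), `reference_episodes.csv`, and `report.json`.
#' @return A list of class `bc_report`; see [print.bc_report()].
#' @export
run_full_pipeline <- function(cultures, contacts, assessments, followup,
                              lexicon = organism_lexicon(),
                              windows = list(), study_start = NULL,
                              output_dir = NULL) {
  if (is.character(cultures)) cultures <- read_blood_cultures(cultures)
  if (is.character(contacts)) contacts <- read_hospital_contacts(contacts)
  if (is.character(assessments)) assessments <- read_assessments(assessments)
  if (is.character(followup)) followup <- read_followup(followup)
  w <- utils::modifyList(
    list(episode_span = 2, contamination_window = 5, hca_window = 30,
         attach_window = 30, incident_lookback = 365),
    windows)

  validation <- list(
    cultures = validation_report(cultures),
    contacts = validation_report(contacts),
    assessments = validation_report(assessments),
    followup = validation_report(followup)
  )

  all_cultures <- cultures
  if (!is.null(study_start)) {
    bed <- best_estimate_date(cultures$draw_date, cultures$receipt_date)
    cultures <- cultures[bed >= as.Date(study_start), , drop = FALSE]
  }

  if (nrow(cultures) == 0) {
    report <- structure(list(
      n_cultures = 0L, n_computer_episodes = 0L, n_reference_episodes = 0L,
      n_linked = 0L, unpaired = character(), validation = validation,
      comparisons = list(), mortality = list(),
      notes = "empty input: no positive blood cultures"),
      class = "bc_report")
    if (!is.null(output_dir)) .write_report_files(report, NULL, NULL, output_dir)
    return(report)
  }

  computer <- build_computer_episodes(cultures)
  computer <- classify_episodes(computer, cultures, contacts, lexicon,
                                contamination_window = w$contamination_window)
  reference <- build_reference_episodes(cultures, assessments,
                                        attach_window = w$attach_window)
  reference <- flag_incident(reference, all_cultures,
                             lookback = w$incident_lookback)

  pairs <- link_episodes(reference, computer)
  comparisons <- lapply(.comparisons, function(cmp) {
    tab <- cross_tabulate(pairs, cmp)
    evaluate_from_counts(tab$a, tab$b, tab$c, tab$d, cmp)
  })
  names(comparisons) <- .comparisons
  mortality <- lapply(.comparisons, function(cmp)
    mortality_contrasts(pairs, followup, cmp))
  names(mortality) <- .comparisons

  report <- structure(list(
    n_cultures = nrow(cultures),
    n_computer_episodes = nrow(computer),
    n_reference_episodes = nrow(reference),
    n_linked = nrow(pairs),
    unpaired = attr(pairs, "unpaired"),
    n_incident = sum(reference$incident, na.rm = TRUE),
    validation = validation,
    onset_branches = table(computer$onset_branch[!computer$contamination]),
    comparisons = comparisons,
    mortality = mortality,
    notes = character()),
    class = "bc_report")
  if (!is.null(output_dir)) .write_report_files(report, computer, reference, output_dir)
  attr(report, "computer") <- computer
  attr(report, "reference") <- reference
  attr(report, "pairs") <- pairs
  report
}

.write_report_files <- function(report, computer, reference, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(computer)) {
    write_episode_table(computer, file.path(dir, "episodes.csv"))
  }
  if (!is.null(reference)) {
    write_episode_table(reference, file.path(dir, "reference_episodes.csv"))
  }
  write_report_json(report, file.path(dir, "report.json"))
  invisible(dir)
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `bc_report` from [run_full_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  attributes(out) <- list(names = names(out))
  out$onset_branches <- as.list(out$onset_branches)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", force = TRUE)
  invisible(path)
}

#' @export
print.bc_report <- function(x, ...) {
  cat("Blood-culture episode classification report\n")
  cat(sprintf("  cultures: %d  computer episodes: %d  reference episodes: %d (linked %d)\n",
              x$n_cultures, x$n_computer_episodes, x$n_reference_episodes,
              x$n_linked))
  n_invalid <- sum(vapply(x$validation, nrow, 1L))
  if (n_invalid > 0) cat(sprintf("  rejected input rows: %d (see $validation)\n", n_invalid))
  for (cmp in names(x$comparisons)) {
    cc <- x$comparisons[[cmp]]
    cat(sprintf("  %-22s n=%5d  agreement %5.1f%%  kappa %5.2f (%s)\n",
                cmp, cc$counts$n, 100 * cc$percent_agreement, cc$kappa, cc$band))
  }
  if (length(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}
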