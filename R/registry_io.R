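# Canonical CSV schemas for the four registry tables and the episode table.
# All dates are ISO 8601 calendar dates; registries record dates only, never
# times, so everything downstream is integer day arithmetic on `Date`s.

.bc_schemas <- list(
  blood_cultures = list(
    columns  = c("record_id", "patient_id", "draw_date", "receipt_date",
                 "organism_name", "source_site"),
    required = c("record_id", "patient_id", "receipt_date", "organism_name"),
    dates    = c("draw_date", "receipt_date"),
    id       = "record_id"
  ),
  contacts = list(
    columns  = c("contact_id", "patient_id", "contact_type", "indate", "outdate"),
    required = c("contact_id", "patient_id", "contact_type", "indate", "outdate"),
    dates    = c("indate", "outdate"),
    id       = "contact_id"
  ),
  assessments = list(
    columns  = c("patient_id", "assessed_date", "class_onset", "class_micro"),
    required = c("patient_id", "assessed_date", "class_onset", "class_micro"),
    dates    = "assessed_date",
    id       = NULL
  ),
  followup = list(
    columns  = c("patient_id", "death_date", "emigration_date",
                 "comorbidity_category"),
    required = "patient_id",
    dates    = c("death_date", "emigration_date"),
    id       = NULL
  )
)

.onset_levels <- c("contamination", "community_onset", "healthcare_associated",
                   "hospital_onset")
.micro_levels <- c("contamination", "monomicrobial", "polymicrobial")
.comorbidity_levels <- c("0", "1-2", ">2")

.parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  present <- !is.na(x) & nzchar(x)
  out[present] <- as.Date(x[present], format = "%Y-%m-%d", optional = TRUE)
  attr(out, "unparseable") <- present & is.na(out)
  out
}

.new_report <- function() {
  data.frame(line = integer(), id = character(), field = character(),
             problem = character(), stringsAsFactors = FALSE)
}

.add_problem <- function(report, lines, ids, field, problem) {
  if (length(lines) == 0) return(report)
  rbind(report, data.frame(line = lines, id = ids, field = field,
                           problem = problem, stringsAsFactors = FALSE))
}

#' Read and validate a registry table
#'
#' Reads one of the four canonical registry CSVs (`blood_cultures`,
#' `contacts`, `assessments`, `followup`), parses ISO-8601 dates, and checks
#' every row against the schema invariants. Validation is total and collects
#' all problems in one pass, as is usual when cleaning registry extracts:
#' every input row is either accepted or listed (with its file line number)
#' in the validation report attached to the result; invalid rows are dropped
#' from the returned data.
#'
#' Row-level invariants checked:
#' * required fields non-missing, dates parseable;
#' * blood cultures: `draw_date <= receipt_date` when the draw date is
#'   present (the receipt date is never missing), unique `record_id`;
#' * contacts: `indate <= outdate`, `contact_type` one of
#'   `"inpatient"`/`"outpatient"`, unique `contact_id`;
#' * assessments: `class_onset == "contamination"` exactly when
#'   `class_micro == "contamination"` (the two physician variables must agree
#'   on whether the culture was a contamination);
#' * follow-up: at most one record per patient, `comorbidity_category` in
#'   `0` / `1-2` / `>2` when present.
#'
#' A missing required column is a schema error and aborts; row problems do
#' not.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"blood_cultures"`, `"contacts"`, `"assessments"`,
#'   `"followup"`.
#' @return A `data.frame` of the accepted rows with parsed `Date` columns and
#'   a `"validation"` attribute (see [validation_report()]).
#' @seealso [read_blood_cultures()] and friends for per-table wrappers.
#' @export
read_registry_table <- function(path, schema) {
  schema <- match.arg(schema, names(.bc_schemas))
  sch <- .bc_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(sch$columns, names(raw))) raw[[col]] <- ""
  raw <- raw[sch$columns]
  # header is file line 1; data row i sits on line i + 1
  lines <- seq_len(nrow(raw)) + 1L
  report <- .new_report()
  bad <- rep(FALSE, nrow(raw))
  ids <- if (!is.null(sch$id)) trimws(raw[[sch$id]]) else trimws(raw$patient_id)

  for (col in sch$dates) {
    parsed <- .parse_iso_date(raw[[col]])
    unp <- attr(parsed, "unparseable")
    report <- .add_problem(report, lines[unp], ids[unp], col,
                           "unparseable date (expected YYYY-MM-DD)")
    bad <- bad | unp
    attr(parsed, "unparseable") <- NULL
    raw[[col]] <- parsed
  }
  for (col in setdiff(sch$columns, sch$dates)) raw[[col]] <- trimws(raw[[col]])

  for (col in sch$required) {
    miss <- if (inherits(raw[[col]], "Date")) is.na(raw[[col]]) else !nzchar(raw[[col]])
    miss <- miss & !bad  # an unparseable date is already reported
    report <- .add_problem(report, lines[miss], ids[miss], col, "missing required value")
    bad <- bad | miss
  }

  if (schema == "blood_cultures") {
    viol <- !bad & !is.na(raw$draw_date) & raw$draw_date > raw$receipt_date
    report <- .add_problem(report, lines[viol], ids[viol], "draw_date",
                           "draw_date after receipt_date")
    bad <- bad | viol
  }
  if (schema == "contacts") {
    viol <- !bad & raw$indate > raw$outdate
    report <- .add_problem(report, lines[viol], ids[viol], "indate",
                           "indate after outdate")
    bad <- bad | viol
    viol <- !bad & !(raw$contact_type %in% c("inpatient", "outpatient"))
    report <- .add_problem(report, lines[viol], ids[viol], "contact_type",
                           "contact_type must be 'inpatient' or 'outpatient'")
    bad <- bad | viol
  }
  if (schema == "assessments") {
    viol <- !bad & !(raw$class_onset %in% .onset_levels)
    report <- .add_problem(report, lines[viol], ids[viol], "class_onset",
                           "unknown onset class")
    bad <- bad | viol
    viol <- !bad & !(raw$class_micro %in% .micro_levels)
    report <- .add_problem(report, lines[viol], ids[viol], "class_micro",
                           "unknown microbial class")
    bad <- bad | viol
    viol <- !bad & xor(raw$class_onset == "contamination",
                       raw$class_micro == "contamination")
    report <- .add_problem(report, lines[viol], ids[viol], "class_onset",
                           "contamination labels disagree between the two assessment variables")
    bad <- bad | viol
  }
  if (schema == "followup") {
    has_cat <- nzchar(raw$comorbidity_category)
    viol <- !bad & has_cat & !(raw$comorbidity_category %in% .comorbidity_levels)
    report <- .add_problem(report, lines[viol], ids[viol], "comorbidity_category",
                           "comorbidity_category must be one of 0, 1-2, >2")
    bad <- bad | viol
    dup <- !bad & duplicated(ifelse(bad, NA, raw$patient_id), incomparables = NA)
    report <- .add_problem(report, lines[dup], ids[dup], "patient_id",
                           "more than one follow-up record for patient")
    bad <- bad | dup
  }
  if (!is.null(sch$id)) {
    dup <- !bad & duplicated(ifelse(bad, NA, raw[[sch$id]]), incomparables = NA)
    report <- .add_problem(report, lines[dup], ids[dup], sch$id,
                           paste0("duplicate ", sch$id))
    bad <- bad | dup
  }

  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (schema == "followup" && "comorbidity_category" %in% names(out)) {
    out$comorbidity_category[!nzchar(out$comorbidity_category)] <- NA_character_
  }
  if (schema == "blood_cultures") {
    out$source_site[!nzchar(out$source_site)] <- NA_character_
  }
  attr(out, "validation") <- report
  attr(out, "schema") <- schema
  out
}

#' @rdname read_registry_table
#' @export
read_blood_cultures <- function(path) read_registry_table(path, "blood_cultures")

#' @rdname read_registry_table
#' @export
read_hospital_contacts <- function(path) read_registry_table(path, "contacts")

#' @rdname read_registry_table
#' @export
read_assessments <- function(path) read_registry_table(path, "assessments")

#' @rdname read_registry_table
#' @export
read_followup <- function(path) read_registry_table(path, "followup")

#' Validation report of a registry table
#'
#' @param x A table returned by [read_registry_table()].
#' @return A `data.frame` with one row per rejected input row: `line` (file
#'   line number), `id`, `field`, `problem`. Zero rows for a clean file.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation")
  if (is.null(rep)) .new_report() else rep
}

# Episode table round-trip -----------------------------------------------

.episode_columns <- c("episode_id", "patient_id", "kind", "index_date",
                      "member_record_ids", "contamination", "polymicrobial",
                      "onset", "healthcare_associated", "incident",
                      "ref_class_onset", "ref_class_micro")

.na_chr <- function(x) ifelse(is.na(x), "NA", as.character(x))

#' Write classified episodes to CSV
#'
#' One row per episode; member record ids are serialised as a
#' semicolon-separated list. Classification columns that do not apply to an
#' episode's kind or class (e.g. onset for a contamination episode, which by
#' definition carries no onset) are emitted as the `NA` sentinel. The file
#' round-trips losslessly through [read_episode_table()].
#'
#' @param episodes An episode `data.frame` as produced by
#'   [build_computer_episodes()] / [classify_episodes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episode_table <- function(episodes, path) {
  episodes <- as_episode_table(episodes)
  out <- data.frame(
    episode_id = episodes$episode_id,
    patient_id = episodes$patient_id,
    kind = episodes$kind,
    index_date = as.character(episodes$index_date),
    member_record_ids = vapply(episodes$member_record_ids,
                               function(v) paste(sort(v), collapse = ";"), ""),
    contamination = .na_chr(episodes$contamination),
    polymicrobial = .na_chr(episodes$polymicrobial),
    onset = .na_chr(episodes$onset),
    healthcare_associated = .na_chr(episodes$healthcare_associated),
    incident = .na_chr(episodes$incident),
    ref_class_onset = .na_chr(episodes$ref_class_onset),
    ref_class_micro = .na_chr(episodes$ref_class_micro),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read an episode table written by [write_episode_table()]
#'
#' @param path CSV path.
#' @return An episode `data.frame` (list-column `member_record_ids`).
#' @export
read_episode_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "NA")
  if (nrow(raw) == 0) return(empty_episode_table())
  data.frame(
    episode_id = raw$episode_id,
    patient_id = raw$patient_id,
    kind = raw$kind,
    index_date = as.Date(raw$index_date),
    member_record_ids = I(lapply(strsplit(ifelse(is.na(raw$member_record_ids),
                                                 "", raw$member_record_ids), ";",
                                          fixed = TRUE),
                                 function(v) sort(v[nzchar(v)]))),
    contamination = as.logical(raw$contamination),
    polymicrobial = as.logical(raw$polymicrobial),
    onset = raw$onset,
    healthcare_associated = as.logical(raw$healthcare_associated),
    incident = as.logical(raw$incident),
    ref_class_onset = raw$ref_class_onset,
    ref_class_micro = raw$ref_class_micro,
    stringsAsFactors = FALSE
  )
}

#' An empty episode table with the canonical columns
#' @return Zero-row episode `data.frame`.
#' @export
empty_episode_table <- function() {
  data.frame(
    episode_id = character(), patient_id = character(), kind = character(),
    index_date = as.Date(character()),
    member_record_ids = I(list()),
    contamination = logical(), polymicrobial = logical(),
    onset = character(), healthcare_associated = logical(),
    incident = logical(),
    ref_class_onset = character(), ref_class_micro = character(),
    stringsAsFactors = FALSE
  )
}

# Coerce a partial episode frame (e.g. fresh from the builder, before
# classification) to the full canonical column set.
#' @rdname empty_episode_table
#' @param x An episode `data.frame`, possibly lacking classification columns.
#' @export
as_episode_table <- function(x) {
  tmpl <- empty_episode_table()
  for (col in names(tmpl)) {
    if (!col %in% names(x)) {
      x[[col]] <- if (is.list(tmpl[[col]])) I(rep(list(character()), nrow(x)))
                  else rep(tmpl[[col]][NA_integer_][1], nrow(x))
    }
  }
  x[, names(tmpl), drop = FALSE]
}

#' Read a run configuration file
#'
#' Loads a YAML (or JSON) configuration holding input paths, the organism
#' lexicon override, and the window constants. Window constants default to
#' the surveillance rules' standard values: 2-day episode span, 5-day
#' contamination repeat-growth window, 30-day healthcare-association window,
#' 30-day reference-episode attachment window, 365-day incident lookback.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list with elements `paths`, `lexicon`, `windows`,
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(episode_span = 2, contamination_window = 5,
                   hca_window = 30, attach_window = 30,
                   incident_lookback = 365)
  cfg$windows <- utils::modifyList(defaults, as.list(cfg$windows))
  bad <- vapply(cfg$windows, function(w) !is.numeric(w) || w <= 0, TRUE)
  if (any(bad)) {
    stop("window constants must be positive: ",
         paste(names(cfg$windows)[bad], collapse = ", "))
  }
  if (!is.null(cfg$lexicon)) {
    cfg$lexicon <- organism_lexicon(
      genus_patterns = cfg$lexicon$genus_patterns %||% NULL,
      exact_labels = cfg$lexicon$exact_labels %||% NULL,
      cons_species = cfg$lexicon$cons_species %||% NULL
    )
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
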