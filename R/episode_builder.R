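# Episode derivation: best-estimate-dates, 2-day computer episodes,
# physician-anchored reference episodes, and the incident flag.

#' Best-estimate-date of a positive blood culture
#'
#' The analysis date of a culture is its draw date; when the draw date was
#' not recorded (about 9% of records in routine laboratory extracts) the
#' receipt date — which is never missing — stands in for it.
#'
#' @param draw_date `Date` vector, may contain `NA`.
#' @param receipt_date `Date` vector, no `NA` allowed.
#' @return `Date` vector: `draw_date` where present, else `receipt_date`.
#' @export
best_estimate_date <- function(draw_date, receipt_date) {
  if (anyNA(receipt_date)) stop("receipt_date must never be missing")
  out <- draw_date
  out[is.na(out)] <- receipt_date[is.na(draw_date)]
  out
}

# Add the bed column to a validated cultures table.
.with_bed <- function(cultures) {
  cultures$bed <- best_estimate_date(cultures$draw_date, cultures$receipt_date)
  cultures
}

#' Group a patient's cultures into 2-day computer episodes
#'
#' The first computer episode comprises all of a patient's positive cultures
#' on the earliest best-estimate-date and the day after; each subsequent
#' episode starts at the earliest best-estimate-date strictly after the
#' previous episode's 2-day span, and so on until every culture is assigned.
#' The episodes partition the records: every record belongs to exactly one
#' episode.
#'
#' @param cultures Validated blood-culture table ([read_blood_cultures()]),
#'   any number of patients; may be empty.
#' @return Episode `data.frame` (kind `"computer"`), ordered by patient and
#'   index date, with the list-column `member_record_ids`.
#' @export
build_computer_episodes <- function(cultures) {
  if (nrow(cultures) == 0) return(empty_episode_table())
  cultures <- .with_bed(cultures)
  res <- lapply(split(cultures, cultures$patient_id), .computer_episodes_one)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  as_episode_table(out[order(out$patient_id, out$index_date), , drop = FALSE])
}

.computer_episodes_one <- function(recs) {
  dates <- sort(unique(recs$bed))
  starts <- as.Date(integer(0), origin = "1970-01-01")
  while (length(dates) > 0) {
    d <- dates[1]
    starts <- c(starts, d)
    dates <- dates[dates > d + 1]
  }
  members <- lapply(starts, function(d) {
    sort(recs$record_id[recs$bed >= d & recs$bed <= d + 1])
  })
  data.frame(
    episode_id = sprintf("%s-C%03d", recs$patient_id[1], seq_along(starts)),
    patient_id = recs$patient_id[1],
    kind = "computer",
    index_date = starts,
    member_record_ids = I(members),
    stringsAsFactors = FALSE
  )
}

#' Build physician-anchored reference episodes
#'
#' Each recorded physician assessment anchors a reference episode at the
#' assessed culture's best-estimate-date: a patient's first reference episode
#' is anchored at the earliest assessed date, the next at the next assessed
#' date after it, iterated to exhaustion. Cultures *without* a recorded
#' assessment are attached to the earliest reference episode whose
#' `(index_date, index_date + attach_window]` interval covers their
#' best-estimate-date; unassessed cultures that precede the patient's first
#' assessed date (or fall outside every window) remain unattached and form
#' computer episodes only. Each episode carries its anchoring assessment's
#' two classification variables as the physician reference labels.
#'
#' An assessment whose `assessed_date` matches no culture best-estimate-date
#' for that patient is a validation error. When several assessments share a
#' patient and date, the first by file order wins and a warning is emitted.
#'
#' @param cultures Validated blood-culture table.
#' @param assessments Validated physician-assessment table.
#' @param attach_window Days after the anchor date within which unassessed
#'   cultures are pulled into the episode (default 30).
#' @return Episode `data.frame` (kind `"reference"`) with `ref_class_onset`
#'   and `ref_class_micro` filled in.
#' @export
build_reference_episodes <- function(cultures, assessments, attach_window = 30) {
  if (nrow(assessments) == 0) return(empty_episode_table())
  cultures <- .with_bed(cultures)

  key <- paste(assessments$patient_id, assessments$assessed_date)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " conflicting assessment(s) on an already-assessed date; ",
            "keeping the first by file order")
    assessments <- assessments[!dup, , drop = FALSE]
  }
  culture_key <- paste(cultures$patient_id, cultures$bed)
  orphan <- !(paste(assessments$patient_id, assessments$assessed_date) %in% culture_key)
  if (any(orphan)) {
    stop("assessment(s) with no positive blood culture on the assessed date: ",
         paste(utils::head(paste(assessments$patient_id[orphan],
                                 assessments$assessed_date[orphan]), 5),
               collapse = "; "))
  }

  out <- lapply(split(seq_len(nrow(assessments)), assessments$patient_id),
                function(idx) {
    asm <- assessments[idx, , drop = FALSE]
    asm <- asm[order(asm$assessed_date), , drop = FALSE]
    recs <- cultures[cultures$patient_id == asm$patient_id[1], , drop = FALSE]
    anchors <- asm$assessed_date
    assessed_rec <- recs$bed %in% anchors
    # assessed cultures join the episode anchored on their own date
    member_of <- match(recs$bed, anchors)
    # unassessed cultures attach to the earliest episode whose window covers them
    for (i in which(!assessed_rec)) {
      cand <- which(recs$bed[i] > anchors & recs$bed[i] <= anchors + attach_window)
      member_of[i] <- if (length(cand) > 0) cand[1] else NA_integer_
    }
    members <- lapply(seq_along(anchors), function(k) {
      sort(recs$record_id[!is.na(member_of) & member_of == k])
    })
    data.frame(
      episode_id = sprintf("%s-R%03d", asm$patient_id[1], seq_along(anchors)),
      patient_id = asm$patient_id[1],
      kind = "reference",
      index_date = anchors,
      member_record_ids = I(members),
      ref_class_onset = asm$class_onset,
      ref_class_micro = asm$class_micro,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  as_episode_table(out[order(out$patient_id, out$index_date), , drop = FALSE])
}

#' Flag incident reference episodes
#'
#' A patient's first in-study reference episode is *incident* when the
#' patient had no positive blood culture in the `lookback` days before its
#' index date (day `lookback` before counts as within the window, i.e. the
#' boundary is inclusive); cultures from a lag period before the study window
#' participate in the check. Any later reference episode of the same patient
#' is non-incident by definition.
#'
#' @param reference Reference episode table ([build_reference_episodes()]).
#' @param cultures All blood cultures, including any lag-period records.
#' @param lookback Lookback length in days (default 365).
#' @return `reference` with its `incident` column filled.
#' @export
flag_incident <- function(reference, cultures, lookback = 365) {
  if (nrow(reference) == 0) return(reference)
  cultures <- .with_bed(cultures)
  reference <- reference[order(reference$patient_id, reference$index_date), ,
                         drop = FALSE]
  first <- !duplicated(reference$patient_id)
  incident <- rep(FALSE, nrow(reference))
  for (i in which(first)) {
    beds <- cultures$bed[cultures$patient_id == reference$patient_id[i]]
    gap <- as.integer(reference$index_date[i] - beds)
    incident[i] <- !any(gap >= 1 & gap <= lookback)
  }
  reference$incident <- incident
  rownames(reference) <- NULL
  reference
}
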