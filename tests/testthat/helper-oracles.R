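# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately avoid the package's own offset/episode machinery:
# they scan calendar days and enumerate raw (date x contact) combinations
# with explicit loops, so agreement with the package is a real check.

D <- function(x) as.Date(x)

make_cultures <- function(patient_id, dates, organisms = "Escherichia coli",
                          draw_missing = FALSE, id_prefix = "R") {
  n <- length(dates)
  organisms <- rep_len(organisms, n)
  draw_missing <- rep_len(draw_missing, n)
  dates <- as.Date(dates)
  df <- data.frame(
    record_id = sprintf("%s%s%d", id_prefix, rep_len(patient_id, n), seq_len(n)),
    patient_id = rep_len(patient_id, n),
    draw_date = dates,
    receipt_date = dates + 1,
    organism_name = organisms,
    source_site = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  df$draw_date[draw_missing] <- NA
  df$receipt_date[draw_missing] <- dates[draw_missing]
  df
}

make_contacts <- function(patient_id, indates, outdates,
                          types = "inpatient", id_prefix = "C") {
  n <- length(indates)
  data.frame(
    contact_id = sprintf("%s%s%d", id_prefix, rep_len(patient_id, n), seq_len(n)),
    patient_id = rep_len(patient_id, n),
    contact_type = rep_len(types, n),
    indate = as.Date(indates),
    outdate = as.Date(outdates),
    stringsAsFactors = FALSE
  )
}

make_assessments <- function(patient_id, dates, class_onset = "community_onset",
                             class_micro = "monomicrobial") {
  data.frame(
    patient_id = rep_len(patient_id, length(dates)),
    assessed_date = as.Date(dates),
    class_onset = rep_len(class_onset, length(dates)),
    class_micro = rep_len(class_micro, length(dates)),
    stringsAsFactors = FALSE
  )
}

write_csv_fixture <- function(df, path) {
  for (col in names(df)) if (inherits(df[[col]], "Date")) {
    df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# --- independent oracles ------------------------------------------------

# Day-scan grouping of best-estimate-dates into 2-day episodes.
oracle_group_dates <- function(dates) {
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) == 0) return(list())
  groups <- list()
  current <- NULL
  start <- NULL
  for (day in seq(min(dates), max(dates), by = "day")) {
    day <- as.Date(day, origin = "1970-01-01")
    if (!day %in% dates) next
    if (is.null(start) || day > start + 1) {
      if (!is.null(current)) groups[[length(groups) + 1]] <- current
      current <- day
      start <- day
    } else {
      current <- c(current, day)
    }
  }
  groups[[length(groups) + 1]] <- current
  lapply(groups, function(g) as.Date(g, origin = "1970-01-01"))
}

# Place-of-onset decision straight from the raw tables, nested loops.
oracle_onset <- function(episode_dates, contacts) {
  ti <- c(); to <- c(); stay <- c()
  for (i in seq_len(nrow(contacts))) {
    if (contacts$contact_type[i] != "inpatient") next
    for (bed in as.list(episode_dates)) {
      a <- as.integer(bed - contacts$indate[i])
      b <- as.integer(bed - contacts$outdate[i])
      if (a < -2 || b > 30) next
      ti <- c(ti, a); to <- c(to, b)
      stay <- c(stay, as.integer(contacts$outdate[i] - contacts$indate[i]))
    }
  }
  if (length(ti) == 0) return("community")
  low <- min(ti)
  if (low >= 2) return("hospital")
  if (low == 0 || low == 1) {
    need <- if (low == 0) 2 else 1
    for (j in seq_along(ti)) {
      if (to[j] == 0 && stay[j] >= need) return("hospital")
      if (ti[j] > 1 && to[j] < 0) return("hospital")
    }
  }
  "community"
}

# Healthcare association straight from raw pairs.
oracle_hca <- function(episode_dates, contacts) {
  for (i in seq_len(nrow(contacts))) {
    for (bed in as.list(episode_dates)) {
      a <- as.integer(bed - contacts$indate[i])
      b <- as.integer(bed - contacts$outdate[i])
      if (a < -2 || b > 30) next
      if (a <= 30 && b > 0) return(TRUE)
      if (a > 30 && b > 0 && b <= 30) return(TRUE)
    }
  }
  FALSE
}

# Contamination screen evaluated record by record.
oracle_contamination <- function(index_date, member_ids, cultures, lexicon) {
  bed <- best_estimate_date(cultures$draw_date, cultures$receipt_date)
  commensal <- classify_organism(cultures$organism_name, lexicon) == "commensal"
  for (i in seq_len(nrow(cultures))) {
    is_member <- cultures$record_id[i] %in% member_ids
    if (is_member && !commensal[i]) return("bsi")
    gap <- as.integer(bed[i] - index_date)
    if (commensal[i] && gap >= 1 && gap <= 4) return("bsi")
  }
  "contamination"
}

# Random single-patient instance for the onset/contamination equivalence
# suites: up to 5 contacts and 3 separate culture clusters around day 0.
random_patient_instance <- function(pid) {
  base <- D("2006-06-01")
  n_dates <- sample(1:4, 1)
  beds <- base + sort(sample(0:12, n_dates))
  orgs <- sample(c("Escherichia coli", "Staphylococcus aureus",
                   "Staphylococcus epidermidis", "Corynebacterium striatum",
                   "coagulase-negative staphylococcus", "Micrococcus luteus"),
                 n_dates, replace = TRUE)
  cultures <- make_cultures(pid, beds, orgs)
  n_ctc <- sample(0:5, 1)
  indates <- base + sample(-40:14, n_ctc, replace = TRUE)
  stays <- sample(0:45, n_ctc, replace = TRUE)
  contacts <- if (n_ctc > 0) {
    make_contacts(pid, indates, indates + stays,
                  types = sample(c("inpatient", "outpatient"), n_ctc,
                                 replace = TRUE))
  } else {
    make_contacts(pid, character(0), character(0))
  }
  list(cultures = cultures, contacts = contacts)
}
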