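# Rule-based classification of episodes: organism lexicon, contamination
# screen, polymicrobial count, admission time-offsets, place of onset, and
# healthcare association.

.default_cons_species <- c(
  "Staphylococcus epidermidis", "Staphylococcus hominis",
  "Staphylococcus haemolyticus", "Staphylococcus capitis",
  "Staphylococcus warneri", "Staphylococcus saprophyticus",
  "Staphylococcus lugdunensis", "Staphylococcus simulans",
  "Staphylococcus cohnii", "Staphylococcus pettenkoferi"
)

#' Organism lexicon for the commensal/pathogen dichotomy
#'
#' The contamination rule rests on a short list of common skin commensals:
#' coagulase-negative staphylococci, *Propionibacterium* spp., *Bacillus*
#' spp., *Micrococcus* spp., and *Corynebacterium* spp., plus the provisional
#' labels laboratories record when an isolate is not speciated
#' ("coagulase-negative staphylococcus", "coryneform rod"). Everything not
#' matched is a pathogen. Matching is case-insensitive after whitespace
#' trimming; the four genera match as genus-level prefixes (any
#' "Corynebacterium ..." label), the provisional labels and the
#' coagulase-negative staphylococcal species match exactly. Since
#' coagulase-negative status is not derivable from the genus name
#' (*Staphylococcus aureus* is a pathogen), the CoNS species list is explicit
#' and overridable.
#'
#' @param genus_patterns Genus names matched as word prefixes.
#' @param exact_labels Provisional labels matched exactly.
#' @param cons_species Coagulase-negative staphylococcal species, matched
#'   exactly.
#' @return An object of class `organism_lexicon`.
#' @export
organism_lexicon <- function(genus_patterns = NULL, exact_labels = NULL,
                             cons_species = NULL) {
  lex <- structure(list(
    genus_patterns = genus_patterns %||%
      c("Propionibacterium", "Bacillus", "Micrococcus", "Corynebacterium"),
    exact_labels = exact_labels %||%
      c("coagulase-negative staphylococcus", "coryneform rod"),
    cons_species = cons_species %||% .default_cons_species
  ), class = "organism_lexicon")
  lex
}

.norm_org <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Classify organism labels as commensal or pathogen
#'
#' @param name Character vector of recorded organism labels.
#' @param lexicon An [organism_lexicon()].
#' @return Character vector, `"commensal"` or `"pathogen"`. Unmatched labels
#'   default to pathogen; classification is total.
#' @export
classify_organism <- function(name, lexicon = organism_lexicon()) {
  stopifnot(inherits(lexicon, "organism_lexicon"))
  n <- .norm_org(name)
  if (any(!nzchar(n))) stop("organism name must be non-empty")
  exact <- .norm_org(c(lexicon$exact_labels, lexicon$cons_species))
  hit <- n %in% exact
  for (g in .norm_org(lexicon$genus_patterns)) {
    hit <- hit | n == g | startsWith(n, paste0(g, " "))
  }
  ifelse(hit, "commensal", "pathogen")
}

#' Contamination screen for a computer episode
#'
#' An episode is a contamination when common skin commensals, and nothing
#' else, grew — and only on the episode's earliest best-estimate-date within
#' a 5-day period. Concretely: (a) every member organism is commensal, (b) no
#' commensal-positive culture of the patient falls on any of the `window - 1`
#' days after the index date (repeat growth of a commensal within the window
#' is taken as evidence of true infection), and (c) no pathogen occurs in the
#' episode. Clause (b) is evaluated against *all* of the patient's cultures,
#' not only episode members, since the repeat-growth screen is about the
#' patient's culture history, not the episode bookkeeping. Everything else is
#' a bloodstream infection (BSI) episode.
#'
#' @param episode One-row episode `data.frame`.
#' @param cultures The patient's blood cultures (validated table).
#' @param lexicon An [organism_lexicon()].
#' @param window Length of the repeat-growth window in days (default 5:
#'   the index date plus the four following days).
#' @return `"contamination"` or `"bsi"`.
#' @export
classify_contamination <- function(episode, cultures,
                                   lexicon = organism_lexicon(), window = 5) {
  stopifnot(nrow(episode) == 1)
  cultures <- .with_bed(cultures)
  cultures <- cultures[cultures$patient_id == episode$patient_id, , drop = FALSE]
  members <- cultures[cultures$record_id %in% episode$member_record_ids[[1]], ,
                      drop = FALSE]
  if (nrow(members) == 0) stop("episode has no member records")
  cls_member <- classify_organism(members$organism_name, lexicon)
  if (any(cls_member == "pathogen")) return("bsi")
  idx <- episode$index_date
  later <- cultures$bed > idx & cultures$bed <= idx + (window - 1)
  if (any(later) &&
      any(classify_organism(cultures$organism_name[later], lexicon) == "commensal")) {
    return("bsi")
  }
  "contamination"
}

#' Monomicrobial or polymicrobial bloodstream infection
#'
#' A BSI episode is polymicrobial when at least two distinct microorganism
#' types were isolated within it. Types are distinct recorded labels after
#' case/whitespace normalisation; duplicate per-bottle rows of the same
#' organism do not count, but a provisional label counts as its own type
#' (so *Candida albicans* together with "yeast-like organism" is
#' polymicrobial, a known over-call of the rule).
#'
#' @param organism_names Organism labels of the episode's member records.
#' @return `"monomicrobial"` or `"polymicrobial"`.
#' @export
classify_polymicrobial <- function(organism_names) {
  if (length(organism_names) == 0) stop("episode has no member organisms")
  n_types <- length(unique(.norm_org(organism_names)))
  if (n_types >= 2) "polymicrobial" else "monomicrobial"
}

#' Time offsets between an episode's culture dates and hospital contacts
#'
#' For every combination of a member best-estimate-date and a contact,
#' `time_in = best-estimate-date - indate` and
#' `time_out = best-estimate-date - outdate` (integer days). Pairs with
#' `time_in < -2` (contact began more than 2 days after the culture) or
#' `time_out > 30` (contact ended more than 30 days before the culture) are
#' omitted; outpatient contacts enter only when `include_outpatient` — place
#' of onset considers inpatient admissions only, healthcare association
#' considers both.
#'
#' @param episode_dates `Date` vector of the episode's member
#'   best-estimate-dates.
#' @param contacts The patient's validated contact table.
#' @param include_outpatient Include ambulatory/emergency-room contacts?
#' @return A `data.frame` of retained pairs: `contact_id`, `contact_type`,
#'   `episode_date`, `time_in`, `time_out`, `stay` (= `outdate - indate`).
#' @export
compute_time_offsets <- function(episode_dates, contacts,
                                 include_outpatient = FALSE) {
  if (!include_outpatient) {
    contacts <- contacts[contacts$contact_type == "inpatient", , drop = FALSE]
  }
  episode_dates <- sort(unique(episode_dates))
  if (nrow(contacts) == 0 || length(episode_dates) == 0) {
    return(data.frame(contact_id = character(), contact_type = character(),
                      episode_date = as.Date(character()),
                      time_in = integer(), time_out = integer(),
                      stay = integer(), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(ci = seq_len(nrow(contacts)),
                      di = seq_along(episode_dates))
  bed <- episode_dates[grid$di]
  out <- data.frame(
    contact_id = contacts$contact_id[grid$ci],
    contact_type = contacts$contact_type[grid$ci],
    episode_date = bed,
    time_in = as.integer(bed - contacts$indate[grid$ci]),
    time_out = as.integer(bed - contacts$outdate[grid$ci]),
    stay = as.integer(contacts$outdate[grid$ci] - contacts$indate[grid$ci]),
    stringsAsFactors = FALSE
  )
  out <- out[out$time_in >= -2 & out$time_out <= 30, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place of onset of a bloodstream-infection episode
#'
#' Decided from the retained inpatient time-offset pairs
#' ([compute_time_offsets()] with `include_outpatient = FALSE`):
#'
#' * lowest `time_in` at least 2 — the patient had already been in hospital
#'   for 2+ days: **hospital onset**;
#' * lowest `time_in` 0 or 1 — admitted the day of (or before) the culture;
#'   still hospital onset when a transfer pattern shows the patient arrived
#'   from another ward rather than from home: either (i) some retained
#'   contact ended on the culture date (`time_out = 0`) after a stay of at
#'   least 2 days (lowest `time_in` 0) or at least 1 day (lowest `time_in`
#'   1), or (ii) some retained contact spans the culture date from an earlier
#'   admission (`time_in > 1` and `time_out < 0`). Otherwise **community
#'   onset**.
#'
#' A negative lowest `time_in` (admission only after the culture) is
#' community onset. With no retained inpatient contact at all the episode is
#' classified community onset with a warning — the rule presumes cultures are
#' drawn in hospital, so this situation signals unusual input rather than a
#' defined rule branch.
#'
#' @param offsets Retained inpatient offset pairs for one episode.
#' @return `"community"` or `"hospital"`.
#' @export
classify_onset <- function(offsets) {
  offsets <- offsets[offsets$contact_type == "inpatient", , drop = FALSE]
  if (nrow(offsets) == 0) {
    warning("no retained inpatient contact for episode; classifying as community onset")
    return("community")
  }
  min_ti <- min(offsets$time_in)
  if (min_ti >= 2) return("hospital")
  if (min_ti %in% c(0L, 1L)) {
    need_stay <- if (min_ti == 0L) 2L else 1L
    transfer_ended_today <- any(offsets$time_out == 0L & offsets$stay >= need_stay)
    transfer_spanning <- any(offsets$time_in > 1L & offsets$time_out < 0L)
    if (transfer_ended_today || transfer_spanning) return("hospital")
  }
  "community"
}

#' Healthcare association of a community-onset episode
#'
#' A community-onset episode is healthcare-associated when the patient had
#' an inpatient or outpatient contact in the 30-day period before the index
#' date: some retained offset pair satisfies
#' `(time_in <= 30 and time_out > 0)` — a contact that began within 30 days
#' before the culture and ended before it — or
#' `(time_in > 30 and 30 >= time_out > 0)` — a longer stay that still ended
#' 1 to 30 days before the culture.
#'
#' @param offsets Retained offset pairs computed with
#'   `include_outpatient = TRUE`.
#' @return `TRUE`/`FALSE`.
#' @export
classify_hca <- function(offsets) {
  any((offsets$time_in <= 30 & offsets$time_out > 0) |
      (offsets$time_in > 30 & offsets$time_out > 0 & offsets$time_out <= 30))
}

#' Classify a table of computer episodes
#'
#' Applies the four rules to every episode: contamination vs BSI, then — for
#' BSI episodes only — mono/polymicrobial and place of onset, and — for
#' community-onset episodes only — healthcare association. Contamination
#' episodes carry `NA` for the labels that do not apply to them; every BSI
#' episode gets exactly one onset label and every community-onset episode
#' exactly one healthcare-association flag. When an episode spans two
#' culture dates, both dates contribute offset pairs and the rules consume
#' the pooled retained pairs.
#'
#' @param episodes Episode table from [build_computer_episodes()] (also
#'   accepts reference episodes for evaluation symmetry — their member
#'   records are classified the same way).
#' @param cultures Validated blood-culture table.
#' @param contacts Validated hospital-contact table.
#' @param lexicon An [organism_lexicon()].
#' @param contamination_window Repeat-growth window in days (default 5).
#' @return `episodes` with `contamination`, `polymicrobial`, `onset`,
#'   `healthcare_associated` filled in, plus an `onset_branch` audit column
#'   naming the rule branch that fired (`admitted_2plus_days`,
#'   `transfer_ended_today`, `transfer_spanning`, `community`,
#'   `no_inpatient_contact`, or `NA` for contamination episodes).
#' @export
classify_episodes <- function(episodes, cultures, contacts,
                              lexicon = organism_lexicon(),
                              contamination_window = 5) {
  if (nrow(episodes) == 0) {
    episodes$onset_branch <- character(0)
    return(episodes)
  }
  cultures <- .with_bed(cultures)
  cultures_by_pt <- split(cultures, cultures$patient_id)
  contacts_by_pt <- split(contacts, contacts$patient_id)
  empty_contacts <- contacts[0, , drop = FALSE]

  n <- nrow(episodes)
  contamination <- logical(n)
  polymicrobial <- rep(NA, n)
  onset <- rep(NA_character_, n)
  hca <- rep(NA, n)
  branch <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    pt <- episodes$patient_id[i]
    recs <- cultures_by_pt[[pt]]
    ctc <- contacts_by_pt[[pt]] %||% empty_contacts
    ep <- episodes[i, , drop = FALSE]
    members <- recs[recs$record_id %in% ep$member_record_ids[[1]], , drop = FALSE]

    contamination[i] <- identical(
      classify_contamination(ep, recs, lexicon, contamination_window),
      "contamination")
    if (contamination[i]) next

    polymicrobial[i] <- identical(
      classify_polymicrobial(members$organism_name), "polymicrobial")

    inpat <- compute_time_offsets(members$bed, ctc, include_outpatient = FALSE)
    onset[i] <- withCallingHandlers(
      classify_onset(inpat),
      warning = function(w) {
        branch[i] <<- "no_inpatient_contact"
        invokeRestart("muffleWarning")
      })
    if (is.na(branch[i])) branch[i] <- .onset_branch(inpat)
    if (onset[i] == "community") {
      allofs <- compute_time_offsets(members$bed, ctc, include_outpatient = TRUE)
      hca[i] <- classify_hca(allofs)
    }
  }
  episodes$contamination <- contamination
  episodes$polymicrobial <- polymicrobial
  episodes$onset <- onset
  episodes$healthcare_associated <- hca
  episodes$onset_branch <- branch
  episodes
}

# Name the onset rule branch that fired, for audit logging.
.onset_branch <- function(offsets) {
  offsets <- offsets[offsets$contact_type == "inpatient", , drop = FALSE]
  if (nrow(offsets) == 0) return("no_inpatient_contact")
  min_ti <- min(offsets$time_in)
  if (min_ti >= 2) return("admitted_2plus_days")
  if (min_ti %in% c(0L, 1L)) {
    need_stay <- if (min_ti == 0L) 2L else 1L
    if (any(offsets$time_out == 0L & offsets$stay >= need_stay))
      return("transfer_ended_today")
    if (any(offsets$time_in > 1L & offsets$time_out < 0L))
      return("transfer_spanning")
  }
  "community"
}
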