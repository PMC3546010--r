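# Synthetic linked registries with planted ground truth. Every episode's
# cultures and contacts are constructed so that the classification rules
# yield the planted class by design (no rejection sampling); physician
# labels equal the truth except for configurable per-comparison flips.

.sim_pathogens <- c("Escherichia coli", "Staphylococcus aureus",
                    "Klebsiella pneumoniae", "Streptococcus pneumoniae",
                    "Enterococcus faecalis", "Pseudomonas aeruginosa",
                    "Candida albicans")
.sim_commensals <- c("Staphylococcus epidermidis", "Staphylococcus hominis",
                     "coagulase-negative staphylococcus",
                     "Corynebacterium striatum", "coryneform rod",
                     "Propionibacterium acnes", "Bacillus cereus",
                     "Micrococcus luteus")

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a registry loosely shaped like a two-hospital Danish
#' cohort of positive blood cultures: roughly a fifth of episodes are
#' contaminations, a tenth of infections polymicrobial, a quarter
#' hospital-onset, 8.8% of records missing the draw date, per-bottle
#' duplicate rows (1-4 per organism at the site numbering per bottle, 1-2 at
#' the site numbering per bottle pair), physician assessment coverage of
#' 90%, and physician labels that disagree with the planted truth at
#' per-comparison flip rates echoing the observed discordance pattern (small
#' for contamination and microbial count, larger for place of onset,
#' largest for healthcare association).
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end Study window (ISO dates).
#' @param episode_rate Expected number of *additional* episodes per patient
#'   beyond the first (Poisson).
#' @param p_contamination Probability an episode is a contamination.
#' @param p_polymicrobial Probability a BSI episode is polymicrobial.
#' @param p_hospital_onset Probability a BSI episode is hospital-onset.
#' @param p_hca Probability a community-onset episode is
#'   healthcare-associated.
#' @param p_transfer Probability a hospital-onset episode is planted through
#'   an intra-hospital transfer pattern rather than a plain long admission.
#' @param p_commensal_repeat Probability a monomicrobial BSI episode is
#'   planted as repeat commensal growth (commensal on the index date and
#'   again 3 days later) rather than as a pathogen.
#' @param p_mixed_poly Probability a polymicrobial episode pairs a pathogen
#'   with a commensal (else two pathogens, occasionally a speciated/
#'   provisional pair).
#' @param missing_draw_date_rate Fraction of culture rows whose draw date is
#'   blanked after construction.
#' @param duplicate_rows Named list of per-site multiplicity distributions
#'   (probabilities over 1..k duplicate rows per organism and date).
#' @param assessment_rate Probability an episode has a recorded physician
#'   assessment.
#' @param flip Named numeric: per-comparison probabilities that the
#'   physician label contradicts the truth (`contamination`, `micro`,
#'   `onset`, `hca`).
#' @param mortality Named numeric: 30-day death probability given the planted
#'   class (`contamination`, `bsi_community`, `bsi_hospital`).
#' @param p_late_death Probability of a death on days 31-365 for episodes
#'   without a 30-day death.
#' @param p_emigration Probability a patient emigrates during follow-up.
#' @param p_lag_culture Probability a patient has a positive culture in the
#'   lag period before the study window (exercises the incident flag).
#' @param seed Integer seed; identical configs reproduce byte-identical
#'   registries.
#' @return A validated list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    n_patients = 600,
    study_start = "2006-01-01", study_end = "2008-12-31",
    episode_rate = 0.15,
    p_contamination = 0.20,
    p_polymicrobial = 0.10,
    p_hospital_onset = 0.25,
    p_hca = 0.15,
    p_transfer = 0.35,
    p_commensal_repeat = 0.03,
    p_mixed_poly = 0.15,
    missing_draw_date_rate = 0.088,
    duplicate_rows = list(herlev = c(0.45, 0.3, 0.15, 0.1),
                          hvidovre = c(0.6, 0.4)),
    assessment_rate = 0.9,
    flip = c(contamination = 0.03, micro = 0.05, onset = 0.17, hca = 0.36),
    mortality = c(contamination = 0.10, bsi_community = 0.20,
                  bsi_hospital = 0.30),
    p_late_death = 0.10,
    p_emigration = 0.001,
    p_lag_culture = 0.02,
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              episode_rate = episode_rate,
              p_contamination = p_contamination,
              p_polymicrobial = p_polymicrobial,
              p_hospital_onset = p_hospital_onset,
              p_hca = p_hca, p_transfer = p_transfer,
              p_commensal_repeat = p_commensal_repeat,
              p_mixed_poly = p_mixed_poly,
              missing_draw_date_rate = missing_draw_date_rate,
              duplicate_rows = duplicate_rows,
              assessment_rate = assessment_rate,
              flip = flip, mortality = mortality,
              p_late_death = p_late_death,
              p_emigration = p_emigration,
              p_lag_culture = p_lag_culture,
              seed = as.integer(seed))
  probs <- c(cfg$p_contamination, cfg$p_polymicrobial, cfg$p_hospital_onset,
             cfg$p_hca, cfg$p_transfer, cfg$p_commensal_repeat,
             cfg$p_mixed_poly, cfg$missing_draw_date_rate,
             cfg$assessment_rate, cfg$flip, cfg$mortality,
             cfg$p_late_death, cfg$p_emigration, cfg$p_lag_culture,
             unlist(cfg$duplicate_rows))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!all(c("contamination", "micro", "onset", "hca") %in% names(cfg$flip))) {
    stop("flip must name contamination, micro, onset, hca")
  }
  if (cfg$study_end <= cfg$study_start) stop("study window is empty")
  if (cfg$n_patients < 1) stop("n_patients must be positive")
  if (cfg$p_hospital_onset >= 1 && cfg$p_hca > 0) {
    stop("inconsistent config: HCA probability > 0 with hospital-onset probability 1")
  }
  structure(cfg, class = "synthetic_cohort_config")
}

#' Contact pattern exercising one branch of the place-of-onset rule
#'
#' Emits admission(s) around an index date so that exactly one branch of the
#' hospital-onset rule fires:
#' * `home_direct` — a single admission 3-10 days before the culture
#'   (lowest `time_in >= 2`): plain hospital onset;
#' * `same_day_transfer` — a prior-ward stay of 2-5 days ending on the
#'   culture date (`time_out = 0`, sufficient stay) plus the receiving-ward
#'   admission on the culture date;
#' * `overlapping_ward` — an earlier admission spanning the culture date
#'   (`time_in > 1`, `time_out < 0`) plus the receiving-ward admission on
#'   the culture date.
#'
#' With no scenario (a community case) the patient is simply admitted on the
#' culture date.
#'
#' @param index_date The episode index date.
#' @param scenario `"home_direct"`, `"same_day_transfer"`, or
#'   `"overlapping_ward"`.
#' @return A `data.frame` of contact rows (`contact_type`, `indate`,
#'   `outdate`).
#' @export
plant_transfer_scenario <- function(index_date,
                                    scenario = c("home_direct",
                                                 "same_day_transfer",
                                                 "overlapping_ward")) {
  scenario <- match.arg(scenario)
  mk <- function(indate, outdate) {
    data.frame(contact_type = "inpatient", indate = indate, outdate = outdate,
               stringsAsFactors = FALSE)
  }
  switch(scenario,
    home_direct = mk(index_date - sample(3:10, 1),
                     index_date + sample(3:10, 1)),
    same_day_transfer = rbind(
      mk(index_date - sample(2:5, 1), index_date),       # prior ward, ends today
      mk(index_date, index_date + sample(3:10, 1))),     # receiving ward
    overlapping_ward = rbind(
      mk(index_date - sample(2:8, 1), index_date + sample(1:3, 1)),  # spans index
      mk(index_date, index_date + sample(3:10, 1)))
  )
}

#' Simulate a linked synthetic cohort
#'
#' Generates the four registry tables (blood cultures, hospital contacts,
#' physician assessments, follow-up) plus a ground-truth table of planted
#' episode classes. Construction guarantees that the classification rules
#' recover every planted class exactly: episodes are spaced at least 75 days
#' apart so that contamination windows, 30-day attachment windows, and the
#' 30-day contact-offset filters of consecutive episodes cannot interact;
#' contacts are placed with [plant_transfer_scenario()] patterns; duplicate
#' per-bottle rows and missing draw dates are injected after construction
#' (missingness only on rows whose receipt date equals the draw date, so the
#' best-estimate-date — and with it the planted truth — is unchanged).
#' Physician labels equal the truth except for per-comparison flips at the
#' configured rates.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list of class `synthetic_cohort`: `cultures`, `contacts`,
#'   `assessments`, `followup`, `truth` (one row per planted episode with
#'   `patient_id`, `index_date`, `contamination`, `polymicrobial`, `onset`,
#'   `hca`, `assessed`), and `config`.
#' @export
simulate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  span <- as.integer(config$study_end - config$study_start)

  cultures <- list(); contacts <- list(); truth <- list()
  assessments <- list(); followup <- list()
  rec_counter <- 0L; ctc_counter <- 0L

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", p)
    site <- if (stats::runif(1) < 0.5) "herlev" else "hvidovre"
    n_ep <- 1L + stats::rpois(1, config$episode_rate)

    # episode index dates, >= 75 days apart, inside the study window
    idx <- config$study_start + sample.int(max(span - 40L, 1L), 1L)
    if (n_ep > 1) {
      for (k in 2:n_ep) {
        nxt <- idx[k - 1] + 75L + sample.int(120L, 1L)
        if (nxt > config$study_end - 5L) break
        idx <- c(idx, nxt)
      }
    }

    pt_cult <- list(); pt_ctc <- list()
    add_culture <- function(org, date) {
      n_dup <- sample(seq_along(config$duplicate_rows[[site]]), 1,
                      prob = config$duplicate_rows[[site]])
      for (j in seq_len(n_dup)) {
        rec_counter <<- rec_counter + 1L
        lag <- sample(0:1, 1)
        pt_cult[[length(pt_cult) + 1L]] <<- data.frame(
          record_id = sprintf("B%07d", rec_counter), patient_id = pid,
          draw_date = date, receipt_date = date + lag,
          organism_name = org, source_site = site, stringsAsFactors = FALSE)
      }
    }
    add_contacts <- function(rows) {
      for (j in seq_len(nrow(rows))) {
        ctc_counter <<- ctc_counter + 1L
        pt_ctc[[length(pt_ctc) + 1L]] <<- data.frame(
          contact_id = sprintf("H%07d", ctc_counter), patient_id = pid,
          contact_type = rows$contact_type[j], indate = rows$indate[j],
          outdate = rows$outdate[j], stringsAsFactors = FALSE)
      }
    }

    died30 <- FALSE; death_date <- as.Date(NA)

    for (k in seq_along(idx)) {
      d <- idx[k]
      contam <- stats::runif(1) < config$p_contamination
      poly <- NA; onset <- NA_character_; hca <- NA

      if (contam) {
        add_culture(sample(.sim_commensals, 1), d)
        # hospitalised when the contaminated culture was drawn
        add_contacts(data.frame(contact_type = "inpatient", indate = d,
                                outdate = d + sample(1:5, 1)))
      } else {
        poly <- stats::runif(1) < config$p_polymicrobial
        two_day <- FALSE
        if (poly) {
          if (stats::runif(1) < config$p_mixed_poly) {
            orgs <- c(sample(.sim_pathogens, 1), sample(.sim_commensals, 1))
          } else if (stats::runif(1) < 0.1) {
            orgs <- c("Candida albicans", "yeast-like organism")
          } else {
            orgs <- sample(.sim_pathogens, 2)
          }
          second_day <- sample(0:1, 1)
          two_day <- second_day == 1L
          add_culture(orgs[1], d)
          add_culture(orgs[2], d + second_day)
        } else if (stats::runif(1) < config$p_commensal_repeat) {
          org <- sample(.sim_commensals, 1)   # repeat commensal growth = BSI
          add_culture(org, d)
          add_culture(org, d + 3L)
        } else {
          add_culture(sample(.sim_pathogens, 1), d)
        }

        hosp <- stats::runif(1) < config$p_hospital_onset
        if (hosp) {
          onset <- "hospital"
          scenario <- if (stats::runif(1) < config$p_transfer) {
            sample(c("same_day_transfer", "overlapping_ward"), 1)
          } else "home_direct"
          add_contacts(plant_transfer_scenario(d, scenario))
        } else {
          onset <- "community"
          # a two-day episode admitted the day before the first culture would
          # trip the spanning-transfer clause via the day-2 culture date, so
          # the day-before admission is planted only for one-day episodes
          add_contacts(data.frame(contact_type = "inpatient",
                                  indate = d - (if (two_day) 0L else sample(0:1, 1)),
                                  outdate = d + sample(3:10, 1)))
          hca <- stats::runif(1) < config$p_hca
          if (hca)

            add_contacts(.plant_hca_contact(d))
        }
      }

      assessed <- stats::runif(1) < config$assessment_rate
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, index_date = d, contamination = contam,
        polymicrobial = poly, onset = onset, hca = hca, assessed = assessed,
        stringsAsFactors = FALSE)
      if (assessed) {
        lab <- .physician_labels(contam, poly, onset, hca, config$flip)
        assessments[[length(assessments) + 1L]] <- data.frame(
          patient_id = pid, assessed_date = d,
          class_onset = lab$onset, class_micro = lab$micro,
          stringsAsFactors = FALSE)
      }

      if (!died30) {
        p_death <- if (contam) config$mortality[["contamination"]]
                   else if (identical(onset, "hospital")) config$mortality[["bsi_hospital"]]
                   else config$mortality[["bsi_community"]]
        if (stats::runif(1) < p_death) {
          died30 <- TRUE
          death_date <- d + sample(0:30, 1)
        }
      }
      if (died30) {      # no cultures after death
        idx <- idx[seq_len(k)]
        break
      }
    }

    # lag-period culture before the first in-study episode (incident check)
    if (stats::runif(1) < config$p_lag_culture) {
      add_culture(sample(.sim_pathogens, 1), idx[1] - sample(40:365, 1))
    }

    if (!died30 && stats::runif(1) < config$p_late_death) {
      death_date <- idx[length(idx)] + sample(31:365, 1)
    }
    emig <- if (is.na(death_date) && stats::runif(1) < config$p_emigration) {
      idx[length(idx)] + sample(5:25, 1)
    } else as.Date(NA)
    followup[[length(followup) + 1L]] <- data.frame(
      patient_id = pid, death_date = death_date, emigration_date = emig,
      comorbidity_category = sample(.comorbidity_levels, 1,
                                    prob = c(0.25, 0.365, 0.385)),
      stringsAsFactors = FALSE)

    cultures <- c(cultures, pt_cult)
    contacts <- c(contacts, pt_ctc)
  }

  cultures <- do.call(rbind, cultures)
  # inject missing draw dates without moving any best-estimate-date:
  # only rows whose receipt equals the draw date are eligible
  eligible <- which(cultures$receipt_date == cultures$draw_date)
  n_blank <- round(config$missing_draw_date_rate * nrow(cultures))
  blank <- sample(eligible, min(n_blank, length(eligible)))
  cultures$draw_date[blank] <- NA

  out <- list(
    cultures = cultures,
    contacts = do.call(rbind, contacts),
    assessments = if (length(assessments)) do.call(rbind, assessments) else
      data.frame(patient_id = character(), assessed_date = as.Date(character()),
                 class_onset = character(), class_micro = character()),
    followup = do.call(rbind, followup),
    truth = do.call(rbind, truth),
    config = config
  )
  structure(out, class = "synthetic_cohort")
}

# HCA-qualifying prior contact: ends 1-30 days before the index date, via
# either disjunct of the rule; half inpatient, half outpatient.
.plant_hca_contact <- function(index_date) {
  type <- sample(c("inpatient", "outpatient"), 1)
  end <- index_date - sample(1:30, 1)
  start <- if (type == "outpatient") end else {
    if (stats::runif(1) < 0.3) index_date - sample(31:60, 1)  # time_in > 30 disjunct
    else end - sample(0:10, 1)
  }
  if (start > end) start <- end
  data.frame(contact_type = type, indate = start, outdate = end,
             stringsAsFactors = FALSE)
}

# Physician labels = truth with independent per-comparison flips.
.physician_labels <- function(contam, poly, onset, hca, flip) {
  flip_contam <- stats::runif(1) < flip[["contamination"]]
  phys_contam <- xor(contam, flip_contam)
  if (phys_contam) {
    return(list(onset = "contamination", micro = "contamination"))
  }
  if (contam) {
    # truth contamination, physician calls it an infection
    return(list(onset = "community_onset", micro = "monomicrobial"))
  }
  phys_poly <- xor(poly, stats::runif(1) < flip[["micro"]])
  phys_hosp <- xor(identical(onset, "hospital"), stats::runif(1) < flip[["onset"]])
  if (phys_hosp) {
    onset_lab <- "hospital_onset"
  } else {
    base_hca <- if (identical(onset, "community")) hca else FALSE
    phys_hca <- xor(base_hca, stats::runif(1) < flip[["hca"]])
    onset_lab <- if (phys_hca) "healthcare_associated" else "community_onset"
  }
  list(onset = onset_lab,
       micro = if (phys_poly) "polymicrobial" else "monomicrobial")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `blood_cultures.csv`, `contacts.csv`, `assessments.csv`,
#' `followup.csv`, and `truth.csv` into `dir`, in the canonical schemas
#' accepted by [read_registry_table()].
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- as.character(df[[col]])
    }
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(cohort$cultures, "blood_cultures.csv")
  wr(cohort$contacts, "contacts.csv")
  wr(cohort$assessments, "assessments.csv")
  wr(cohort$followup, "followup.csv")
  wr(cohort$truth, "truth.csv")
  invisible(dir)
}
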