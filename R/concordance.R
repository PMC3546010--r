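# Concordance evaluation: linking reference to computer episodes, 2x2
# agreement tables, percent agreement, Cohen's kappa with Landis-Koch bands,
# and crude 30-day-mortality odds ratios.

.comparisons <- c("contamination_vs_bsi", "mono_vs_poly",
                  "community_vs_hospital", "hca_vs_not")

#' Link reference episodes to their computer episodes
#'
#' The reference episode is the analytical unit; each is paired with the
#' computer episode of the same patient whose index date equals the
#' reference index date, falling back to the computer episode whose 2-day
#' window contains the reference index date. Because computer episodes of a
#' patient are disjoint, at most one can match. Reference episodes with no
#' counterpart (possible only when the two collections were not built from
#' the same records) are dropped from the pairs and listed in the
#' `"unpaired"` attribute.
#'
#' @param reference Classified reference episode table (labels from the
#'   anchoring physician assessment).
#' @param computer Classified computer episode table
#'   ([classify_episodes()]).
#' @return A `data.frame` with one row per paired reference episode:
#'   physician labels (`phys_onset`, `phys_micro`) and algorithm labels
#'   (`algo_contamination`, `algo_polymicrobial`, `algo_onset`, `algo_hca`),
#'   plus ids and index dates.
#' @export
link_episodes <- function(reference, computer) {
  ref_key <- paste(reference$patient_id, reference$index_date)
  comp_key <- paste(computer$patient_id, computer$index_date)
  comp_key_prev <- paste(computer$patient_id, computer$index_date + 1)
  m <- match(ref_key, comp_key)
  fallback <- match(ref_key, comp_key_prev)   # ref index on day 2 of the window
  both <- !is.na(m) & !is.na(fallback) & m != fallback
  if (any(both)) stop("ambiguous episode pairing; computer episodes overlap")
  m[is.na(m)] <- fallback[is.na(m)]
  unpaired <- reference$episode_id[is.na(m)]
  keep <- !is.na(m)
  pairs <- data.frame(
    ref_episode_id = reference$episode_id[keep],
    comp_episode_id = computer$episode_id[m[keep]],
    patient_id = reference$patient_id[keep],
    index_date = reference$index_date[keep],
    incident = reference$incident[keep],
    phys_onset = reference$ref_class_onset[keep],
    phys_micro = reference$ref_class_micro[keep],
    algo_contamination = computer$contamination[m[keep]],
    algo_polymicrobial = computer$polymicrobial[m[keep]],
    algo_onset = computer$onset[m[keep]],
    algo_hca = computer$healthcare_associated[m[keep]],
    stringsAsFactors = FALSE
  )
  attr(pairs, "unpaired") <- unpaired
  pairs
}

# Per-pair binary labels for one comparison: list(algo=, phys=, eligible=).
# "Positive" follows the reporting convention of the agreement tables:
# bsi, polymicrobial, community onset, healthcare-associated.
.comparison_labels <- function(pairs, comparison) {
  phys_bsi <- pairs$phys_onset != "contamination"
  algo_bsi <- !pairs$algo_contamination
  both_bsi <- phys_bsi & algo_bsi
  switch(comparison,
    contamination_vs_bsi = list(
      eligible = rep(TRUE, nrow(pairs)),
      algo = algo_bsi, phys = phys_bsi),
    mono_vs_poly = list(
      eligible = both_bsi,
      algo = pairs$algo_polymicrobial,
      phys = pairs$phys_micro == "polymicrobial"),
    community_vs_hospital = list(
      eligible = both_bsi,
      algo = pairs$algo_onset == "community",
      phys = pairs$phys_onset %in% c("community_onset", "healthcare_associated")),
    hca_vs_not = list(
      eligible = both_bsi &
        pairs$algo_onset == "community" &
        pairs$phys_onset %in% c("community_onset", "healthcare_associated"),
      algo = pairs$algo_hca,
      phys = pairs$phys_onset == "healthcare_associated")
  )
}

#' Construct a 2x2 agreement table from counts
#'
#' Rows are the computer algorithm, columns the physician assessment; `a` is
#' the concordant "positive" cell (both call the episode BSI, polymicrobial,
#' community-onset, or healthcare-associated, depending on the comparison),
#' `d` the concordant "negative" cell, `b` (algorithm positive / physician
#' negative) and `c` (algorithm negative / physician positive) the
#' discrepant cells.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param comparison One of `"contamination_vs_bsi"`, `"mono_vs_poly"`,
#'   `"community_vs_hospital"`, `"hca_vs_not"`.
#' @return An object of class `agreement_table`.
#' @export
agreement_table <- function(a, b, c, d, comparison = "contamination_vs_bsi") {
  comparison <- match.arg(comparison, .comparisons)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  structure(list(comparison = comparison,
                 a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("2x2 agreement table (", x$comparison, "), rows = algorithm, cols = physician\n",
      sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(algorithm = c("positive", "negative"),
                              physician = c("positive", "negative")))
  print(m)
  pa <- percent_agreement(x)
  k <- cohen_kappa(x)
  cat(sprintf("agreement %.1f%%, kappa %.2f (%s)\n",
              100 * pa, k, landis_koch(k)))
  invisible(x)
}

#' Cross-tabulate algorithm against physician labels
#'
#' Builds the 2x2 [agreement_table()] for one comparison from linked episode
#' pairs. Eligibility follows the evaluation design: the
#' contamination-vs-BSI table uses all pairs; the mono/polymicrobial and
#' community/hospital tables only pairs both sides call BSI; the
#' healthcare-association table only pairs both sides additionally call
#' community-onset. Pairs missing a required label are excluded and counted
#' in the `"excluded"` attribute.
#'
#' @param pairs Linked pairs from [link_episodes()].
#' @param comparison See [agreement_table()].
#' @return An `agreement_table`.
#' @export
cross_tabulate <- function(pairs, comparison = .comparisons) {
  comparison <- match.arg(comparison, .comparisons)
  lab <- .comparison_labels(pairs, comparison)
  usable <- lab$eligible & !is.na(lab$algo) & !is.na(lab$phys)
  excluded <- sum(lab$eligible & (is.na(lab$algo) | is.na(lab$phys)))
  algo <- lab$algo[usable]
  phys <- lab$phys[usable]
  tab <- agreement_table(sum(algo & phys), sum(algo & !phys),
                         sum(!algo & phys), sum(!algo & !phys),
                         comparison)
  attr(tab, "excluded") <- excluded
  tab
}

#' Percent agreement of a 2x2 table
#'
#' @param table An [agreement_table()].
#' @return `(a + d) / (a + b + c + d)`, a fraction in `[0, 1]`.
#' @export
percent_agreement <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  n <- table$a + table$b + table$c + table$d
  if (n == 0) stop("empty agreement table: percent agreement undefined")
  (table$a + table$d) / n
}

#' Cohen's kappa of a 2x2 table
#'
#' Chance-corrected agreement: `kappa = (Po - Pe) / (1 - Pe)` with observed
#' agreement `Po = (a + d) / n` and expected agreement from the marginal
#' products, `Pe = ((a + b)(a + c) + (c + d)(b + d)) / n^2`.
#'
#' @param table An [agreement_table()].
#' @return Kappa in `[-1, 1]`. Degenerate margins (`Pe = 1`) are an error.
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  n <- table$a + table$b + table$c + table$d
  if (n == 0) stop("empty agreement table: kappa undefined")
  po <- (table$a + table$d) / n
  pe <- ((table$a + table$b) * (table$a + table$c) +
         (table$c + table$d) * (table$b + table$d)) / n^2
  if (pe >= 1) stop("degenerate margins (expected agreement 1): kappa undefined")
  (po - pe) / (1 - pe)
}

#' Landis-Koch interpretation band for a kappa value
#'
#' Verbal categories for positive kappa: slight (0-0.2], fair (0.2-0.4],
#' moderate (0.4-0.6], substantial (0.6-0.8], almost perfect (0.8-1.0]. The
#' conventional band edges overlap in print; shared boundaries are assigned
#' to the lower band (0.2 is "slight"), except 0 itself which is "slight".
#' Negative values are labelled "poor".
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return Character: one of `"poor"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost perfect"`.
#' @export
landis_koch <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  out <- bands[pmax(1L, findInterval(kappa, c(0, 0.2, 0.4, 0.6, 0.8),
                                     left.open = TRUE))]
  out[kappa < 0] <- "poor"
  out
}

#' 30-day mortality indicator for episodes
#'
#' Death within 30 days after the index date, day 30 inclusive. Episodes of
#' patients who emigrated before day 30 without a recorded death have
#' incomplete follow-up and are flagged rather than counted as survivors.
#'
#' @param episodes Episode table (or linked pairs) with `patient_id` and
#'   `index_date`.
#' @param followup Validated follow-up table.
#' @return A `data.frame` with `died_30d` (logical) and
#'   `incomplete_followup` (logical), one row per episode.
#' @export
mortality_30d <- function(episodes, followup) {
  m <- match(episodes$patient_id, followup$patient_id)
  death <- followup$death_date[m]
  emig <- followup$emigration_date[m]
  delta <- as.integer(death - episodes$index_date)
  died <- !is.na(delta) & delta >= 0 & delta <= 30
  emig_delta <- as.integer(emig - episodes$index_date)
  incomplete <- !died & !is.na(emig_delta) & emig_delta < 30
  data.frame(died_30d = died, incomplete_followup = incomplete)
}

#' Crude odds ratio with 95% confidence interval
#'
#' Closed-form odds ratio for a single binary exposure,
#' `OR = (d1 * s0) / (d0 * s1)`, identical to the exponentiated coefficient
#' of a logistic regression on the group indicator. The 95% CI uses the
#' log-OR normal approximation with standard error
#' `sqrt(1/d1 + 1/s1 + 1/d0 + 1/s0)`.
#'
#' @param group_deaths,group_survivors Death/survivor counts in the group.
#' @param ref_deaths,ref_survivors Counts in the reference group.
#' @return A list: `or`, `lower`, `upper`.
#' @export
crude_odds_ratio <- function(group_deaths, group_survivors,
                             ref_deaths, ref_survivors) {
  counts <- c(group_deaths, group_survivors, ref_deaths, ref_survivors)
  if (any(counts <= 0)) {
    stop("zero cell in mortality table: odds ratio undefined; ",
         "apply an explicit continuity strategy before calling")
  }
  or <- (group_deaths * ref_survivors) / (ref_deaths * group_survivors)
  se <- sqrt(sum(1 / counts))
  list(or = or,
       lower = exp(log(or) - stats::qnorm(0.975) * se),
       upper = exp(log(or) + stats::qnorm(0.975) * se))
}

#' Crude 30-day-mortality contrasts across the four cells of a comparison
#'
#' Splits the linked pairs into the four cells of one comparison's 2x2 table,
#' counts 30-day deaths and survivors per cell (excluding incomplete
#' follow-up), and reports each cell's crude odds ratio against the
#' concordant cell presumed prognostically worst: both-BSI, both-
#' polymicrobial, both-hospital-onset, both-healthcare-associated.
#'
#' @param pairs Linked pairs from [link_episodes()].
#' @param followup Validated follow-up table.
#' @param comparison See [agreement_table()].
#' @return A `data.frame` with one row per cell: `cell` (`a`/`b`/`c`/`d`),
#'   `algo_positive`, `phys_positive`, `deaths`, `survivors`, `excluded`
#'   (incomplete follow-up), `or`, `lower`, `upper` (`NA` for the reference
#'   cell; `NA` with a note when a zero cell makes the OR undefined).
#' @export
mortality_contrasts <- function(pairs, followup, comparison = .comparisons) {
  comparison <- match.arg(comparison, .comparisons)
  lab <- .comparison_labels(pairs, comparison)
  usable <- lab$eligible & !is.na(lab$algo) & !is.na(lab$phys)
  pairs <- pairs[usable, , drop = FALSE]
  algo <- lab$algo[usable]
  phys <- lab$phys[usable]
  mort <- mortality_30d(pairs, followup)

  # reference = concordant prognostically worst cell
  ref_cell <- if (comparison == "community_vs_hospital") "d" else "a"
  cells <- data.frame(cell = c("a", "b", "c", "d"),
                      algo_positive = c(TRUE, TRUE, FALSE, FALSE),
                      phys_positive = c(TRUE, FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(4)) {
    in_cell <- algo == cells$algo_positive[i] & phys == cells$phys_positive[i]
    ok <- in_cell & !mort$incomplete_followup
    cells$deaths[i] <- sum(mort$died_30d[ok])
    cells$survivors[i] <- sum(!mort$died_30d[ok])
    cells$excluded[i] <- sum(in_cell & mort$incomplete_followup)
  }
  ref <- cells[cells$cell == ref_cell, ]
  cells$or <- cells$lower <- cells$upper <- NA_real_
  cells$note <- ""
  for (i in seq_len(4)) {
    if (cells$cell[i] == ref_cell) {
      cells$note[i] <- "reference"
      next
    }
    counts <- c(cells$deaths[i], cells$survivors[i], ref$deaths, ref$survivors)
    if (any(counts == 0)) {
      cells$note[i] <- "zero cell; OR undefined"
      next
    }
    est <- crude_odds_ratio(cells$deaths[i], cells$survivors[i],
                            ref$deaths, ref$survivors)
    cells$or[i] <- est$or
    cells$lower[i] <- est$lower
    cells$upper[i] <- est$upper
  }
  cells
}
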