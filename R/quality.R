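# round half away from zero at `digits` decimals (base round() is
# round-half-even, which is wrong for report formatting)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

QUALITY_ITEMS <- c(therapy_start_date = "therapy_date",
                   followup_status = "status_label",
                   followup_date = "followup_date")

#' Item completeness of the survival parameters
#'
#' For the three items a Kaplan-Meier analysis needs — therapy start date,
#' follow-up status and follow-up date — counts how many cases have each
#' item documented, and how many have all three, stratified by entry mode
#' (routine documentation vs retrospective transfer) plus the total.
#' A "case" is a patient's current (most recent) follow-up form; pass the
#' `current` element of [deduplicate_forms()] or any one-row-per-patient
#' form data frame. Percentages are rounded half-up to one decimal.
#'
#' @param current_forms data frame of patient-level current forms with an
#'   `entry_mode` column.
#' @return data frame of class `completeness_report`: columns `stratum`
#'   (`routine`, `retrospective`, `total`), `cases`, `item`
#'   (`therapy_start_date`, `followup_status`, `followup_date`,
#'   `all_three`), `available`, `percentage`.
#' @examples
#' doc <- fixture_from_counts(207, c(3, 0, 24), 180, "routine")
#' item_completeness(doc$forms)
#' @export
item_completeness <- function(current_forms) {
  if (inherits(current_forms, "form_document"))
    current_forms <- deduplicate_forms(current_forms)$current
  strata <- list(routine = current_forms$entry_mode %in% "routine",
                 retrospective = current_forms$entry_mode %in% "retrospective",
                 total = rep(TRUE, nrow(current_forms)))
  rows <- list()
  for (s in names(strata)) {
    sub <- current_forms[strata[[s]], , drop = FALSE]
    ncase <- nrow(sub)
    have <- lapply(QUALITY_ITEMS, function(col) !is.na(sub[[col]]))
    avail <- c(vapply(have, sum, 0L), all_three = sum(Reduce(`&`, have)))
    for (it in names(avail)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, cases = ncase, item = it,
        available = unname(avail[it]),
        percentage = if (ncase > 0)
          round_half_up(100 * unname(avail[it]) / ncase, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("completeness_report", "data.frame")
  out
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("Completeness of survival data (cases = patient-level current forms)\n\n")
  wide <- stats::reshape(as.data.frame(x)[, c("stratum", "item", "percentage")],
                         idvar = "stratum", timevar = "item",
                         direction = "wide")
  names(wide) <- sub("^percentage\\.", "", names(wide))
  wide$cases <- x$cases[match(wide$stratum, x$stratum)]
  print(wide[, c("stratum", "cases", names(QUALITY_ITEMS), "all_three")],
        row.names = FALSE)
  invisible(x)
}

#' Form completeness against an eligible population
#'
#' The fraction of eligible patients (for example, all patients with the
#' relevant main diagnosis in a calendar year) that have at least one
#' follow-up form carrying survival information, i.e. both a follow-up
#' date and a follow-up status. Forms of patients outside the eligible set
#' are ignored.
#'
#' @param eligible_ids character vector of eligible patient identifiers
#'   (non-empty).
#' @param forms data frame of follow-up forms, or a `form_document`.
#' @return list with `with_form`, `eligible` and `percentage` (half-up,
#'   one decimal).
#' @export
form_completeness <- function(eligible_ids, forms) {
  if (inherits(forms, "form_document")) forms <- forms$forms
  eligible_ids <- unique(as.character(eligible_ids))
  if (length(eligible_ids) == 0L)
    stop("eligible set is empty; the completeness ratio is undefined",
         call. = FALSE)
  info <- !is.na(forms$followup_date) & !is.na(forms$status_label)
  with_form <- sum(eligible_ids %in% forms$patient_pseudonym[info])
  list(with_form = with_form, eligible = length(eligible_ids),
       percentage = round_half_up(100 * with_form / length(eligible_ids), 1))
}

#' Follow-up completeness as a person-time ratio
#'
#' The ratio of total observed person-time of follow-up to the total
#' potential person-time: each patient's observed time runs from origin to
#' last contact; their potential time runs from origin to death (death
#' closes follow-up, so a patient who died at last contact is completely
#' followed) or, for patients not known to have died, to the end of the
#' study. Reported as a percentage.
#'
#' @param records data frame of survival records with `origin_date`,
#'   `last_contact_date` (`Date`) and `os_event`.
#' @param study_end `Date` (or ISO string): end of the study period; must
#'   not precede any origin. A last contact after `study_end` clamps that
#'   patient's potential time to the last contact, with a warning.
#' @return completeness percentage in `[0, 100]`.
#' @examples
#' rec <- data.frame(origin_date = as.Date(c("2000-01-01", "2000-01-01")),
#'                   last_contact_date = as.Date(c("2005-01-01", "2010-01-01")),
#'                   os_event = c(0L, 0L))
#' clark_completeness(rec, "2010-01-01")  # 75
#' @export
clark_completeness <- function(records, study_end) {
  study_end <- as.Date(study_end)
  origin <- as.Date(records$origin_date)
  last <- as.Date(records$last_contact_date)
  if (any(study_end < origin))
    stop("study_end precedes some origin dates", call. = FALSE)
  observed <- as.numeric(last - origin)
  potential <- ifelse(records$os_event == 1L, observed,
                      as.numeric(study_end - origin))
  over <- records$os_event == 0L & last > study_end
  if (any(over)) {
    warning(sum(over), " record(s) with last contact after study_end; ",
            "potential time clamped to last contact", call. = FALSE)
    potential[over] <- observed[over]
  }
  100 * sum(observed) / sum(potential)
}

#' Combined data-quality report
#'
#' Convenience wrapper producing the item-completeness table plus, when the
#' inputs are given, form completeness and the person-time completeness C.
#'
#' @param current_forms patient-level current forms (see
#'   [item_completeness()]).
#' @param eligible_ids optional eligible patient set for form completeness.
#' @param all_forms forms searched for survival information (defaults to
#'   `current_forms`).
#' @param records optional survival records for Clark's C.
#' @param study_end study end date, required with `records`.
#' @param path optional CSV path for the item table (columns stratum,
#'   cases, item, available, percentage).
#' @return list with elements `items`, and where computed `form` and
#'   `clark_c`.
#' @export
quality_report <- function(current_forms, eligible_ids = NULL,
                           all_forms = current_forms, records = NULL,
                           study_end = NULL, path = NULL) {
  out <- list(items = item_completeness(current_forms))
  if (!is.null(eligible_ids))
    out$form <- form_completeness(eligible_ids, all_forms)
  if (!is.null(records)) {
    if (is.null(study_end))
      stop("study_end is required to compute person-time completeness",
           call. = FALSE)
    out$clark_c <- clark_completeness(records, study_end)
  }
  if (!is.null(path))
    utils::write.csv(as.data.frame(out$items), path, row.names = FALSE)
  out
}
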