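#' Deduplicate multi-form patients
#'
#' Each patient accumulates one follow-up form per visit; analysis uses only
#' the most current form. "Most current" means the latest resolved follow-up
#' date; ties are broken by entry timestamp, then by form id. Forms without
#' a follow-up date never outrank a dated form.
#'
#' @param forms data frame of follow-up forms (the `forms` element of a
#'   [form_document()], or any data frame with the canonical columns).
#' @return list with `current` (one row per patient, the most current form)
#'   and `history` (all forms, sorted ascending within patient by the same
#'   ordering). Deduplication is idempotent: deduplicating the `current`
#'   rows returns them unchanged.
#' @export
deduplicate_forms <- function(forms) {
  if (inherits(forms, "form_document")) forms <- forms$forms
  stopifnot(nrow(forms) >= 0)
  if (nrow(forms) == 0L)
    return(list(current = forms, history = forms))
  fu <- resolve_date(forms$followup_date)
  ts <- forms$entry_timestamp
  ts[is.na(ts)] <- sprintf("~%09d", seq_len(nrow(forms)))[is.na(ts)]
  o <- order(forms$patient_pseudonym, !is.na(fu), fu, ts, forms$form_id,
             na.last = FALSE)
  history <- forms[o, , drop = FALSE]
  last <- !duplicated(history$patient_pseudonym, fromLast = TRUE)
  current <- history[last, , drop = FALSE]
  rownames(current) <- rownames(history) <- NULL
  list(current = current, history = history)
}

#' Build analysis-ready survival records from follow-up forms
#'
#' Turns the raw multi-form documentation into one survival record per
#' patient. The origin of the time axis is the earliest resolved therapy
#' start date (or diagnosis date) across the patient's forms; observation
#' time runs from the origin to the follow-up date of the most current form,
#' in years of 365.25 days. The overall-survival event indicator is the OS
#' flag of the current status. The event-free-survival time runs to the
#' earliest form whose status carries an EFS event (relapse or death); when
#' no such form exists the EFS time equals the observation time with
#' `efs_event = 0`.
#'
#' Patients that cannot be analyzed are excluded, never silently: missing
#' origin date, missing current follow-up date or status, or a follow-up
#' date before the origin (a data error). Exclusions are returned in the
#' `excluded` attribute as a data frame of patient id and reason, which
#' feeds the data-quality reporting.
#'
#' @param doc a `form_document`, or a data frame of forms.
#' @param mapping `status_mapping`; defaults to the document's own mapping
#'   (or [default_status_mappings()] for a bare data frame).
#' @param origin `"therapy"` (default) or `"diagnosis"`: which date starts
#'   the clock.
#' @param group optional named character vector mapping patient ids to a
#'   group label for stratified analysis.
#' @return data frame of survival records (columns `patient_id`,
#'   `department`, `diagnosis_date`, `therapy_date`, `followup_date`,
#'   `status_label`, `os_event`, `efs_event`, `time_years`,
#'   `efs_time_years`, `entry_mode`, `study`, `source`, `group`, plus
#'   `origin_date` and `last_contact_date` as `Date`), with attribute
#'   `excluded`.
#' @examples
#' doc <- simulate_cohort(cohort_spec(n_patients = 20, seed = 7))
#' rec <- build_records(doc)
#' head(rec[, c("patient_id", "time_years", "os_event", "efs_event")])
#' @export
build_records <- function(doc, mapping = NULL,
                          origin = c("therapy", "diagnosis"),
                          group = NULL) {
  origin <- match.arg(origin)
  if (inherits(doc, "form_document")) {
    forms <- doc$forms
    if (is.null(mapping)) mapping <- doc$mapping
  } else {
    forms <- doc
    for (col in FORM_COLS)                 # tolerate partial column sets
      if (is.null(forms[[col]])) forms[[col]] <- NA_character_
    if (is.null(mapping)) mapping <- default_status_mappings()
  }
  origin_col <- if (origin == "therapy") "therapy_date" else "diagnosis_date"
  if (nrow(forms) == 0L) {
    out <- empty_records()
    attr(out, "excluded") <- data.frame(patient_id = character(0),
                                        reason = character(0))
    return(out)
  }
  dd <- deduplicate_forms(forms)
  cur <- dd$current
  flags <- lookup_status(forms$department, forms$status_label, mapping)

  # per-patient earliest resolved origin date across all forms
  odates <- resolve_date(forms[[origin_col]])
  pid <- forms$patient_pseudonym
  origin_by <- tapply(as.numeric(odates), pid, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  # per-patient earliest date of an EFS-positive form (first relapse/death)
  efs_d <- as.numeric(resolve_date(forms$followup_date))
  efs_d[is.na(flags$efs_flag) | flags$efs_flag != 1L] <- NA_real_
  efs_by <- tapply(efs_d, pid, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))

  origin_date <- as.Date(as.vector(origin_by[cur$patient_pseudonym]),
                         origin = "1970-01-01")
  efs_date <- as.Date(as.vector(efs_by[cur$patient_pseudonym]),
                      origin = "1970-01-01")
  last_contact <- resolve_date(cur$followup_date)
  cur_flags <- lookup_status(cur$department, cur$status_label, mapping)
  time_years <- years_between(origin_date, last_contact)
  efs_event <- as.integer(!is.na(efs_date))
  efs_time <- ifelse(efs_event == 1L, years_between(origin_date, efs_date),
                     time_years)

  reason <- rep(NA_character_, nrow(cur))
  reason[is.na(origin_date)] <- paste0("missing_", origin, "_date")
  reason[is.na(reason) & is.na(cur$status_label)] <- "missing_status"
  reason[is.na(reason) & is.na(last_contact)] <- "missing_followup_date"
  neg <- is.na(reason) & (time_years < 0 | efs_time < 0)
  if (any(neg)) {
    warning(sum(neg), " patient(s) with follow-up before origin; excluded",
            call. = FALSE)
    reason[neg] <- "followup_before_origin"
  }
  keep <- is.na(reason)

  out <- data.frame(
    patient_id = cur$patient_pseudonym,
    department = cur$department,
    diagnosis_date = cur$diagnosis_date,
    therapy_date = cur$therapy_date,
    followup_date = cur$followup_date,
    status_label = cur$status_label,
    os_event = cur_flags$os_flag,
    efs_event = pmax(efs_event, cur_flags$efs_flag),
    time_years = time_years,
    efs_time_years = pmin(efs_time, time_years),
    entry_mode = cur$entry_mode,
    study = cur$study,
    source = cur$source,
    group = if (!is.null(group)) unname(group[cur$patient_pseudonym])
            else NA_character_,
    origin_date = origin_date,
    last_contact_date = last_contact,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  excl_df <- data.frame(patient_id = cur$patient_pseudonym[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl_df
  out
}

empty_records <- function() {
  out <- data.frame(matrix(NA_character_, 0, length(RECORD_COLS),
                           dimnames = list(NULL, RECORD_COLS)),
                    stringsAsFactors = FALSE)
  out$os_event <- integer(0); out$efs_event <- integer(0)
  out$time_years <- numeric(0); out$efs_time_years <- numeric(0)
  out$origin_date <- as.Date(character(0))
  out$last_contact_date <- as.Date(character(0))
  out
}

RECORD_COLS <- c("patient_id", "department", "diagnosis_date", "therapy_date",
                 "followup_date", "status_label", "os_event", "efs_event",
                 "time_years", "efs_time_years", "entry_mode", "study",
                 "source", "group")

#' Export survival records as pseudonymized CSV
#'
#' Writes the fixed analysis schema (comma-separated, UTF-8, header):
#' `patient_id, department, diagnosis_date, therapy_date, followup_date,
#' status_label, os_event, efs_event, time_years, efs_time_years,
#' entry_mode, study, source, group`. Rows are ordered by `patient_id`,
#' dates are ISO strings, absent optional values are empty. An optional
#' keyed hash can be applied to the patient identifiers so the export
#' carries stable pseudonyms rather than the source ids.
#'
#' @param records data frame from [build_records()] (or matching the schema).
#' @param path output file; when `NULL` the CSV text is returned.
#' @param pseudonymize_key optional string; when given, patient ids are
#'   replaced by a keyed hash (stable across exports with the same key).
#' @return `path` invisibly, or CSV text.
#' @export
export_csv <- function(records, path = NULL, pseudonymize_key = NULL) {
  out <- records[, RECORD_COLS, drop = FALSE]
  if (!is.null(pseudonymize_key))
    out$patient_id <- keyed_pseudonym(out$patient_id, pseudonymize_key)
  out <- out[order(out$patient_id), , drop = FALSE]
  num <- vapply(out, is.numeric, TRUE) &
    !names(out) %in% c("os_event", "efs_event")
  for (col in names(out)[num]) out[[col]] <- sprintf("%.12g", out[[col]])
  con <- if (is.null(path)) textConnection(NULL, "w") else file(path, "w")
  utils::write.csv(out, con, row.names = FALSE, na = "")
  if (is.null(path)) {
    txt <- paste(textConnectionValue(con), collapse = "\n")
    close(con)
    return(txt)
  }
  close(con)
  invisible(path)
}

#' @rdname export_csv
#' @param text CSV text (alternative to `path`).
#' @export
read_records_csv <- function(path = NULL, text = NULL) {
  rec <- utils::read.csv(if (is.null(path)) textConnection(text) else path,
                         stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(RECORD_COLS, names(rec))
  if (length(missing_cols))
    stop("CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec <- rec[, RECORD_COLS]
  for (col in c("os_event", "efs_event")) rec[[col]] <- as.integer(rec[[col]])
  for (col in c("time_years", "efs_time_years"))
    rec[[col]] <- as.numeric(rec[[col]])
  rec$last_contact_date <- resolve_date(rec$followup_date)
  rec$origin_date <- rec$last_contact_date -
    round(rec$time_years * 365.25)
  rec
}

# Stable keyed pseudonym: a short hex digest of key||id. Uses a simple
# 64-bit FNV-1a accumulator; collision-safety at registry scale, not
# cryptographic strength, is the goal here.
keyed_pseudonym <- function(ids, key) {
  vapply(ids, function(id) {
    bytes <- utf8ToInt(paste0(key, ":", id))
    h1 <- 2166136261; h2 <- 40389
    for (b in bytes) {
      h1 <- ((h1 %% 65536) * 16777619 + bitwXor(b, h1 %/% 65536)) %% 2^31
      h2 <- (h2 * 31 + b) %% 2^31
    }
    sprintf("P%08X%08X", h1, h2)
  }, "", USE.NAMES = FALSE)
}
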