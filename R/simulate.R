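#' Specification of a synthetic follow-up cohort
#'
#' Describes a two-department oncology cohort with relapse and death events,
#' routine vs retrospectively entered forms, imprecise dates and item-level
#' missingness — the statistical structure the follow-up pipeline assumes.
#' Defaults emulate a registry of 965 prostate-cancer/AML patients accrued
#' over 1992-2009 and followed to mid-2010, with death and relapse hazards
#' chosen so that median overall survival is about 16.4 years and median
#' event-free survival about 7.7 years, a roughly 20% routine-documentation
#' share, and per-item missingness of a few percent.
#'
#' @param n_patients number of patients.
#' @param department_mix named fractions summing to 1 over configured
#'   departments.
#' @param hazard_death,hazard_relapse exponential event rates, per year.
#' @param accrual_start,accrual_end origin dates are uniform over this
#'   window (ISO strings or `Date`).
#' @param study_end administrative censoring date.
#' @param routine_fraction fraction of patients documented in routine mode
#'   (the rest are retrospective transfers).
#' @param missing_rates named fractions for `therapy_date`, `status`,
#'   `followup_date` item missingness on the analysis-relevant form.
#' @param imprecise_date_rate fraction of dates recorded at reduced
#'   (month or year) precision.
#' @param interim_form_prob probability that an interim annual visit form
#'   is retained in the record (the final form always is, so forms per
#'   patient average a little above one).
#' @param seed integer RNG seed; identical spec + seed yields an identical
#'   cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 965,
                        department_mix = c(urology = 0.9, haematology = 0.1),
                        hazard_death = log(2) / 16.4,
                        hazard_relapse = log(2) / 7.7 - log(2) / 16.4,
                        accrual_start = "1992-06-03",
                        accrual_end = "2009-12-31",
                        study_end = "2010-05-31",
                        routine_fraction = 0.215,
                        missing_rates = c(therapy_date = 0.024,
                                          status = 0.016,
                                          followup_date = 0.057),
                        imprecise_date_rate = 0.05,
                        interim_form_prob = 0.05,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               department_mix = department_mix,
               hazard_death = hazard_death, hazard_relapse = hazard_relapse,
               accrual_start = as.Date(accrual_start),
               accrual_end = as.Date(accrual_end),
               study_end = as.Date(study_end),
               routine_fraction = routine_fraction,
               missing_rates = missing_rates,
               imprecise_date_rate = imprecise_date_rate,
               interim_form_prob = interim_form_prob,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  if (is.na(s$n_patients) || s$n_patients < 1L)
    stop("n_patients must be a positive integer", call. = FALSE)
  if (abs(sum(s$department_mix) - 1) > 1e-8 || any(s$department_mix < 0))
    stop("department_mix must be non-negative fractions summing to 1",
         call. = FALSE)
  if (s$hazard_death < 0 || s$hazard_relapse < 0)
    stop("hazards must be non-negative", call. = FALSE)
  if (!(s$accrual_start <= s$accrual_end && s$accrual_end <= s$study_end))
    stop("dates must satisfy accrual_start <= accrual_end <= study_end",
         call. = FALSE)
  fr <- c(s$routine_fraction, s$missing_rates, s$imprecise_date_rate,
          s$interim_form_prob)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  need <- c("therapy_date", "status", "followup_date")
  if (!all(need %in% names(s$missing_rates)))
    stop("missing_rates must name therapy_date, status and followup_date",
         call. = FALSE)
  invisible(s)
}

# department vocabularies used by the generator
dept_labels <- function(dep) {
  if (dep == "urology")
    list(free = "Relapse free", relapse = "Relapse (PSA)",
         deaths = c("Death of prostate cancer",
                    "Death independent from prostate cancer",
                    "Death of unknown cause"))
  else
    list(free = "First remission", relapse = "Relapse",
         deaths = c("Death of AML", "Death independent from AML",
                    "Death of unknown cause"))
}

# truncate an ISO day date to month/year precision with probability `rate`
blur_dates <- function(iso, rate) {
  u <- stats::runif(length(iso))
  out <- iso
  mo <- u < rate * 2 / 3
  yr <- u >= rate * 2 / 3 & u < rate
  out[mo] <- substr(iso[mo], 1, 7)
  out[yr] <- substr(iso[yr], 1, 4)
  out
}

#' Simulate a synthetic follow-up cohort
#'
#' Generates one latent disease history per patient — independent
#' exponential times to relapse and to death, with death terminating
#' observation and administrative censoring at the study end — and turns it
#' into follow-up forms: annual interim visit forms (each retained with a
#' small probability; the visit at which a relapse is first seen is always
#' retained) and a final form at death or last contact carrying the current
#' status in the department's vocabulary. Item missingness, reduced date
#' precision and routine/retrospective entry mode are injected at the
#' configured rates.
#'
#' @param spec a [cohort_spec()].
#' @return a `form_document`; the latent event history (origin, relapse,
#'   death and exit times per patient) is attached as attribute `latent`.
#' @examples
#' doc <- simulate_cohort(cohort_spec(n_patients = 50, seed = 42))
#' doc
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_patients
  deps <- sample(names(spec$department_mix), n, TRUE, spec$department_mix)
  span <- as.numeric(spec$accrual_end - spec$accrual_start)
  origin <- spec$accrual_start + floor(stats::runif(n) * (span + 1))
  lag <- sample(0:60, n, TRUE)                       # diagnosis precedes therapy
  death_t <- if (spec$hazard_death > 0)
    stats::rexp(n, spec$hazard_death) else rep(Inf, n)
  relapse_t <- if (spec$hazard_relapse > 0)
    stats::rexp(n, spec$hazard_relapse) else rep(Inf, n)
  max_fu <- years_between(origin, spec$study_end)
  exit_t <- pmin(death_t, max_fu)
  died <- death_t <= max_fu
  relapsed <- relapse_t < exit_t
  routine <- stats::runif(n) < spec$routine_fraction
  miss_ther <- stats::runif(n) < spec$missing_rates["therapy_date"]
  miss_stat <- stats::runif(n) < spec$missing_rates["status"]
  miss_fud <- stats::runif(n) < spec$missing_rates["followup_date"]
  death_lab <- sample(1:3, n, TRUE, prob = c(0.8, 0.1, 0.1))
  in_study <- stats::runif(n) < 0.15
  has_source <- stats::runif(n) < 0.3
  source_lab <- sample(c("general practitioner", "registration office"),
                       n, TRUE)

  rows <- vector("list", 4L * n)
  nr <- 0L
  for (i in seq_len(n)) {
    lab <- dept_labels(deps[i])
    interim <- seq_len(max(0L, floor(exit_t[i] - 1e-9)))
    keep <- stats::runif(length(interim)) < spec$interim_form_prob
    if (relapsed[i]) {
      j_rel <- ceiling(relapse_t[i])
      keep[interim == j_rel] <- TRUE        # the visit that documents relapse
    }
    interim <- interim[keep]
    visit_t <- c(interim, exit_t[i])
    status <- c(ifelse(interim >= relapse_t[i], lab$relapse, lab$free),
                if (died[i]) lab$deaths[death_lab[i]]
                else if (relapsed[i]) lab$relapse else lab$free)
    nf <- length(visit_t)
    fu_date <- format(origin[i] + round(visit_t * 365.25), "%Y-%m-%d")
    ther <- if (miss_ther[i]) NA_character_ else format(origin[i], "%Y-%m-%d")
    diag <- format(origin[i] - lag[i], "%Y-%m-%d")
    # missingness of status / follow-up date hits the current (final) form
    if (miss_stat[i]) status[nf] <- NA_character_
    if (miss_fud[i]) fu_date[nf] <- NA_character_
    for (k in seq_len(nf)) {
      nr <- nr + 1L
      rows[[nr]] <- c(form_id = "", patient_pseudonym = sprintf("P%05d", i),
                      department = deps[i],
                      diagnosis_date = diag, diagnosis_text = "initial tumour",
                      diagnosis_classification = NA_character_,
                      therapy_date = ther,
                      therapy_text = if (deps[i] == "urology")
                        "radical prostatectomy" else "induction chemotherapy",
                      therapy_classification = NA_character_,
                      study = if (in_study[i])
                        paste0(toupper(substr(deps[i], 1, 3)), "-registry")
                        else NA_character_,
                      followup_date = fu_date[k], status_label = status[k],
                      source = if (k == nf && has_source[i]) source_lab[i]
                               else NA_character_,
                      entry_mode = if (routine[i]) "routine" else "retrospective",
                      entry_timestamp = "")
    }
  }
  forms <- as.data.frame(do.call(rbind, rows[seq_len(nr)]),
                         stringsAsFactors = FALSE)
  forms$form_id <- sprintf("F%06d", seq_len(nr))
  forms$entry_timestamp <- format(
    as.POSIXct("2010-07-01 00:00:00", tz = "UTC") + seq_len(nr),
    "%Y-%m-%dT%H:%M:%S")
  if (spec$imprecise_date_rate > 0)
    for (col in DATE_ITEMS) {
      ok <- !is.na(forms[[col]])
      forms[[col]][ok] <- blur_dates(forms[[col]][ok],
                                     spec$imprecise_date_rate)
    }
  studies <- list(urology = "URO-registry", haematology = "HAE-registry")
  doc <- form_document(forms, default_status_mappings(), studies,
                       metadata = list(study_name = "Synthetic follow-up cohort"))
  attr(doc, "latent") <- data.frame(
    patient_pseudonym = sprintf("P%05d", seq_len(n)),
    department = deps, origin_date = origin,
    relapse_years = relapse_t, death_years = death_t,
    exit_years = exit_t, died = died, relapsed = relapsed,
    entry_mode = ifelse(routine, "routine", "retrospective"),
    stringsAsFactors = FALSE)
  doc
}

#' Deterministic completeness fixture from printed counts
#'
#' Reconstructs a one-form-per-patient document with exactly the requested
#' per-item missing counts for the three survival items (therapy start
#' date, follow-up status, follow-up date) and exactly `all_three_present`
#' patients having all items. Feasibility requires
#' `max(missing) <= n - all_three_present <= sum(missing)`; the overlap of
#' the missing sets (patients missing more than one item) is constructed
#' greedily by wrapping the item assignments around the first patients, so
#' the result is deterministic.
#'
#' @param n number of patients (cases).
#' @param missing_per_item integer vector of length 3: missing counts for
#'   therapy start date, follow-up status, follow-up date.
#' @param all_three_present number of patients with all three items.
#' @param entry_mode `"routine"` or `"retrospective"`, applied to all cases.
#' @param department department vocabulary to use.
#' @return a `form_document` with `n` forms.
#' @examples
#' doc <- fixture_from_counts(207, c(3, 0, 24), 180, "routine")
#' item_completeness(doc$forms)
#' @export
fixture_from_counts <- function(n, missing_per_item, all_three_present,
                                entry_mode = c("routine", "retrospective"),
                                department = "urology") {
  entry_mode <- match.arg(entry_mode)
  m <- as.integer(missing_per_item)
  stopifnot(length(m) == 3L)
  n <- as.integer(n); a3 <- as.integer(all_three_present)
  if (any(m < 0) || a3 < 0 || a3 > n)
    stop("counts must be non-negative with all_three_present <= n",
         call. = FALSE)
  u <- n - a3                                  # patients missing >= 1 item
  if (max(m) > u)
    stop("infeasible counts: max(missing_per_item) = ", max(m),
         " exceeds n - all_three_present = ", u, call. = FALSE)
  if (u > sum(m))
    stop("infeasible counts: n - all_three_present = ", u,
         " exceeds sum(missing_per_item) = ", sum(m), call. = FALSE)
  miss <- matrix(FALSE, n, 3L)
  pos <- 0L
  for (k in 1:3) {
    if (m[k] > 0L) {
      idx <- ((pos + seq_len(m[k]) - 1L) %% u) + 1L
      miss[idx, k] <- TRUE
      pos <- pos + m[k]
    }
  }
  free_lab <- dept_labels(department)$free
  forms <- data.frame(
    form_id = sprintf("F%05d", seq_len(n)),
    patient_pseudonym = sprintf("P%05d", seq_len(n)),
    department = department,
    diagnosis_date = "1999-11-20",
    therapy_date = ifelse(miss[, 1], NA_character_, "2000-01-15"),
    followup_date = ifelse(miss[, 3], NA_character_, "2005-06-01"),
    status_label = ifelse(miss[, 2], NA_character_, free_lab),
    entry_mode = entry_mode,
    entry_timestamp = sprintf("2010-03-01T00:00:%02d", seq_len(n) %% 60),
    stringsAsFactors = FALSE)
  form_document(forms)
}
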