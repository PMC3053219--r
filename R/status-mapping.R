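#' Department status vocabularies and their OS/EFS encoding
#'
#' Each department documents follow-up status in its own disease-specific
#' vocabulary (remission stages for acute myeloid leukaemia, PSA relapse for
#' prostate cancer). For survival analysis only two indicators matter: did
#' the status constitute a death (overall-survival event, OS) and did it
#' constitute a relapse or death (event-free-survival event, EFS). A status
#' mapping is the department's code list together with these two flags.
#'
#' Every death is by definition also an EFS event, so `os_flag = 1` forces
#' `efs_flag = 1`; the constructor enforces this.
#'
#' @param department department label, e.g. `"urology"`.
#' @param status_label character vector of status labels.
#' @param os_flag,efs_flag 0/1 vectors, one element per label.
#' @return data frame of class `status_mapping` with columns `department`,
#'   `status_label`, `os_flag`, `efs_flag`.
#' @examples
#' status_mapping("urology",
#'                c("Relapse free", "Relapse (PSA)", "Death of unknown cause"),
#'                os_flag  = c(0, 0, 1),
#'                efs_flag = c(0, 1, 1))
#' @export
status_mapping <- function(department, status_label, os_flag, efs_flag) {
  stopifnot(length(status_label) == length(os_flag),
            length(status_label) == length(efs_flag))
  os_flag <- as.integer(os_flag)
  efs_flag <- as.integer(efs_flag)
  if (!all(os_flag %in% 0:1) || !all(efs_flag %in% 0:1))
    stop("os_flag and efs_flag must be 0 or 1", call. = FALSE)
  if (any(os_flag == 1L & efs_flag == 0L))
    stop("os_flag = 1 implies efs_flag = 1 (a death is always an EFS event)",
         call. = FALSE)
  if (anyDuplicated(status_label))
    stop("duplicated status labels within department '", department, "': ",
         paste(unique(status_label[duplicated(status_label)]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(department = rep_len(as.character(department),
                                         length(status_label)),
                    status_label = as.character(status_label),
                    os_flag = os_flag, efs_flag = efs_flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("status_mapping", "data.frame")
  out
}

#' Built-in status mappings for the two reference departments
#'
#' The haematology (AML) and urology (prostate cancer) vocabularies with
#' their OS/EFS encoding. Remission and relapse-free statuses carry no
#' event; relapse and persistent-disease statuses are EFS events only;
#' all death statuses are both OS and EFS events.
#'
#' @return `status_mapping` data frame covering both departments.
#' @export
default_status_mappings <- function() {
  haem <- status_mapping(
    "haematology",
    c("Initial diagnosis", "Aplasia", "First remission",
      "Complete remission unconfirmed", "Second remission",
      "Relapse", "Persistent AML",
      "Death of AML", "Death independent from AML", "Death of unknown cause"),
    os_flag  = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1),
    efs_flag = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  uro <- status_mapping(
    "urology",
    c("Initial diagnosis", "Relapse free",
      "Relapse (PSA)", "Relapse (imaging)",
      "Death of prostate cancer", "Death independent from prostate cancer",
      "Death of unknown cause"),
    os_flag  = c(0, 0, 0, 0, 1, 1, 1),
    efs_flag = c(0, 0, 1, 1, 1, 1, 1))
  out <- rbind(haem, uro)
  class(out) <- c("status_mapping", "data.frame")
  out
}

#' Map a status label to its OS/EFS event flags
#'
#' @param department department the label belongs to.
#' @param status_label a single status label.
#' @param mapping a `status_mapping` (may cover several departments);
#'   defaults to [default_status_mappings()].
#' @return named integer vector `c(os_flag = , efs_flag = )`.
#' @examples
#' map_status("urology", "Relapse (PSA)")       # os 0, efs 1
#' map_status("haematology", "Death of AML")    # os 1, efs 1
#' @export
map_status <- function(department, status_label,
                       mapping = default_status_mappings()) {
  rows <- mapping[mapping$department == department, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no status mapping configured for department '", department, "'",
         call. = FALSE)
  i <- match(status_label, rows$status_label)
  if (is.na(i))
    stop("unknown status label '", status_label, "' for department '",
         department, "'; valid labels: ",
         paste(rows$status_label, collapse = ", "), call. = FALSE)
  c(os_flag = rows$os_flag[i], efs_flag = rows$efs_flag[i])
}

# Vectorized lookup used by the record builder; returns a data.frame with
# os_flag/efs_flag (NA where the label is NA), erroring on unknown labels.
lookup_status <- function(department, status_label, mapping) {
  os <- efs <- rep(NA_integer_, length(status_label))
  for (dep in unique(department)) {
    rows <- mapping[mapping$department == dep, , drop = FALSE]
    sel <- which(department == dep & !is.na(status_label))
    if (!length(sel)) next
    if (nrow(rows) == 0L)
      stop("no status mapping configured for department '", dep, "'",
           call. = FALSE)
    i <- match(status_label[sel], rows$status_label)
    if (anyNA(i))
      stop("unknown status label '", status_label[sel][which(is.na(i))[1]],
           "' for department '", dep, "'; valid labels: ",
           paste(rows$status_label, collapse = ", "), call. = FALSE)
    os[sel] <- rows$os_flag[i]
    efs[sel] <- rows$efs_flag[i]
  }
  data.frame(os_flag = os, efs_flag = efs)
}

#' Read or write a status-mapping configuration file
#'
#' The configuration mirrors the departmental code lists: a JSON (or YAML)
#' object with one entry per department, each holding `status` (label,
#' os, efs triples) and optionally `studies`.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_mapping()` returns a `status_mapping`; `write_mapping()`
#'   returns `path` invisibly.
#' @export
read_mapping <- function(path) {
  cfg <- read_config(path)
  parts <- lapply(names(cfg), function(dep) {
    st <- cfg[[dep]]$status
    status_mapping(dep,
                   vapply(st, `[[`, "", "label"),
                   vapply(st, function(e) as.numeric(e$os), 0),
                   vapply(st, function(e) as.numeric(e$efs), 0))
  })
  out <- do.call(rbind, parts)
  class(out) <- c("status_mapping", "data.frame")
  out
}

#' @rdname read_mapping
#' @param mapping a `status_mapping` to serialize.
#' @param studies optional named list of study label vectors per department.
#' @export
write_mapping <- function(mapping, path, studies = NULL) {
  cfg <- lapply(split(mapping, mapping$department), function(rows) {
    out <- list(status = lapply(seq_len(nrow(rows)), function(i) {
      list(label = rows$status_label[i],
           os = rows$os_flag[i], efs = rows$efs_flag[i])
    }))
    st <- studies[[rows$department[1]]]
    if (!is.null(st)) out$studies <- as.list(st)
    out
  })
  write_config(cfg, path)
  invisible(path)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configuration",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

write_config <- function(x, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML configuration",
           call. = FALSE)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
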