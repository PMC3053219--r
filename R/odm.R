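# Canonical column set of a follow-up form: the 13-attribute common core
# (identity, diagnosis, therapy, study, follow-up item groups) plus the
# bookkeeping keys form_id and entry_timestamp.
FORM_COLS <- c("form_id", "patient_pseudonym", "department",
               "diagnosis_date", "diagnosis_text", "diagnosis_classification",
               "therapy_date", "therapy_text", "therapy_classification",
               "study",
               "followup_date", "status_label", "source",
               "entry_mode", "entry_timestamp")

# item OID -> item group, mirroring the five item groups of the form
ITEM_GROUPS <- list(
  identity = c("department"),
  diagnosis = c("diagnosis_date", "diagnosis_text", "diagnosis_classification"),
  therapy  = c("therapy_date", "therapy_text", "therapy_classification"),
  study    = c("study"),
  followup = c("followup_date", "status_label", "source",
               "entry_mode", "entry_timestamp"))

DATE_ITEMS <- c("diagnosis_date", "therapy_date", "followup_date")

odm_ns <- "http://www.cdisc.org/ns/odm/v1.3"

#' Construct a follow-up form document
#'
#' A form document bundles an ordered collection of follow-up forms (one row
#' per documentation event, several rows per patient over the course of the
#' disease) with the departmental code lists needed to interpret them and
#' free metadata (study identifiers, opaque concept annotations per item).
#'
#' @param forms data frame with (a subset of) the canonical form columns:
#'   `form_id`, `patient_pseudonym`, `department`, `diagnosis_date`,
#'   `diagnosis_text`, `diagnosis_classification`, `therapy_date`,
#'   `therapy_text`, `therapy_classification`, `study`, `followup_date`,
#'   `status_label`, `source`, `entry_mode`, `entry_timestamp`. Missing
#'   columns are added as `NA`; date columns hold ISO truncated strings
#'   (see [imprecise_date()]).
#' @param mapping `status_mapping` covering every department appearing in
#'   `forms`.
#' @param studies optional named list: department -> character vector of
#'   study labels.
#' @param metadata optional list of document metadata; the element
#'   `annotations` (named character, item -> concept code) is serialized as
#'   item aliases.
#' @return object of class `form_document`.
#' @export
form_document <- function(forms = NULL, mapping = default_status_mappings(),
                          studies = NULL, metadata = list()) {
  if (is.null(forms))
    forms <- data.frame(matrix(NA_character_, 0, length(FORM_COLS),
                               dimnames = list(NULL, FORM_COLS)),
                        stringsAsFactors = FALSE)
  forms <- as.data.frame(forms, stringsAsFactors = FALSE)
  for (col in FORM_COLS)
    if (is.null(forms[[col]])) forms[[col]] <- NA_character_
  forms <- forms[, FORM_COLS]
  for (col in FORM_COLS) forms[[col]] <- as.character(forms[[col]])
  rownames(forms) <- NULL
  if (is.null(studies)) {
    studies <- lapply(unique(mapping$department), function(d) character(0))
    names(studies) <- unique(mapping$department)
  }
  doc <- structure(list(forms = forms, mapping = mapping, studies = studies,
                        metadata = metadata),
                   class = "form_document")
  validate_form_document(doc)
  doc
}

validate_form_document <- function(doc) {
  forms <- doc$forms
  if (anyDuplicated(forms$form_id))
    stop("form_id values must be unique within a document: ",
         paste(unique(forms$form_id[duplicated(forms$form_id)]),
               collapse = ", "), call. = FALSE)
  deps <- unique(stats::na.omit(forms$department))
  known <- unique(doc$mapping$department)
  if (length(setdiff(deps, known)))
    stop("department(s) without a configured code list: ",
         paste(setdiff(deps, known), collapse = ", "), call. = FALSE)
  for (col in DATE_ITEMS) validate_imprecise(forms[[col]])
  em <- forms$entry_mode
  if (any(!is.na(em) & !em %in% c("routine", "retrospective")))
    stop("entry_mode must be 'routine' or 'retrospective'", call. = FALSE)
  # every present status label must resolve against its department list
  lookup_status(forms$department, forms$status_label, doc$mapping)
  invisible(doc)
}

#' @export
print.form_document <- function(x, ...) {
  cat("Follow-up form document\n")
  cat("  forms:    ", nrow(x$forms), " (",
      length(unique(x$forms$patient_pseudonym)), " patients)\n", sep = "")
  cat("  departments:", paste(unique(x$mapping$department), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a form document to ODM-style XML
#'
#' Writes the supported dialect of CDISC ODM 1.3.1: a `Study` element whose
#' `MetaDataVersion` defines the five item groups (identity, diagnosis,
#' therapy, study data, follow-up data), the item definitions with optional
#' concept-code aliases, and per-department code lists carrying the OS/EFS
#' flags as aliases; followed by `ClinicalData` with one `FormData` per
#' follow-up form. Output is deterministic: identical documents serialize to
#' byte-identical XML.
#'
#' @param doc a `form_document`.
#' @param path optional file path; when omitted the XML is returned as a
#'   string.
#' @return `path` invisibly, or the XML text when `path` is `NULL`.
#' @export
write_odm <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "form_document"))
  validate_form_document(doc)
  root <- xml2::xml_new_root("ODM", xmlns = odm_ns,
                             FileOID = "survtrack.followup",
                             FileType = "Snapshot", ODMVersion = "1.3.1")
  study <- xml2::xml_add_child(root, "Study", OID = "ST.followup")
  gv <- xml2::xml_add_child(study, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName",
                      doc$metadata$study_name %||% "Oncological follow-up")
  xml2::xml_add_child(gv, "StudyDescription",
                      "Generic follow-up documentation for survival analysis")
  xml2::xml_add_child(gv, "ProtocolName", "followup")
  mdv <- xml2::xml_add_child(study, "MetaDataVersion", OID = "MDV.1",
                             Name = "Follow-up form")
  fdef <- xml2::xml_add_child(mdv, "FormDef", OID = "F.followup",
                              Name = "Follow-up form", Repeating = "Yes")
  for (g in names(ITEM_GROUPS))
    xml2::xml_add_child(fdef, "ItemGroupRef",
                        ItemGroupOID = paste0("IG.", g), Mandatory = "No")
  for (g in names(ITEM_GROUPS)) {
    gdef <- xml2::xml_add_child(mdv, "ItemGroupDef",
                                OID = paste0("IG.", g), Name = g,
                                Repeating = "No")
    for (it in ITEM_GROUPS[[g]])
      xml2::xml_add_child(gdef, "ItemRef", ItemOID = paste0("IT.", it),
                          Mandatory = "No")
  }
  ann <- doc$metadata$annotations
  for (it in unlist(ITEM_GROUPS, use.names = FALSE)) {
    dtype <- if (it %in% DATE_ITEMS) "partialDate"
             else if (it == "entry_timestamp") "datetime" else "text"
    idef <- xml2::xml_add_child(mdv, "ItemDef", OID = paste0("IT.", it),
                                Name = it, DataType = dtype)
    if (!is.null(ann) && !is.na(ann[it]) && !is.null(ann[[it]]))
      xml2::xml_add_child(idef, "Alias", Context = "concept",
                          Name = as.character(ann[[it]]))
  }
  for (dep in unique(doc$mapping$department)) {
    rows <- doc$mapping[doc$mapping$department == dep, , drop = FALSE]
    cl <- xml2::xml_add_child(mdv, "CodeList",
                              OID = paste0("CL.status.", dep),
                              Name = paste("status", dep), DataType = "text")
    for (i in seq_len(nrow(rows))) {
      item <- xml2::xml_add_child(cl, "CodeListItem",
                                  CodedValue = rows$status_label[i])
      xml2::xml_add_child(item, "Alias", Context = "os_flag",
                          Name = as.character(rows$os_flag[i]))
      xml2::xml_add_child(item, "Alias", Context = "efs_flag",
                          Name = as.character(rows$efs_flag[i]))
    }
    st <- doc$studies[[dep]]
    if (length(st)) {
      cls <- xml2::xml_add_child(mdv, "CodeList",
                                 OID = paste0("CL.study.", dep),
                                 Name = paste("study", dep), DataType = "text")
      for (s in st)
        xml2::xml_add_child(cls, "CodeListItem", CodedValue = s)
    }
  }
  cd <- xml2::xml_add_child(root, "ClinicalData", StudyOID = "ST.followup",
                            MetaDataVersionOID = "MDV.1")
  forms <- doc$forms
  for (pat in unique(forms$patient_pseudonym)) {
    sub <- xml2::xml_add_child(cd, "SubjectData", SubjectKey = pat)
    sed <- xml2::xml_add_child(sub, "StudyEventData",
                               StudyEventOID = "SE.followup",
                               StudyEventRepeatKey = "1")
    for (i in which(forms$patient_pseudonym == pat)) {
      fd <- xml2::xml_add_child(sed, "FormData", FormOID = "F.followup",
                                FormRepeatKey = forms$form_id[i])
      for (g in names(ITEM_GROUPS)) {
        items <- ITEM_GROUPS[[g]]
        vals <- unlist(forms[i, items, drop = TRUE])
        if (all(is.na(vals))) next
        igd <- xml2::xml_add_child(fd, "ItemGroupData",
                                   ItemGroupOID = paste0("IG.", g))
        for (it in items)
          if (!is.na(forms[i, it]))
            xml2::xml_add_child(igd, "ItemData", ItemOID = paste0("IT.", it),
                                Value = forms[i, it])
      }
    }
  }
  txt <- as.character(root)
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Parse an ODM-style XML follow-up document
#'
#' Reads the dialect written by [write_odm()]: departmental status code
#' lists (with OS/EFS flags carried as aliases), study code lists, item
#' concept annotations, and one follow-up form per `FormData` element.
#' Items absent from a form yield `NA` fields; the form itself is kept.
#' Every status label found in the clinical data must resolve against its
#' department's code list, otherwise a vocabulary error names the label
#' and department.
#'
#' @param x XML text, a file path, or a connection accepted by
#'   [xml2::read_xml()].
#' @return a `form_document`.
#' @export
parse_odm <- function(x) {
  xml <- xml2::read_xml(x)
  xml2::xml_ns_strip(xml)
  cls <- xml2::xml_find_all(xml, ".//CodeList")
  map_rows <- list(); studies <- list()
  for (cl in cls) {
    oid <- xml2::xml_attr(cl, "OID")
    items <- xml2::xml_find_all(cl, "./CodeListItem")
    if (grepl("^CL\\.status\\.", oid)) {
      dep <- sub("^CL\\.status\\.", "", oid)
      lab <- xml2::xml_attr(items, "CodedValue")
      osf <- as.integer(xml2::xml_attr(
        xml2::xml_find_first(items, "./Alias[@Context='os_flag']"), "Name"))
      eff <- as.integer(xml2::xml_attr(
        xml2::xml_find_first(items, "./Alias[@Context='efs_flag']"), "Name"))
      map_rows[[dep]] <- status_mapping(dep, lab, osf, eff)
    } else if (grepl("^CL\\.study\\.", oid)) {
      dep <- sub("^CL\\.study\\.", "", oid)
      studies[[dep]] <- xml2::xml_attr(items, "CodedValue")
    }
  }
  if (!length(map_rows))
    stop("document contains no status code lists", call. = FALSE)
  mapping <- do.call(rbind, unname(map_rows))
  class(mapping) <- c("status_mapping", "data.frame")
  for (dep in unique(mapping$department))
    if (is.null(studies[[dep]])) studies[[dep]] <- character(0)
  idefs <- xml2::xml_find_all(xml, ".//ItemDef")
  ann <- character(0)
  for (idef in idefs) {
    a <- xml2::xml_find_first(idef, "./Alias[@Context='concept']")
    if (!inherits(a, "xml_missing"))
      ann[sub("^IT\\.", "", xml2::xml_attr(idef, "OID"))] <-
        xml2::xml_attr(a, "Name")
  }
  name <- xml2::xml_text(xml2::xml_find_first(xml, ".//StudyName"))

  fds <- xml2::xml_find_all(xml, ".//FormData")
  rows <- lapply(fds, function(fd) {
    pat <- xml2::xml_attr(xml2::xml_find_first(fd, "./ancestor::SubjectData"),
                          "SubjectKey")
    row <- stats::setNames(rep(NA_character_, length(FORM_COLS)), FORM_COLS)
    row["form_id"] <- xml2::xml_attr(fd, "FormRepeatKey")
    row["patient_pseudonym"] <- pat
    its <- xml2::xml_find_all(fd, ".//ItemData")
    keys <- sub("^IT\\.", "", xml2::xml_attr(its, "ItemOID"))
    keep <- keys %in% FORM_COLS
    row[keys[keep]] <- xml2::xml_attr(its, "Value")[keep]
    row
  })
  forms <- if (length(rows))
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  else NULL
  meta <- list(study_name = if (is.na(name)) NULL else name)
  if (length(ann)) meta$annotations <- ann
  form_document(forms, mapping, studies, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
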