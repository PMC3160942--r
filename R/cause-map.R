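#' Build a cause map
#'
#' A cause map recodes fine-grained cause-of-death labels (hospital or
#' physician ICD-10-style diagnoses) onto the condensed common cause list so
#' that methods with different native vocabularies can be cross-tabulated.
#' Matching is case-insensitive on trimmed labels; no fuzzy matching, so
#' every recode is auditable.
#'
#' @param entries Data frame with columns `source_label` and
#'   `condensed_category` (extra columns ignored).
#' @param cause_list Optional character vector of valid condensed
#'   categories; when given, every target must belong to it.
#' @param default_category Category for labels the map does not cover
#'   (default `"other"`).
#' @return An object of class `va_cause_map`.
#' @export
cause_map <- function(entries, cause_list = NULL, default_category = "other") {
  stopifnot(is.data.frame(entries),
            all(c("source_label", "condensed_category") %in% names(entries)))
  entries <- tibble::tibble(
    source_label = norm_label(entries$source_label),
    condensed_category = trimws(entries$condensed_category)
  )
  dup <- duplicated(entries)
  if (any(dup)) {
    warning("Dropping ", sum(dup), " duplicate cause-map rows.", call. = FALSE)
    entries <- entries[!dup, ]
  }
  conflict <- entries$source_label[duplicated(entries$source_label)]
  if (length(conflict) > 0) {
    stop("Source label(s) mapped to conflicting targets: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cause_list)) {
    check_cause_list(cause_list)
    bad <- setdiff(unique(entries$condensed_category),
                   with_indeterminate(cause_list))
    if (length(bad) > 0) {
      stop("Map targets not in the cause list: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!default_category %in% with_indeterminate(cause_list)) {
      stop("`default_category` (\"", default_category,
           "\") is not in the cause list.", call. = FALSE)
    }
  }
  structure(
    list(entries = entries, cause_list = cause_list,
         default_category = default_category),
    class = "va_cause_map"
  )
}

norm_label <- function(x) tolower(trimws(x))

#' @export
print.va_cause_map <- function(x, ...) {
  cat("<va_cause_map> ", nrow(x$entries), " entries -> ",
      length(unique(x$entries$condensed_category)),
      " condensed categories (default: \"", x$default_category, "\")\n",
      sep = "")
  invisible(x)
}

#' Load / write a cause map as two-column CSV
#'
#' File format: header `source_label,condensed_category`, one mapping per
#' row.
#'
#' @param path File path.
#' @inheritParams cause_map
#' @return [load_cause_map()] returns a validated `va_cause_map`;
#'   [write_cause_map_csv()] returns `path` invisibly.
#' @export
load_cause_map <- function(path, cause_list = NULL,
                           default_category = "other") {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("source_label", "condensed_category") %in% names(df))) {
    stop("Cause-map CSV must have columns `source_label,condensed_category` ",
         "(got: ", paste(names(df), collapse = ","), ").", call. = FALSE)
  }
  cause_map(df, cause_list = cause_list, default_category = default_category)
}

#' @param map A `va_cause_map`.
#' @rdname load_cause_map
#' @export
write_cause_map_csv <- function(map, path) {
  stopifnot(inherits(map, "va_cause_map"))
  readr::write_csv(map$entries, path)
  invisible(path)
}

#' Recode cause labels onto the condensed list
#'
#' A label is mapped if the map covers it; kept as-is if it already is a
#' condensed category (which makes recoding idempotent); otherwise sent to
#' the map's default category with a warning. The indeterminate label always
#' passes through unchanged. Recoding is a total function: it never errors
#' on an unseen label.
#'
#' @param labels Character vector of cause labels.
#' @param map A [cause_map()].
#' @return Character vector of condensed categories, same length.
#' @export
#' @examples
#' m <- builtin_cause_map()
#' recode_causes(c("Asthma", "stroke", "tuberculosis (pulmonary)"), m)
recode_causes <- function(labels, map) {
  stopifnot(inherits(map, "va_cause_map"), is.character(labels))
  if (any(!nzchar(trimws(labels)) | is.na(labels))) {
    stop("Cause labels must be non-empty.", call. = FALSE)
  }
  key <- norm_label(labels)
  hit <- match(key, map$entries$source_label)
  out <- map$entries$condensed_category[hit]
  condensed <- unique(c(map$entries$condensed_category,
                        map$cause_list, va_indeterminate()))
  already <- is.na(hit) & key %in% norm_label(condensed)
  # keep canonical capitalization of the condensed list
  out[already] <- condensed[match(key[already], norm_label(condensed))]
  unmapped <- is.na(hit) & !already
  if (any(unmapped)) {
    warning("Unmapped label(s) sent to \"", map$default_category, "\": ",
            paste(utils::head(unique(labels[unmapped]), 5), collapse = ", "),
            call. = FALSE)
    out[unmapped] <- map$default_category
  }
  out
}

#' The built-in condensed-list recoding rules
#'
#' Ships the standard merges used when comparing hospital and physician
#' diagnoses with a 35-category VA cause list: asthma and bronchitis become
#' chronic respiratory diseases; rabies, tetanus and sepsis-only deaths
#' become other acute infections; stroke, hypertension and all heart
#' conditions merge into cardiovascular diseases; shigellosis,
#' gastroenteritis and bloody/non-bloody diarrhea merge into
#' diarrhea/gastroenteritis; pneumonia and pneumonia/sepsis stay in the
#' broad pneumonia/sepsis category. Tuberculosis remains distinct from
#' HIV/AIDS. Users extend the map with their own CSV for categories beyond
#' these rules.
#'
#' @param default_category Category for labels outside the rules.
#' @return A `va_cause_map`.
#' @export
builtin_cause_map <- function(default_category = "other") {
  rules <- tibble::tribble(
    ~source_label, ~condensed_category,
    "asthma", "chronic respiratory diseases",
    "bronchitis", "chronic respiratory diseases",
    "chronic obstructive pulmonary disease", "chronic respiratory diseases",
    "rabies", "other acute infections",
    "tetanus", "other acute infections",
    "sepsis", "other acute infections",
    "septicemia", "other acute infections",
    "stroke", "cardiovascular diseases",
    "hypertension", "cardiovascular diseases",
    "heart failure", "cardiovascular diseases",
    "ischemic heart disease", "cardiovascular diseases",
    "shigellosis", "diarrhea/gastroenteritis",
    "gastroenteritis", "diarrhea/gastroenteritis",
    "bloody diarrhea", "diarrhea/gastroenteritis",
    "nonbloody diarrhea", "diarrhea/gastroenteritis",
    "pneumonia", "pneumonia/sepsis",
    "pneumonia/sepsis", "pneumonia/sepsis"
  )
  cause_map(rules, cause_list = demo_cause_list(),
            default_category = default_category)
}

#' A demonstration condensed cause list
#'
#' The condensed common list used by the demo pipeline: the five major adult
#' cause groups observed in East African hospital cohorts plus the broader
#' merge targets of [builtin_cause_map()] and a residual category. Real
#' analyses supply their own ~35-category list.
#'
#' @return Character vector of cause labels.
#' @export
demo_cause_list <- function() {
  c(
    "HIV/AIDS-related death",
    "tuberculosis (pulmonary)",
    "meningitis",
    "cardiovascular diseases",
    "diabetes",
    "chronic respiratory diseases",
    "other acute infections",
    "diarrhea/gastroenteritis",
    "pneumonia/sepsis",
    "malaria",
    "other"
  )
}
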