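## Audit file formats.
##
## CSV: one row per occasion, UTF-8, comma-delimited, header required.
## Columns: site_id, area, item_id, entity_name, entity_kind, health_class,
## child_targeted, sports_related, size_class, setting. Booleans serialized
## as "true"/"false"; a missing size_class is an empty field. Pricing
## records and facility-size covariates are not occasion rows, so the CSV
## round trip covers occasions only; pass them as arguments to read_audit.
##
## JSON: complete audit (schema version, site_id, covariates, occasions
## array, pricing array); round-trips losslessly.

AUDIT_SCHEMA_VERSION <- "1.0"

#' Read a site audit from CSV or JSON
#'
#' CSV files hold one occasion per row under the documented flat schema;
#' unknown columns are ignored with a warning. JSON files hold the complete
#' audit (occasions, pricing indicators, covariates, schema version).
#' Schema violations produce a descriptive error naming the offending row
#' and field.
#'
#' @param path File path.
#' @param format "auto" (by extension), "csv" or "json".
#' @param pricing For CSV input, an optional [pricing_records()] table.
#' @param n_concessions,n_sports_areas For CSV input, facility-size
#'   covariates (default 0).
#' @param site_id For a CSV file with zero occasion rows, the site id to
#'   assign; otherwise taken from the rows (which must agree).
#' @return A validated \code{site_audit}.
#' @export
read_audit <- function(path, format = c("auto", "csv", "json"),
                       pricing = pricing_records(),
                       n_concessions = 0L, n_sports_areas = 0L,
                       site_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    return(audit_from_json(path))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(raw), occasion_columns())
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  missing_cols <- setdiff(occasion_columns(), names(raw))
  if (length(missing_cols)) {
    stop("audit CSV missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    if (is.null(site_id)) {
      stop("empty occasion file: supply site_id explicitly", call. = FALSE)
    }
    return(site_audit(site_id, empty_occasions(), pricing,
                      n_concessions, n_sports_areas))
  }
  occ <- parse_occasion_rows(raw)
  ids <- unique(occ$site_id)
  if (length(ids) > 1L) {
    stop("audit CSV mixes site ids: ", paste(ids, collapse = ", "),
         "; one file per site", call. = FALSE)
  }
  site_audit(ids, occ, pricing, n_concessions, n_sports_areas)
}

parse_occasion_rows <- function(raw) {
  parse_bool <- function(x, field) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad)) {
      stop(sprintf("row %d: field '%s' value '%s' is not a boolean",
                   bad[1], field, x[bad[1]]), call. = FALSE)
    }
    out
  }
  item_id <- suppressWarnings(as.integer(raw$item_id))
  bad <- which(is.na(item_id))
  if (length(bad)) {
    stop(sprintf("row %d: field 'item_id' value '%s' is not an integer",
                 bad[1], raw$item_id[bad[1]]), call. = FALSE)
  }
  bad <- which(item_id < 1L | item_id > n_audit_items())
  if (length(bad)) {
    stop(sprintf("row %d: field 'item_id' value %d outside 1..%d",
                 bad[1], item_id[bad[1]], n_audit_items()), call. = FALSE)
  }
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(x), NA_character_, x)
  marketing_occasions(
    site_id = raw$site_id,
    area = raw$area,
    item_id = item_id,
    entity_name = raw$entity_name,
    entity_kind = raw$entity_kind,
    health_class = blank_to_na(raw$health_class),
    child_targeted = parse_bool(raw$child_targeted, "child_targeted"),
    sports_related = parse_bool(raw$sports_related, "sports_related"),
    size_class = blank_to_na(raw$size_class),
    setting = raw$setting
  )
}

#' Write a site audit to CSV or JSON
#'
#' @param audit A \code{site_audit}.
#' @param path Destination path.
#' @param format "auto" (by extension), "csv" (occasion rows only) or
#'   "json" (full audit, lossless round trip).
#' @return \code{path}, invisibly.
#' @export
write_audit <- function(audit, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(audit, "site_audit"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(
      schema_version = AUDIT_SCHEMA_VERSION,
      site_id = audit$site_id,
      n_concessions = audit$n_concessions,
      n_sports_areas = audit$n_sports_areas,
      occasions = audit$occasions,
      pricing = audit$pricing[c("indicator_id", "triggered")]
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    occ <- audit$occasions
    occ$child_targeted <- ifelse(occ$child_targeted, "true", "false")
    occ$sports_related <- ifelse(occ$sports_related, "true", "false")
    occ$size_class[is.na(occ$size_class)] <- ""
    occ$health_class[is.na(occ$health_class)] <- ""
    utils::write.csv(occ, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

audit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema_version", "site_id", "occasions", "pricing")
  missing_f <- setdiff(need, names(obj))
  if (length(missing_f)) {
    stop("audit JSON missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  occ <- obj$occasions
  if (is.null(occ) || (is.data.frame(occ) && nrow(occ) == 0L) ||
      (!is.data.frame(occ) && length(occ) == 0L)) {
    occ <- empty_occasions()
  } else {
    occ <- as.data.frame(occ, stringsAsFactors = FALSE)
    occ <- marketing_occasions(
      occ$site_id, occ$area, occ$item_id, occ$entity_name, occ$entity_kind,
      occ$health_class, occ$child_targeted, occ$sports_related,
      occ$size_class, occ$setting
    )
  }
  pr <- obj$pricing
  if (is.null(pr) || (is.data.frame(pr) && nrow(pr) == 0L) ||
      (!is.data.frame(pr) && length(pr) == 0L)) {
    pr <- pricing_records()
  } else {
    pr <- as.data.frame(pr, stringsAsFactors = FALSE)
    pr <- pricing_records(pr$indicator_id, pr$triggered)
  }
  site_audit(obj$site_id, occ, pr,
             n_concessions = if (is.null(obj$n_concessions)) 0L else obj$n_concessions,
             n_sports_areas = if (is.null(obj$n_sports_areas)) 0L else obj$n_sports_areas)
}
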