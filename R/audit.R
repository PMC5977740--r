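#' @keywords internal
"_PACKAGE"

## Controlled vocabularies -----------------------------------------------

#' Controlled vocabularies of the audit schema
#'
#' The FoodMATS records marketing occasions against fixed category sets:
#' three ordered healthfulness classes, three ordered physical-size classes,
#' three facility areas, three marketed-entity kinds and two settings.
#' Ordering of the health and size classes matters for scoring and for
#' weighted-kappa reliability analysis.
#'
#' @return A character vector of levels, in increasing order where the
#'   scale is ordered.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
health_levels <- function() c("most_healthy", "less_healthy", "least_healthy")

#' @rdname vocabularies
#' @export
size_levels <- function() c("small", "medium", "large")

#' @rdname vocabularies
#' @export
area_levels <- function() c("food", "sport", "other")

#' @rdname vocabularies
#' @export
entity_kinds <- function() c("product", "brand", "retailer")

#' @rdname vocabularies
#' @export
setting_levels <- function() c("indoor", "outdoor")

# Item layout: 37 audit items = 26 location items (1..26) and 11 pricing
# items (27..37); pricing indicator i corresponds to item 26 + i.
N_LOCATION_ITEMS <- 26L
N_PRICING_INDICATORS <- 11L
N_ITEMS <- N_LOCATION_ITEMS + N_PRICING_INDICATORS

#' Number of audit items and the pricing-item offset
#'
#' The instrument has 37 items: 26 location items where marketing occasions
#' are recorded, and 11 pricing indicators. Pricing indicator \code{i} is
#' item \code{26 + i}.
#' @return An integer.
#' @export
n_audit_items <- function() N_ITEMS

## Occasion table --------------------------------------------------------

occasion_columns <- function() {
  c("site_id", "area", "item_id", "entity_name", "entity_kind",
    "health_class", "child_targeted", "sports_related", "size_class",
    "setting")
}

#' Build a marketing-occasion table
#'
#' One row per observed marketing occasion: any commercial advertising,
#' promotion or messaging of a food or beverage product, brand or retailer
#' in the facility. Product packaging is not an occasion and is never
#' entered. The (entity_name, entity_kind) pair is the identity used for
#' repetition counting.
#'
#' @param site_id Site identifier (recycled).
#' @param area Facility area, one of \code{area_levels()}.
#' @param item_id Integer audit item in 1..37 (location items are 1..26).
#' @param entity_name Name of the marketed product, brand or retailer.
#' @param entity_kind One of \code{entity_kinds()}.
#' @param health_class Ordered healthfulness class or \code{NA} until
#'   classified.
#' @param child_targeted,sports_related Logical design flags.
#' @param size_class Ordered size class or \code{NA} (size is excluded for
#'   some pricing and place occasions).
#' @param setting \code{"indoor"} or \code{"outdoor"}.
#' @return A data.frame with one row per occasion.
#' @export
marketing_occasions <- function(site_id, area, item_id, entity_name,
                                entity_kind = "product",
                                health_class = NA_character_,
                                child_targeted = FALSE,
                                sports_related = FALSE,
                                size_class = NA_character_,
                                setting = "indoor") {
  df <- data.frame(
    site_id = as.character(site_id),
    area = as.character(area),
    item_id = as.integer(item_id),
    entity_name = as.character(entity_name),
    entity_kind = as.character(entity_kind),
    health_class = as.character(health_class),
    child_targeted = as.logical(child_targeted),
    sports_related = as.logical(sports_related),
    size_class = as.character(size_class),
    setting = as.character(setting),
    stringsAsFactors = FALSE
  )
  df
}

empty_occasions <- function() {
  marketing_occasions(character(0), character(0), integer(0), character(0),
                      character(0), character(0), logical(0), logical(0),
                      character(0), character(0))
}

#' Build a pricing-indicator table
#'
#' The instrument has 11 pricing indicators: four relate to overeating or
#' rewards for repeat visits, seven compare prices of healthier and less
#' healthy options. A triggered indicator is classified Least Healthy;
#' an untriggered one carries no classification.
#'
#' @param indicator_id Integer in 1..11.
#' @param triggered Logical.
#' @return A data.frame with columns indicator_id, triggered,
#'   classification.
#' @export
pricing_records <- function(indicator_id = integer(0), triggered = logical(0)) {
  indicator_id <- as.integer(indicator_id)
  triggered <- as.logical(triggered)
  data.frame(
    indicator_id = indicator_id,
    triggered = triggered,
    classification = ifelse(triggered, "least_healthy", NA_character_),
    stringsAsFactors = FALSE
  )
}

## Site audit ------------------------------------------------------------

#' Construct a site audit
#'
#' A site audit bundles everything recorded for one site (one building; two
#' geographically separate buildings are two sites): the marketing
#' occasions, the pricing-indicator records and the facility-size
#' covariates. It is the unit of scoring.
#'
#' @param site_id Site identifier.
#' @param occasions Occasion table from [marketing_occasions()] (may have
#'   zero rows).
#' @param pricing Pricing table from [pricing_records()] (at most 11 rows,
#'   unique indicator ids).
#' @param n_concessions,n_sports_areas Non-negative integer facility-size
#'   covariates.
#' @param check If TRUE (default), stop on the first validation failure.
#' @return An object of class \code{site_audit}.
#' @seealso [validate_audit()], [read_audit()], [foodmats_score()]
#' @export
site_audit <- function(site_id, occasions = empty_occasions(),
                       pricing = pricing_records(),
                       n_concessions = 0L, n_sports_areas = 0L,
                       check = TRUE) {
  audit <- structure(
    list(
      site_id = as.character(site_id)[1],
      occasions = occasions,
      pricing = pricing,
      n_concessions = as.integer(n_concessions),
      n_sports_areas = as.integer(n_sports_areas)
    ),
    class = "site_audit"
  )
  if (check) {
    viol <- validate_audit(audit)
    if (length(viol)) {
      stop("invalid site audit:\n  ", paste(viol, collapse = "\n  "),
           call. = FALSE)
    }
  }
  audit
}

#' Validate a site audit
#'
#' Checks every schema invariant and returns the violations as messages;
#' it never raises. An empty return value means the audit is valid. The
#' verdict is deterministic and does not depend on row order.
#'
#' @param audit A \code{site_audit}.
#' @return Character vector of violation messages (length 0 if valid).
#' @export
validate_audit <- function(audit) {
  v <- character(0)
  if (!inherits(audit, "site_audit")) {
    return("not a site_audit object")
  }
  occ <- audit$occasions
  missing_cols <- setdiff(occasion_columns(), names(occ))
  if (length(missing_cols)) {
    return(paste0("occasion table missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(occ)) {
    bad <- which(occ$site_id != audit$site_id)
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: site_id '%s' does not match audit site '%s'",
                        i, occ$site_id[i], audit$site_id))
    }
    bad <- which(is.na(occ$item_id) | occ$item_id < 1L | occ$item_id > N_ITEMS)
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: item_id %s outside 1..%d",
                        i, occ$item_id[i], N_ITEMS))
    }
    bad <- which(!occ$area %in% area_levels())
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: area '%s' not one of %s",
                        i, occ$area[i], paste(area_levels(), collapse = "/")))
    }
    bad <- which(is.na(occ$entity_name) | !nzchar(occ$entity_name))
    for (i in bad) v <- c(v, sprintf("occasion row %d: entity_name empty", i))
    bad <- which(!occ$entity_kind %in% entity_kinds())
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: entity_kind '%s' not one of %s",
                        i, occ$entity_kind[i], paste(entity_kinds(), collapse = "/")))
    }
    bad <- which(!is.na(occ$health_class) & !occ$health_class %in% health_levels())
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: health_class '%s' not one of %s",
                        i, occ$health_class[i], paste(health_levels(), collapse = "/")))
    }
    bad <- which(!is.na(occ$size_class) & !occ$size_class %in% size_levels())
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: size_class '%s' not one of %s",
                        i, occ$size_class[i], paste(size_levels(), collapse = "/")))
    }
    bad <- which(!occ$setting %in% setting_levels())
    for (i in bad) {
      v <- c(v, sprintf("occasion row %d: setting '%s' not one of %s",
                        i, occ$setting[i], paste(setting_levels(), collapse = "/")))
    }
    bad <- which(is.na(occ$child_targeted) | is.na(occ$sports_related))
    for (i in bad) v <- c(v, sprintf("occasion row %d: missing technique flag", i))
  }
  pr <- audit$pricing
  if (nrow(pr)) {
    if (nrow(pr) > N_PRICING_INDICATORS) {
      v <- c(v, sprintf("pricing table has %d rows; at most %d allowed",
                        nrow(pr), N_PRICING_INDICATORS))
    }
    dup <- unique(pr$indicator_id[duplicated(pr$indicator_id)])
    for (d in dup) v <- c(v, sprintf("duplicate pricing indicator_id %s", d))
    bad <- which(is.na(pr$indicator_id) | pr$indicator_id < 1L |
                   pr$indicator_id > N_PRICING_INDICATORS)
    for (i in bad) {
      v <- c(v, sprintf("pricing row %d: indicator_id %s outside 1..%d",
                        i, pr$indicator_id[i], N_PRICING_INDICATORS))
    }
    bad <- which(pr$triggered & (is.na(pr$classification) |
                                   pr$classification != "least_healthy"))
    for (i in bad) {
      v <- c(v, sprintf("pricing row %d: triggered indicator must be classified least_healthy", i))
    }
    bad <- which(!pr$triggered & !is.na(pr$classification))
    for (i in bad) {
      v <- c(v, sprintf("pricing row %d: untriggered indicator must carry no classification", i))
    }
  }
  if (is.na(audit$n_concessions) || audit$n_concessions < 0L) {
    v <- c(v, "n_concessions must be a non-negative integer")
  }
  if (is.na(audit$n_sports_areas) || audit$n_sports_areas < 0L) {
    v <- c(v, "n_sports_areas must be a non-negative integer")
  }
  v
}

#' @export
print.site_audit <- function(x, ...) {
  cat(sprintf("FoodMATS site audit: site '%s'\n", x$site_id))
  cat(sprintf("  occasions: %d (food %d / sport %d / other %d)\n",
              nrow(x$occasions),
              sum(x$occasions$area == "food"),
              sum(x$occasions$area == "sport"),
              sum(x$occasions$area == "other")))
  cat(sprintf("  pricing indicators recorded: %d (triggered %d)\n",
              nrow(x$pricing), sum(x$pricing$triggered)))
  cat(sprintf("  covariates: %d concession(s), %d sports area(s)\n",
              x$n_concessions, x$n_sports_areas))
  invisible(x)
}

## Rater audit -----------------------------------------------------------

#' Construct a rater's audit
#'
#' Wraps a [site_audit()] with the rater identity and the per-item
#' presence map required for item-level reliability analysis. If
#' \code{item_presence} is omitted it is derived from the audit: a location
#' item is present when at least one occasion was recorded against it, and
#' a pricing item is present when the indicator was triggered.
#'
#' @param rater_id Rater identifier.
#' @param audit A \code{site_audit}.
#' @param item_presence Optional named logical vector covering all 37 items
#'   (names "1".."37").
#' @return An object of class \code{rater_audit}.
#' @export
rater_audit <- function(rater_id, audit, item_presence = NULL) {
  stopifnot(inherits(audit, "site_audit"))
  if (is.null(item_presence)) {
    item_presence <- derive_item_presence(audit)
  }
  if (length(item_presence) != N_ITEMS) {
    stop("item_presence must cover all ", N_ITEMS, " items", call. = FALSE)
  }
  names(item_presence) <- as.character(seq_len(N_ITEMS))
  structure(
    list(rater_id = as.character(rater_id)[1], audit = audit,
         item_presence = item_presence),
    class = "rater_audit"
  )
}

derive_item_presence <- function(audit) {
  pres <- rep(FALSE, N_ITEMS)
  if (nrow(audit$occasions)) {
    pres[unique(audit$occasions$item_id)] <- TRUE
  }
  if (nrow(audit$pricing)) {
    trig <- audit$pricing$indicator_id[audit$pricing$triggered]
    pres[N_LOCATION_ITEMS + trig] <- TRUE
  }
  names(pres) <- as.character(seq_len(N_ITEMS))
  pres
}

#' @export
print.rater_audit <- function(x, ...) {
  cat(sprintf("FoodMATS rater audit: rater '%s', site '%s', %d occasions, %d items present\n",
              x$rater_id, x$audit$site_id, nrow(x$audit$occasions),
              sum(x$item_presence)))
  invisible(x)
}
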