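## Rule-based healthfulness / size / technique classification.
##
## Products and brands are ranked on three ordered classes: Most Healthy
## (unprocessed, no added fat, sugar or salt), Less Healthy (some added
## fat, sugar or salt), Least Healthy (processed energy-dense,
## nutrient-poor). Retailers are ranked by category, falling back to the
## most prominent product sold. The shipped default rule set is keyword
## driven and editable (JSON config), because site-by-site nutrient data
## are rarely available during an audit; an optional added-fat/sugar/salt
## override hook maps directly onto the three classes.

#' Load a classification rule set
#'
#' Rule sets are versioned JSON documents with four parts: an ordered list
#' of product keyword rules (first match wins), a retailer category map, a
#' brand map (brand name to representative product description), and the
#' controlled technique vocabulary. The default shipped with the package
#' can be copied and edited.
#'
#' @param path Path to a rules JSON file; default is the packaged rule set.
#' @return An object of class \code{foodmats_rules}.
#' @export
default_rules <- function(path = system.file("extdata", "foodmats_rules.json",
                                             package = "foodmats")) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- list(
    version = obj$version,
    product_rules = as.data.frame(obj$product_rules, stringsAsFactors = FALSE),
    retailer_rules = unlist(obj$retailer_rules),
    brand_map = unlist(obj$brand_map),
    technique_vocab = list(
      child = unlist(obj$technique_vocab$child),
      sports = unlist(obj$technique_vocab$sports)
    ),
    pricing_indicators = as.data.frame(obj$pricing_indicators,
                                       stringsAsFactors = FALSE)
  )
  bad <- !rules$product_rules$class %in% health_levels()
  if (any(bad)) {
    stop("rule set: product rule class(es) not in health vocabulary: ",
         paste(rules$product_rules$class[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(rules$retailer_rules %in% health_levels())) {
    stop("rule set: retailer class outside health vocabulary", call. = FALSE)
  }
  structure(rules, class = "foodmats_rules")
}

#' @export
print.foodmats_rules <- function(x, ...) {
  cat(sprintf("FoodMATS classification rules v%s: %d product rules, %d retailer categories, %d brands\n",
              x$version, nrow(x$product_rules), length(x$retailer_rules),
              length(x$brand_map)))
  invisible(x)
}

unclassified_error <- function(what) {
  stop(structure(
    class = c("foodmats_unclassified", "error", "condition"),
    list(message = paste0("cannot classify ", what,
                          ": no matching rule; assign manually or extend the rule set"),
         call = NULL)
  ))
}

#' Classify a product's healthfulness
#'
#' Maps a product to the ordered Most/Less/Least Healthy classes. If the
#' added fat/sugar/salt level is supplied it decides directly (none = Most,
#' some = Less, high = Least). Otherwise the ordered keyword rules are
#' applied to the product name, then to the category hint; the first match
#' wins, so rule order is the precedence.
#'
#' @param name Product name (non-empty).
#' @param category_hint Optional free-text category (e.g. "beverage",
#'   "snack") also matched against the rules.
#' @param added_fat_sugar_salt Optional: "none", "some" or "high".
#' @param rules A \code{foodmats_rules} object.
#' @return One of \code{health_levels()}.
#' @export
classify_product <- function(name, category_hint = NULL,
                             added_fat_sugar_salt = NULL,
                             rules = default_rules()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("product name must be a non-empty string", call. = FALSE)
  }
  if (!is.null(added_fat_sugar_salt)) {
    lev <- match.arg(added_fat_sugar_salt, c("none", "some", "high"))
    return(switch(lev, none = "most_healthy", some = "less_healthy",
                  high = "least_healthy"))
  }
  text <- tolower(paste(name, if (!is.null(category_hint)) category_hint else ""))
  for (i in seq_len(nrow(rules$product_rules))) {
    if (grepl(rules$product_rules$pattern[i], text, perl = TRUE)) {
      return(rules$product_rules$class[i])
    }
  }
  unclassified_error(paste0("product '", name, "'"))
}

#' Classify a brand's healthfulness
#'
#' Brands are ranked as per the product rankings, for the product the
#' brand most closely represents (e.g. a cola brand ranks as a sweetened
#' soft drink; a bottled-water brand ranks as water). The brand map in the
#' rule set supplies the representative product.
#'
#' @param brand Brand name.
#' @param rules A \code{foodmats_rules} object.
#' @return One of \code{health_levels()}.
#' @export
classify_brand <- function(brand, rules = default_rules()) {
  if (!is.character(brand) || length(brand) != 1L || !nzchar(brand)) {
    stop("brand name must be a non-empty string", call. = FALSE)
  }
  key <- names(rules$brand_map)[tolower(names(rules$brand_map)) == tolower(brand)]
  if (length(key)) {
    return(classify_product(rules$brand_map[[key[1]]], rules = rules))
  }
  # fall back to the product rules on the brand name itself
  tryCatch(classify_product(brand, rules = rules),
           foodmats_unclassified = function(e) {
             unclassified_error(paste0("brand '", brand, "'"))
           })
}

#' Classify a food retailer's healthfulness
#'
#' Retailer categories map directly onto the three classes (grocery
#' stores, farmers' markets, salad/sandwich/smoothie outlets are Most
#' Healthy; sit-down restaurants, cafeterias, coffee outlets, prepared
#' grocery and supplement stores are Less Healthy; pizza, burger, taco,
#' fried chicken, Asian and ice-cream outlets and pubs/lounges/alcohol
#' stores are Least Healthy). A retailer outside the category list is
#' classified as per its most prominent product sold.
#'
#' @param name Retailer name.
#' @param category Optional retailer category (matched, after
#'   normalisation, against the rule set's category names).
#' @param prominent_product Optional most prominent product sold, used as
#'   fallback via [classify_product()].
#' @param rules A \code{foodmats_rules} object.
#' @return One of \code{health_levels()}.
#' @export
classify_retailer <- function(name, category = NULL, prominent_product = NULL,
                              rules = default_rules()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("retailer name must be a non-empty string", call. = FALSE)
  }
  norm <- function(x) gsub("[^a-z]+", "_", tolower(trimws(x)))
  if (!is.null(category)) {
    key <- norm(category)
    hit <- which(vapply(names(rules$retailer_rules),
                        function(k) grepl(k, key, fixed = TRUE) ||
                          grepl(key, k, fixed = TRUE),
                        logical(1)))
    if (length(hit)) return(unname(rules$retailer_rules[hit[1]]))
  }
  if (!is.null(prominent_product)) {
    return(classify_product(prominent_product, rules = rules))
  }
  tryCatch(classify_product(name, rules = rules),
           foodmats_unclassified = function(e) {
             unclassified_error(paste0("retailer '", name, "'"))
           })
}

#' Classify the physical size of a promotion
#'
#' Size is recorded in multiples of a letter sheet of paper (8.5 x 11 in),
#' with different thresholds indoors and outdoors. Indoors: small < 1
#' sheet, medium 1-3 sheets, large > 3. Outdoors: small < 1, medium 1-10,
#' large > 10. The medium intervals are closed: exactly 1, 3 or 10 sheets
#' is medium.
#'
#' @param sheet_equivalents Positive area in letter-sheet equivalents.
#' @param setting "indoor" or "outdoor".
#' @return One of \code{size_levels()}.
#' @export
classify_size <- function(sheet_equivalents, setting = c("indoor", "outdoor")) {
  setting <- match.arg(setting)
  if (!is.numeric(sheet_equivalents) || length(sheet_equivalents) != 1L ||
      is.na(sheet_equivalents) || sheet_equivalents <= 0) {
    stop("sheet_equivalents must be a positive number", call. = FALSE)
  }
  upper <- if (setting == "indoor") 3 else 10
  if (sheet_equivalents < 1) "small"
  else if (sheet_equivalents <= upper) "medium"
  else "large"
}

#' Derive the technique flags from observer tags
#'
#' Child-targeting techniques include animated or fictional characters,
#' taste appeals, humour, action-adventure, fantasy, fun shapes/colours,
#' competitions, give-aways, cartoonish font and child actors.
#' Sports-related techniques are any reference to physical activity,
#' exercise, sport, game, recreation, performance or competition. The two
#' flags are independent.
#'
#' @param tags Character vector of tags from the controlled vocabulary
#'   (may be empty).
#' @param rules A \code{foodmats_rules} object (holds the vocabulary).
#' @return Named logical vector \code{c(child_targeted=, sports_related=)}.
#' @export
classify_technique <- function(tags = character(0), rules = default_rules()) {
  vocab <- c(rules$technique_vocab$child, rules$technique_vocab$sports)
  unknown <- setdiff(tags, vocab)
  if (length(unknown)) {
    stop("unknown technique tag(s): ", paste(unknown, collapse = ", "),
         "\n  vocabulary: ", paste(vocab, collapse = ", "), call. = FALSE)
  }
  c(child_targeted = any(tags %in% rules$technique_vocab$child),
    sports_related = any(tags %in% rules$technique_vocab$sports))
}

#' Classify a pricing indicator
#'
#' A triggered pricing indicator (pricing that encourages overeating,
#' rewards repeat visits, or prices unhealthy options below healthy ones)
#' is classified Least Healthy; an untriggered indicator carries no
#' classification.
#'
#' @param indicator_id Integer in 1..11.
#' @param triggered Logical.
#' @return A one-row [pricing_records()] table.
#' @export
classify_pricing <- function(indicator_id, triggered) {
  indicator_id <- as.integer(indicator_id)
  if (is.na(indicator_id) || indicator_id < 1L ||
      indicator_id > N_PRICING_INDICATORS) {
    stop("indicator_id must be in 1..", N_PRICING_INDICATORS, call. = FALSE)
  }
  pricing_records(indicator_id, isTRUE(triggered))
}
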