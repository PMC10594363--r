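#' Country unit-cost table
#'
#' Holds the euro-per-unit prices (2020 price level) for event-denominated
#' items, together with the country parameters needed to price the
#' hour-denominated family impacts: the national average wage (human-capital
#' valuation of parental time off work) and the hourly market price of a
#' formal caregiver (valuation of informal care). `inflation_index` is the
#' multiplier that brings costs expressed at an earlier price level (or in
#' another currency) to 2020 euros.
#'
#' @param country Country identifier.
#' @param entries Tibble with columns `item_id`, `category`, `euro_per_unit`.
#'   Hour-denominated parental items may carry `NA` prices; they are priced
#'   from `wage_per_hour` / `informal_care_price_per_hour` instead.
#' @param wage_per_hour National average gross wage, euros/hour.
#' @param informal_care_price_per_hour Formal-caregiver market price,
#'   euros/hour.
#' @param inflation_index Multiplier to 2020 prices, > 0.
#' @return A `unit_cost_table` object.
#' @export
unit_cost_table <- function(country, entries,
                            wage_per_hour = 0,
                            informal_care_price_per_hour = 0,
                            inflation_index = 1) {
  entries <- tibble::as_tibble(entries)
  need <- c("item_id", "category", "euro_per_unit")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns item_id, category, euro_per_unit", call. = FALSE)
  }
  unknown <- setdiff(unique(entries$category), cost_categories())
  if (length(unknown) > 0L) {
    stop("unknown categories in unit-cost table: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(entries$item_id)) {
    stop("duplicate item_id in unit-cost table", call. = FALSE)
  }
  if (any(entries$euro_per_unit < 0, na.rm = TRUE)) {
    stop("unit costs must be nonnegative", call. = FALSE)
  }
  stopifnot(wage_per_hour >= 0, informal_care_price_per_hour >= 0)
  if (!is.numeric(inflation_index) || inflation_index <= 0) {
    stop("inflation_index must be > 0", call. = FALSE)
  }
  structure(
    list(
      country = country, entries = entries,
      wage_per_hour = as.numeric(wage_per_hour),
      informal_care_price_per_hour = as.numeric(informal_care_price_per_hour),
      inflation_index = as.numeric(inflation_index)
    ),
    class = "unit_cost_table"
  )
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("<unit_cost_table> ", x$country, ": ", nrow(x$entries), " items, wage ",
    x$wage_per_hour, " EUR/h, informal care ",
    x$informal_care_price_per_hour, " EUR/h\n",
    sep = ""
  )
  invisible(x)
}

#' Read a unit-cost table and country parameters from disk
#'
#' `read_unit_costs()` reads the item-level CSV (`item_id`, `category`,
#' `euro_per_unit`); `read_country_config()` reads the YAML holding the
#' country parameters (wage, informal-care price, inflation index, discount
#' rate, school recosting, optional out-of-pocket inputs) and, combined with
#' the CSV, returns the assembled [unit_cost_table()] in `$unit_costs`.
#'
#' @param path CSV (unit costs) or YAML (country config) file path.
#' @return `read_unit_costs()`: a tibble of entries. `read_country_config()`:
#'   a list with the country parameters and a ready `unit_costs` table when
#'   `unit_costs_csv` is resolvable.
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) {
    stop("unit-cost file not found: ", path, call. = FALSE)
  }
  entries <- readr::read_csv(
    path,
    col_types = readr::cols(
      item_id = readr::col_character(),
      category = readr::col_character(),
      euro_per_unit = readr::col_double()
    )
  )
  entries
}

#' @rdname read_unit_costs
#' @export
read_country_config <- function(path) {
  if (!file.exists(path)) {
    stop("country config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  need <- c("country", "wage_per_hour", "informal_care_price_per_hour")
  missing_fields <- setdiff(need, names(cfg))
  if (length(missing_fields) > 0L) {
    stop("country config missing fields: ",
      paste(missing_fields, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(cfg$unit_costs_csv)) {
    csv <- cfg$unit_costs_csv
    if (!file.exists(csv)) {
      csv <- file.path(dirname(path), cfg$unit_costs_csv)
    }
    cfg$unit_costs <- unit_cost_table(
      country = cfg$country,
      entries = read_unit_costs(csv),
      wage_per_hour = cfg$wage_per_hour,
      informal_care_price_per_hour = cfg$informal_care_price_per_hour,
      inflation_index = cfg$inflation_index %||% 1
    )
  }
  cfg
}

# Price of one unit of an item: event items from the entries table,
# hour-denominated parental items from the country wage / care price.
item_price <- function(table, item_id, category = NULL) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (is.null(category)) {
    hit <- match(item_id, table$entries$item_id)
    if (is.na(hit)) {
      stop("unknown item id: ", item_id, call. = FALSE)
    }
    category <- table$entries$category[[hit]]
  }
  if (category == "parental_productivity") {
    return(table$wage_per_hour)
  }
  if (category == "parental_informal_care") {
    return(table$informal_care_price_per_hour)
  }
  hit <- match(item_id, table$entries$item_id)
  if (is.na(hit) || is.na(table$entries$euro_per_unit[[hit]])) {
    stop("no unit cost for item id: ", item_id, call. = FALSE)
  }
  table$entries$euro_per_unit[[hit]]
}
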