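#' Read a cost ledger from CSV or JSON
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header, "." decimal mark.
#' Indian digit grouping in money columns ("4,91,040") is accepted on input
#' (the grouping commas must then be quoted) but never emitted on output.
#' JSON mirrors the field names one-to-one: an object with `items` (array of
#' item objects) and the ledger-level parameters.
#'
#' Enum fields (`phase`, `cost_class`, `cost_behavior`) are normalized
#' case-insensitively. File order of items is preserved.
#'
#' @param path file to read.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @return a [cost_ledger()].
#' @seealso [write_ledger()]
#' @export
read_ledger <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") read_ledger_csv(path) else read_ledger_json(path)
}

LEDGER_PARAMS <- c("discount_rate", "cohort_size", "exchange_rate",
                   "annual_operational_minutes")

read_ledger_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  header_cols <- setdiff(ITEM_COLUMNS, LEDGER_PARAMS)
  missing <- setdiff(header_cols, names(raw))
  if (length(missing) > 0) {
    stop("ledger CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- list()
  for (p in LEDGER_PARAMS) {
    if (p %in% names(raw) && nrow(raw) > 0) {
      v <- parse_money(raw[[p]][1])
      if (!is.na(v)) params[[p]] <- v
    }
  }
  items <- parse_items(raw)
  do.call(cost_ledger, c(list(items = items), params))
}

read_ledger_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- obj$items
  if (is.null(items) || (is.data.frame(items) && nrow(items) == 0) ||
      length(items) == 0) {
    items <- empty_items()
  } else {
    missing <- setdiff(setdiff(ITEM_COLUMNS,
                               c("useful_life_years",
                                 "staff_minutes_per_patient")),
                       names(items))
    if (length(missing) > 0) {
      stop("ledger JSON items are missing required field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    items <- parse_items(items)
  }
  args <- obj[intersect(names(obj), LEDGER_PARAMS)]
  do.call(cost_ledger, c(list(items = items), args))
}

# coerce a character/any data frame into typed, enum-normalized items
parse_items <- function(raw) {
  if (nrow(raw) == 0) return(empty_items())
  opt_num <- function(col) {
    if (col %in% names(raw)) parse_money(raw[[col]]) else
      rep(NA_real_, nrow(raw))
  }
  items <- data.frame(
    item_id = as.character(raw$item_id),
    label = as.character(raw$label),
    phase = tolower(trimws(as.character(raw$phase))),
    cost_class = tolower(trimws(as.character(raw$cost_class))),
    cost_behavior = tolower(trimws(as.character(raw$cost_behavior))),
    unit_price = parse_money(raw$unit_price),
    quantity = parse_money(raw$quantity),
    useful_life_years = opt_num("useful_life_years"),
    apportionment_fraction = parse_money(raw$apportionment_fraction),
    staff_minutes_per_patient = opt_num("staff_minutes_per_patient"),
    per_patient = parse_flag(raw$per_patient),
    stringsAsFactors = FALSE
  )
  items
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Write a cost ledger to CSV or JSON
#'
#' The ledger must validate without errors. Money and fraction columns are
#' serialized with two decimal places in CSV; the written file reads back
#' with [read_ledger()] to a field-for-field equal ledger. Ledger-level
#' parameters are carried in extra CSV columns (populated on the first row)
#' or as top-level JSON fields.
#'
#' @param ledger a validated [cost_ledger()].
#' @param path destination file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(ledger, "cost_ledger"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  rep <- validate_ledger(ledger)
  if (!rep$ok) {
    stop("refusing to write an invalid ledger: ",
         paste(rep$issues$message[rep$issues$severity == "error"],
               collapse = "; "), call. = FALSE)
  }
  if (format == "csv") write_ledger_csv(ledger, path) else
    write_ledger_json(ledger, path)
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

write_ledger_csv <- function(ledger, path) {
  it <- ledger$items
  out <- data.frame(
    item_id = it$item_id, label = it$label, phase = it$phase,
    cost_class = it$cost_class, cost_behavior = it$cost_behavior,
    unit_price = fmt2(it$unit_price),
    quantity = ifelse(is.na(it$quantity), "", format(it$quantity,
                                                     scientific = FALSE)),
    useful_life_years = ifelse(is.na(it$useful_life_years), "",
                               format(it$useful_life_years,
                                      scientific = FALSE)),
    apportionment_fraction = fmt2(it$apportionment_fraction),
    staff_minutes_per_patient = ifelse(is.na(it$staff_minutes_per_patient),
                                       "",
                                       format(it$staff_minutes_per_patient,
                                              scientific = FALSE)),
    per_patient = tolower(as.character(it$per_patient)),
    stringsAsFactors = FALSE
  )
  for (p in LEDGER_PARAMS) {
    col <- rep("", nrow(out))
    if (nrow(out) > 0) col[1] <- format(ledger[[p]], scientific = FALSE)
    out[[p]] <- col
  }
  if (nrow(out) == 0) {
    # keep param columns in the header so an empty ledger round-trips
    out[LEDGER_PARAMS] <- lapply(LEDGER_PARAMS, function(p) character(0))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

write_ledger_json <- function(ledger, path) {
  obj <- list(
    items = ledger$items,
    discount_rate = ledger$discount_rate,
    cohort_size = ledger$cohort_size,
    exchange_rate = ledger$exchange_rate,
    annual_operational_minutes = ledger$annual_operational_minutes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}
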