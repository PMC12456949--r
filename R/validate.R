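# Schema and referential-integrity checks for the pipeline tables.

.as_table <- function(x, label) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_arg(label, " file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
}

.viol <- function(table, row, column, message) {
  data.frame(table = table, row = row, column = column, message = message,
             stringsAsFactors = FALSE)
}

#' Validate pipeline tables
#'
#' Schema checks (required columns, value ranges: choice in {0,1}, framing
#' in -4..4, kappas in [0,1], gamma > 0, shock/money differences on their
#' grids) and cross-table referential integrity (every choice and framing
#' row's subject must exist in the trait table). Violations are reported
#' with table, row and column; an empty data frame means all checks passed.
#'
#' @param choices,traits,framing,fits Data frames or CSV paths; any subset
#'   may be supplied.
#' @return Data frame of violations (zero rows when clean).
#' @export
validate_tables <- function(choices = NULL, traits = NULL, framing = NULL,
                            fits = NULL) {
  choices <- .as_table(choices, "choices")
  traits <- .as_table(traits, "traits")
  framing <- .as_table(framing, "framing")
  fits <- .as_table(fits, "fits")
  v <- list()
  add <- function(x) if (nrow(x)) v[[length(v) + 1L]] <<- x
  range_check <- function(df, tab, col, ok_fun, msg) {
    if (!col %in% names(df)) {
      add(.viol(tab, NA, col, "missing column"))
      return()
    }
    bad <- which(!ok_fun(df[[col]]))
    if (length(bad)) add(.viol(tab, bad, col, msg))
  }
  if (!is.null(choices)) {
    range_check(choices, "choices", "choice", function(x) x %in% c(0, 1),
                "choice must be 0 or 1")
    range_check(choices, "choices", "delta_s",
                function(x) x >= 1 & x <= 19 & x == round(x),
                "delta_s must be an integer in 1..19")
    range_check(choices, "choices", "delta_m",
                function(x) x > 0 & x <= 19.8 & abs(x * 5 - round(x * 5)) < 1e-9,
                "delta_m must lie on the 0.2..19.8 grid")
    range_check(choices, "choices", "context",
                function(x) x %in% c("gain", "loss"), "unknown context")
    range_check(choices, "choices", "recipient",
                function(x) x %in% c("self", "other"), "unknown recipient")
    if (!"subject_id" %in% names(choices)) {
      add(.viol("choices", NA, "subject_id", "missing column"))
    }
  }
  if (!is.null(traits)) {
    range_check(traits, "traits", "IH", function(x) x >= 1 & x <= 7,
                "IH must lie in [1, 7]")
    range_check(traits, "traits", "IB", function(x) x >= 1 & x <= 7,
                "IB must lie in [1, 7]")
    range_check(traits, "traits", "EC", function(x) x >= 1 & x <= 5,
                "EC must lie in [1, 5]")
  }
  if (!is.null(framing)) {
    range_check(framing, "framing", "framing",
                function(x) x >= -4 & x <= 4 & x == round(x),
                "framing must be an integer in -4..4")
  }
  if (!is.null(fits)) {
    for (col in grep("^kappa_", names(fits), value = TRUE)) {
      range_check(fits, "fits", col, function(x) x >= 0 & x <= 1,
                  "kappa must lie in [0, 1]")
    }
    range_check(fits, "fits", "gamma", function(x) x > 0, "gamma must be > 0")
  }
  if (!is.null(traits) && "subject_id" %in% names(traits)) {
    known <- traits$subject_id
    for (nm in c("choices", "framing", "fits")) {
      df <- get(nm)
      if (!is.null(df) && "subject_id" %in% names(df)) {
        bad <- which(!df$subject_id %in% known)
        if (length(bad)) {
          add(.viol(nm, bad, "subject_id",
                    "subject_id not present in trait table"))
        }
      }
    }
  }
  if (length(v)) {
    do.call(rbind, v)
  } else {
    data.frame(table = character(0), row = integer(0), column = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}
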