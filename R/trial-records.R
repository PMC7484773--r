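#' Construct a set of trial records
#'
#' A trial is an accrual-ordered collection of participants in a two-arm
#' design with a binary outcome. Each record carries its accrual order, the
#' randomized arm, the outcome (defined only for responders) and whether the
#' participant provided follow-up data.
#'
#' @param accrual_index integer vector, 1-based accrual order; must be unique.
#' @param arm character or factor, `"control"` or `"intervention"`.
#' @param outcome binary outcome (0/1); `NA` for non-responders.
#' @param responded logical; `TRUE` when the participant provided follow-up
#'   data. Defaults to `TRUE` for all records.
#'
#' @return A `trial_records` data frame sorted by `accrual_index` with columns
#'   `accrual_index`, `arm`, `outcome`, `responded`.
#' @examples
#' trial_records(1:4, c("intervention", "control", "intervention", "control"),
#'               c(1, 0, 0, 1))
#' @export
trial_records <- function(accrual_index, arm, outcome,
                          responded = rep(TRUE, length(accrual_index))) {
  n <- length(accrual_index)
  stopifnot(length(arm) == n, length(outcome) == n, length(responded) == n)
  accrual_index <- as.integer(accrual_index)
  if (anyNA(accrual_index) || any(accrual_index < 1L)) {
    stop("accrual_index must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(accrual_index)) {
    dup <- accrual_index[duplicated(accrual_index)][1L]
    stop(sprintf("duplicate accrual_index: %d", dup), call. = FALSE)
  }
  arm <- as.character(arm)
  bad_arm <- which(!arm %in% c("control", "intervention"))
  if (length(bad_arm)) {
    stop(sprintf("unknown arm label %s in row %d (expected 'control' or 'intervention')",
                 dQuote(arm[bad_arm[1L]]), bad_arm[1L]), call. = FALSE)
  }
  responded <- as.logical(responded)
  if (anyNA(responded)) stop("responded must be TRUE/FALSE", call. = FALSE)
  outcome <- as.integer(outcome)
  if (any(responded & (is.na(outcome) | !outcome %in% c(0L, 1L)))) {
    bad <- which(responded & (is.na(outcome) | !outcome %in% c(0L, 1L)))[1L]
    stop(sprintf("outcome must be 0/1 for responders (row %d)", bad),
         call. = FALSE)
  }
  outcome[!responded] <- NA_integer_  # outcome undefined without follow-up
  out <- data.frame(accrual_index = accrual_index, arm = arm,
                    outcome = outcome, responded = responded,
                    stringsAsFactors = FALSE)
  out <- out[order(out$accrual_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_records", "data.frame")
  out
}

#' Read a trial from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `accrual_index,arm,outcome,responded`. `outcome` may be empty for rows with
#' `responded` false. Malformed rows are reported with their (1-based data)
#' row number.
#'
#' @param path path to the CSV file.
#' @return A [trial_records] object sorted by accrual order.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(accrual_index = "integer",
                                       arm = "character",
                                       outcome = "integer",
                                       responded = "logical")[0],
                        fileEncoding = "UTF-8")
  required <- c("accrual_index", "arm", "outcome", "responded")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(trial_records(integer(0), character(0), integer(0), logical(0)))
  }
  responded <- df$responded
  if (is.character(responded)) responded <- toupper(responded) %in% c("TRUE", "T", "1")
  responded <- as.logical(responded)
  outcome <- suppressWarnings(as.integer(df$outcome))
  trial_records(df$accrual_index, df$arm, outcome, responded)
}

#' Write a trial to CSV
#'
#' Inverse of [read_trial_csv()]: writes the four-column trial schema, with an
#' empty `outcome` field for non-responders.
#'
#' @param records a [trial_records] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Subset of records that provided follow-up data
#' @param records a [trial_records] object.
#' @return records with `responded == TRUE`, in accrual order.
#' @export
responders <- function(records) {
  records[records$responded, , drop = FALSE]
}
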