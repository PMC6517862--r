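#' Read patient-level case records from CSV
#'
#' Reads a delimited case listing (one row per patient; header required)
#' and validates it against the factor vocabularies. Rows with unknown or
#' missing levels, negative or missing follow-up, or a non-binary event
#' indicator are excluded, mirroring registry practice of dropping records
#' with unknown values; per-column exclusion counts are reported and
#' attached as an attribute.
#'
#' @param path CSV file with columns `id`, `t`, `n`, `m`, `age` (integer
#'   years) or `a` (`A1`/`A2`), optional `h`, `surv_months`, `event`.
#' @param side_file Optional path; excluded rows are written there with a
#'   `reason` column.
#' @param quiet Suppress the exclusion report message.
#' @return Tibble of validated cases with an `exclusions` attribute (named
#'   integer vector of per-column exclusion counts).
#' @export
read_cases <- function(path, side_file = NULL, quiet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) abort("Empty case file.")
  need <- c("surv_months", "event")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))
  v <- tnm_vocab()

  bad <- list()
  flag <- function(col, is_bad) {
    bad[[col]] <<- is_bad
  }
  for (col in intersect(c("t", "n", "m", "h"), names(raw))) {
    flag(col, is.na(raw[[col]]) | !(raw[[col]] %in% v[[col]]))
  }
  if ("a" %in% names(raw) && !"age" %in% names(raw)) {
    flag("a", is.na(raw$a) | !(raw$a %in% v$a))
  }
  if ("age" %in% names(raw)) {
    age <- suppressWarnings(as.numeric(raw$age))
    flag("age", is.na(age) | age < 0)
  }
  sm <- suppressWarnings(as.numeric(raw$surv_months))
  flag("surv_months", is.na(sm) | sm < 0)
  evn <- suppressWarnings(as.numeric(raw$event))
  flag("event", is.na(evn) | !(evn %in% c(0, 1)))

  excl <- vapply(bad, sum, integer(1))
  drop <- Reduce(`|`, bad, rep(FALSE, nrow(raw)))
  if (!quiet && any(drop)) {
    inform(paste0(
      "Excluded ", sum(drop), " of ", nrow(raw), " rows (per column: ",
      paste(names(excl)[excl > 0], excl[excl > 0], sep = "=", collapse = ", "),
      ")"
    ))
  }
  if (!is.null(side_file) && any(drop)) {
    reasons <- vapply(which(drop), function(i) {
      paste(names(bad)[vapply(bad, `[`, logical(1), i)], collapse = ";")
    }, character(1))
    readr::write_csv(dplyr::mutate(raw[drop, ], reason = reasons), side_file)
  }

  out <- raw[!drop, , drop = FALSE]
  if (nrow(out) == 0) abort("No valid rows after exclusions.")
  out$surv_months <- as.numeric(out$surv_months)
  out$event <- as.integer(as.numeric(out$event))
  if ("age" %in% names(out)) out$age <- as.numeric(out$age)
  attr(out, "exclusions") <- excl
  out
}

#' Write case records to CSV
#'
#' @param cases Case tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cases <- function(cases, path) {
  readr::write_csv(cases, path)
  invisible(path)
}
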