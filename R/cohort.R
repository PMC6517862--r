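#' Factor-level vocabularies for well-differentiated thyroid cancer
#'
#' The controlled vocabularies for the prognostic factors used throughout the
#' package: primary tumor (T), regional lymph nodes (N), distant metastasis
#' (M), dichotomized age (A) and histology (H; H1 = follicular,
#' H2 = papillary). Levels are listed in their clinical order.
#'
#' @return A named list of character vectors, one per factor (`t`, `n`, `m`,
#'   `a`, `h`).
#' @export
#' @examples
#' tnm_vocab()$t
tnm_vocab <- function() {
  list(
    t = c("T0", "T1", "T2", "T3", "T4a", "T4b"),
    n = c("N0", "N1a", "N1b"),
    m = c("M0", "M1"),
    a = c("A1", "A2"),
    h = c("H1", "H2")
  )
}

# canonical factor order used for combination labels
.factor_order <- c("T", "N", "M", "A", "H")

#' Dichotomize age at a cutoff
#'
#' Maps age in years to the two-level age factor: `A1` for ages strictly
#' below the cutoff, `A2` otherwise. The default cutoff of 55 years is the
#' one used by the AJCC 8th edition for differentiated thyroid cancer.
#'
#' @param age_years Integer vector of ages in years (non-negative).
#' @param cutoff Age cutoff in years (default 55).
#' @return Character vector of `"A1"`/`"A2"`.
#' @export
#' @examples
#' assign_age_level(c(54, 55), 55)
assign_age_level <- function(age_years, cutoff = 55) {
  if (length(age_years) == 0) abort("`age_years` is empty.")
  if (anyNA(age_years)) abort("`age_years` contains missing values.")
  if (!is.numeric(age_years) || any(age_years < 0)) {
    abort("`age_years` must be non-negative numbers.")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("`cutoff` must be a single positive number.")
  }
  ifelse(age_years < cutoff, "A1", "A2")
}

# Normalize a user-supplied factor set to canonical T,N,M,A,H order.
normalize_factors <- function(factors) {
  f <- toupper(as.character(factors))
  if (length(f) == 0) abort("The factor set is empty.")
  if (anyDuplicated(f)) abort("The factor set contains duplicates.")
  bad <- setdiff(f, .factor_order)
  if (length(bad)) {
    abort(paste0("Unknown factors: ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(.factor_order, collapse = ", "), "."))
  }
  .factor_order[.factor_order %in% f]
}

# Validate survival columns; returns cases invisibly or aborts.
check_survival_columns <- function(cases) {
  for (col in c("surv_months", "event")) {
    if (!col %in% names(cases)) abort(paste0("Column `", col, "` is required."))
  }
  if (anyNA(cases$surv_months) || any(cases$surv_months < 0)) {
    abort("`surv_months` must be non-negative and non-missing.")
  }
  if (!all(cases$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (disease-specific death).")
  }
  invisible(cases)
}

# Resolve the A column: raw age wins over a pre-coded level, with a warning
# when both are present so cutoff experiments can run off one file.
resolve_age <- function(cases, age_cutoff) {
  has_age <- "age" %in% names(cases)
  has_a <- "a" %in% names(cases)
  if (has_age && has_a) {
    warn("Both `age` and `a` present; using raw `age` with the cutoff.")
  }
  if (has_age) {
    cases$a <- assign_age_level(cases$age, age_cutoff)
  } else if (!has_a) {
    abort("Factor A requested but neither `age` nor `a` is present.")
  }
  cases
}

#' Build factor combinations from patient-level records
#'
#' Partitions a cohort into combinations: the cells defined by one level of
#' each selected prognostic factor (e.g. `T1N0M0A1`). Combinations are the
#' clustering unit for the whole pipeline. Labels always concatenate levels
#' in the fixed order T, N, M, A, H regardless of the order in which the
#' factors are requested, and empty cells are not emitted.
#'
#' @param cases A data frame with one row per patient. Required columns:
#'   `id`, `surv_months`, `event`, plus a lower-case column per requested
#'   factor (`t`, `n`, `m`, `h`); for factor A either raw `age` in years or a
#'   pre-coded `a` column (`A1`/`A2`). If both are present the raw age wins.
#' @param factors Character vector naming the factors, a subset of
#'   `c("T","N","M","A","H")`. Order is ignored.
#' @param age_cutoff Age cutoff in years used when dichotomizing raw age
#'   (default 55).
#' @return A tibble with one row per non-empty combination: `label`, one
#'   column per factor level, `size`, and a `data` list-column holding the
#'   member records (`id`, `surv_months`, `event`). Rows are ordered by
#'   factor levels in vocabulary order.
#' @export
#' @examples
#' cases <- tibble::tibble(
#'   id = as.character(1:3), t = c("T1", "T1", "T2"), n = "N0",
#'   surv_months = c(10, 20, 30), event = c(1, 0, 1)
#' )
#' build_combinations(cases, factors = c("T", "N"))
build_combinations <- function(cases, factors = c("T", "N", "M", "A"),
                               age_cutoff = 55) {
  cases <- tibble::as_tibble(cases)
  factors <- normalize_factors(factors)
  if (!"id" %in% names(cases)) {
    cases$id <- as.character(seq_len(nrow(cases)))
  }
  check_survival_columns(cases)
  if ("A" %in% factors) cases <- resolve_age(cases, age_cutoff)

  vocab <- tnm_vocab()
  cols <- tolower(factors)
  for (col in cols) {
    if (!col %in% names(cases)) {
      abort(paste0("Factor ", toupper(col), " requested but column `", col,
                   "` is missing."))
    }
    bad <- is.na(cases[[col]]) | !(cases[[col]] %in% vocab[[col]])
    if (any(bad)) {
      abort(paste0(
        "Invalid ", toupper(col), " level for case id(s): ",
        paste(head(cases$id[bad], 5), collapse = ", "),
        if (sum(bad) > 5) paste0(" (and ", sum(bad) - 5, " more)") else ""
      ))
    }
  }

  out <- cases |>
    dplyr::mutate(label = make_labels(cases, cols)) |>
    dplyr::select(dplyr::all_of(c("label", cols, "id", "surv_months",
                                  "event"))) |>
    tidyr::nest(data = dplyr::all_of(c("id", "surv_months", "event"))) |>
    dplyr::mutate(size = vapply(.data$data, nrow, integer(1)))
  # deterministic ordering by vocabulary level order
  keys <- lapply(cols, function(col) match(out[[col]], vocab[[col]]))
  out <- out[do.call(order, keys), c("label", cols, "size", "data")]
  tibble::as_tibble(out)
}

make_labels <- function(cases, cols) {
  do.call(paste0, lapply(cols, function(col) cases[[col]]))
}

#' Drop combinations below a minimum size
#'
#' Small cells give unstable survival estimates; the pipeline keeps only
#' combinations with at least `min_count` patients (25 by default, matching
#' common registry practice for robust cell-level estimation).
#'
#' @param combinations Tibble from [build_combinations()].
#' @param min_count Minimum number of member patients (default 25).
#' @return A list with tibbles `kept` and `discarded`, original order
#'   preserved in each.
#' @export
filter_min_count <- function(combinations, min_count = 25) {
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 1) {
    abort("`min_count` must be a single integer >= 1.")
  }
  keep <- combinations$size >= min_count
  list(
    kept = combinations[keep, , drop = FALSE],
    discarded = combinations[!keep, , drop = FALSE]
  )
}
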