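#' AJCC 8th-edition stage for well-differentiated thyroid cancer
#'
#' The staging rule of the AJCC 8th edition for papillary and follicular
#' thyroid carcinoma, with age dichotomized at 55 years. Patients under 55
#' (A1) are stage I unless distant metastasis is present (stage II).
#' Patients 55 and over (A2) with distant metastasis are stage IVB;
#' otherwise T1/T2 with N0 is stage I, nodal disease or T3 is stage II,
#' T4a is stage III and T4b is stage IVA.
#'
#' @param t_level,n_level,m_level,a_level Factor levels per [tnm_vocab()];
#'   vectors are recycled to a common length. `T0` is not staged and is
#'   rejected.
#' @return An ordered factor with levels `I < II < III < IVA < IVB`.
#' @export
#' @examples
#' ajcc8_stage("T1", "N1a", "M0", "A2")  # II
ajcc8_stage <- function(t_level, n_level, m_level, a_level) {
  nmax <- max(length(t_level), length(n_level), length(m_level),
              length(a_level))
  t_level <- rep_len(as.character(t_level), nmax)
  n_level <- rep_len(as.character(n_level), nmax)
  m_level <- rep_len(as.character(m_level), nmax)
  a_level <- rep_len(as.character(a_level), nmax)

  v <- tnm_vocab()
  if (any(t_level == "T0")) {
    abort("T0 is not staged by this rule (no evidence of primary tumor).")
  }
  bad <- !(t_level %in% setdiff(v$t, "T0")) | !(n_level %in% v$n) |
    !(m_level %in% v$m) | !(a_level %in% v$a)
  if (any(bad)) {
    abort(paste0("Unknown level(s) at position(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }

  stage <- character(nmax)
  young <- a_level == "A1"
  m1 <- m_level == "M1"
  stage[young & !m1] <- "I"
  stage[young & m1] <- "II"
  old <- !young
  stage[old & m1] <- "IVB"
  idx <- old & !m1
  stage[idx & t_level %in% c("T1", "T2") & n_level == "N0"] <- "I"
  stage[idx & t_level %in% c("T1", "T2") & n_level != "N0"] <- "II"
  stage[idx & t_level == "T3"] <- "II"
  stage[idx & t_level == "T4a"] <- "III"
  stage[idx & t_level == "T4b"] <- "IVA"
  factor(stage, levels = c("I", "II", "III", "IVA", "IVB"), ordered = TRUE)
}

#' Stamp AJCC 8th-edition stages onto a case table
#'
#' @param cases Case tibble with `t`, `n`, `m` and either `age` or `a`.
#' @param age_cutoff Cutoff used when dichotomizing raw age (the rule is
#'   defined for 55; other values are allowed for sensitivity analyses).
#' @return `cases` with an added ordered-factor column `ajcc_stage`.
#' @export
stage_cases <- function(cases, age_cutoff = 55) {
  cases <- resolve_age(tibble::as_tibble(cases), age_cutoff)
  cases$ajcc_stage <- ajcc8_stage(cases$t, cases$n, cases$m, cases$a)
  cases
}

#' Contingency table between two combination-level groupings
#'
#' Cross-tabulates patients by a stage assignment (rows) and a prognostic
#' group assignment (columns), where both are defined per combination and
#' each combination contributes its full patient count to one cell.
#'
#' @param assignments Data frame with one row per combination: columns
#'   `label`, `group` (integer), `stage` (factor or character) and `size`
#'   (patient count).
#' @return A `contingency_table`: list with the counts `matrix`
#'   (stages x groups), `row_totals`, `col_totals` and `total`.
#' @export
contingency <- function(assignments) {
  req <- c("label", "group", "stage", "size")
  if (!all(req %in% names(assignments))) {
    abort(paste0("`assignments` needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(assignments$label)) abort("Duplicate combination labels.")
  stages <- if (is.factor(assignments$stage)) {
    levels(assignments$stage)
  } else {
    sort(unique(as.character(assignments$stage)))
  }
  groups <- sort(unique(assignments$group))
  m <- matrix(0, length(stages), length(groups),
              dimnames = list(stages, as.character(groups)))
  si <- match(as.character(assignments$stage), stages)
  gi <- match(assignments$group, groups)
  for (i in seq_len(nrow(assignments))) {
    m[si[i], gi[i]] <- m[si[i], gi[i]] + assignments$size[i]
  }
  structure(
    list(matrix = m, row_totals = rowSums(m), col_totals = colSums(m),
         total = sum(m)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- cbind(x$matrix, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$total))
  print(m)
  invisible(x)
}

#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::as_tibble(as.table(x$matrix), .name_repair = "minimal") |>
    setNames(c("stage", "group", "count"))
}

#' Association between a grouping and a staging
#'
#' Spearman rank correlation between the prognostic group number and the
#' ordinal stage, computed over combinations (unweighted — one observation
#' per combination, not per patient).
#'
#' @param assignments Data frame with columns `group` and `stage` (ordered
#'   factor or character coercible to the stage order I < II < III < IVA
#'   < IVB), one row per combination.
#' @return A `cor_result` from [spearman_ties()].
#' @export
association <- function(assignments) {
  if (nrow(assignments) < 3) abort("Need at least 3 combinations.")
  st <- assignments$stage
  if (!is.factor(st)) {
    st <- factor(st, levels = c("I", "II", "III", "IVA", "IVB"),
                 ordered = TRUE)
  }
  if (anyNA(st)) abort("Unknown stage labels.")
  spearman_ties(assignments$group, as.integer(st))
}

#' Published stratification tables for well-differentiated thyroid cancer
#'
#' Accessors for the tables bundled with the package, transcribed from the
#' published SEER analysis of papillary and follicular thyroid cancer
#' (diagnoses 2004-2010): the 39 (T, N, M, A) combinations with their
#' prognostic group and AJCC 8th-edition stage, and the patient
#' cross-tabulations of group against stage, per histology and pooled.
#'
#' @return `thyroid_table2()`: tibble with `t`, `n`, `m`, `a`,
#'   `eaccd_group`, `ajcc_stage` (39 rows). `thyroid_contingency()`:
#'   tibble with `histology`, `stage` and one count column per group.
#' @export
thyroid_table2 <- function() {
  readr::read_csv(
    system.file("extdata", "thyroid_table2.csv", package = "eaccd"),
    show_col_types = FALSE
  )
}

#' @rdname thyroid_table2
#' @param histology One of `"follicular"`, `"papillary"`, `"pooled"`.
#' @export
thyroid_contingency <- function(histology = c("pooled", "follicular",
                                              "papillary")) {
  histology <- match.arg(histology)
  file <- if (histology == "pooled") "thyroid_table4.csv" else "thyroid_table3.csv"
  tab <- readr::read_csv(system.file("extdata", file, package = "eaccd"),
                         show_col_types = FALSE)
  if (histology != "pooled") {
    tab <- tab[tab$histology == histology, , drop = FALSE]
  }
  tab
}
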