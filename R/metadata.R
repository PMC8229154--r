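#' Levodopa-equivalent dose conversion schedule
#'
#' The conversion coefficients (mg levodopa per mg of drug, or per unit dose
#' for the dopamine agonists) used to collapse a subject's antiparkinsonian
#' medication into a single levodopa-equivalent dose (LED):
#' levodopa/carbidopa x 1, entacapone x 0.35, pramipexole x 100,
#' ropinirole x 20, rotigotine x 10, selegiline x 10, amantadine x 1.
#'
#' @return Named numeric vector of strictly positive coefficients. Names are
#'   lower-case drug names; the levodopa/carbidopa combination is a single
#'   entry, `"levodopa/carbidopa"`.
#' @export
led_schedule <- function() {
  c("levodopa/carbidopa" = 1,
    "entacapone"         = 0.35,
    "pramipexole"        = 100,
    "ropinirole"         = 20,
    "rotigotine"         = 10,
    "selegiline"         = 10,
    "amantadine"         = 1)
}

#' Compute the levodopa-equivalent dose
#'
#' Weighted sum of daily drug doses using a conversion schedule. Drug names
#' are matched case-insensitively (surrounding whitespace ignored); a dose
#' for a drug absent from the schedule is an error, as is a negative dose.
#'
#' @param doses Named numeric vector or list, mg/day per drug. May be empty.
#' @param schedule Named numeric vector of positive conversion coefficients,
#'   by default [led_schedule()].
#' @return LED in mg/day (scalar). An empty or all-zero dose set gives 0.
#' @examples
#' compute_led(c("levodopa/carbidopa" = 300))
#' compute_led(c("levodopa/carbidopa" = 200, entacapone = 200, pramipexole = 1.5))
#' @export
compute_led <- function(doses, schedule = led_schedule()) {
  if (!is.numeric(schedule) || is.null(names(schedule)) || any(schedule <= 0)) {
    stopf("`schedule` must be a named numeric vector of positive coefficients")
  }
  names(schedule) <- tolower(trimws(names(schedule)))
  doses <- unlist(doses)
  if (length(doses) == 0L) return(0)
  if (is.null(names(doses)) || any(!nzchar(names(doses)))) {
    stopf("every dose must be named by its drug")
  }
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stopf("doses must be finite and >= 0")
  }
  keys <- tolower(trimws(names(doses)))
  unknown <- setdiff(keys, names(schedule))
  if (length(unknown) > 0L) {
    stopf("unknown drug(s) in dose list: %s", paste(unknown, collapse = ", "))
  }
  sum(doses * schedule[keys])
}

#' Screen subjects for head motion
#'
#' Partitions subject records by maximum motion displacement: a subject is
#' excluded if displacement is `threshold_mm` *or more* (the threshold itself
#' is excluded). The displacement is consumed from the table; realignment is
#' upstream of this pipeline.
#'
#' @param records Data frame with a `max_displacement_mm` column (one row per
#'   subject); no missing values allowed.
#' @param threshold_mm Exclusion threshold in mm, default 3.
#' @return List with elements `retained` and `excluded` (two disjoint data
#'   frames whose rows partition `records`).
#' @export
screen_motion <- function(records, threshold_mm = 3.0) {
  if (!is.data.frame(records) || is.null(records$max_displacement_mm)) {
    stopf("`records` must be a data frame with a `max_displacement_mm` column")
  }
  d <- records$max_displacement_mm
  if (any(!is.finite(d))) {
    stopf("missing or non-finite `max_displacement_mm` for record(s): %s",
          paste(which(!is.finite(d)), collapse = ", "))
  }
  out <- d >= threshold_mm
  list(retained = records[!out, , drop = FALSE],
       excluded = records[out, , drop = FALSE])
}

#' The seven MoCA cognitive domains and their integer score ranges
#'
#' Domain subscores of the Montreal Cognitive Assessment as administered in
#' the standard instrument: visuospatial/executive 0-5, naming 0-3,
#' attention 0-6, language 0-3, abstraction 0-2, delayed recall 0-5,
#' orientation 0-6.
#'
#' @return Data frame with columns `domain` and `max_score` (minimum is 0).
#' @export
moca_domains <- function() {
  data.frame(
    domain = c("visuospatial_executive", "naming", "attention", "language",
               "abstraction", "delayed_recall", "orientation"),
    max_score = c(5L, 3L, 6L, 3L, 2L, 5L, 6L),
    stringsAsFactors = FALSE
  )
}

moca_columns <- function() paste0("moca_", moca_domains()$domain)

#' Read a subject metadata table
#'
#' Tab-separated table with one row per subject. Required columns: `id`,
#' `group` (Ctr or PD), `age`, `sex` (M/F), `handedness` (R/L), `mmse`,
#' `max_displacement_mm`. PD-only columns (`disease_duration`, `hoehn_yahr`,
#' the seven `moca_*` domain scores, `led`) may be NA for controls. Drug
#' doses, when present, are columns named `dose_<drug>`.
#'
#' @param path Path to the TSV file.
#' @param screened If `TRUE`, enforce the control definition MMSE >= 24 on
#'   Ctr rows.
#' @return Validated data frame.
#' @export
read_subject_table <- function(path, screened = TRUE) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("id", "group", "age", "sex", "handedness", "mmse",
                "max_displacement_mm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stopf("subject table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$group %in% c("Ctr", "PD"))) {
    stopf("`group` must be 'Ctr' or 'PD'")
  }
  if (!all(tab$sex %in% c("M", "F"))) stopf("`sex` must be 'M' or 'F'")
  if (!all(tab$handedness %in% c("R", "L"))) {
    stopf("`handedness` must be 'R' or 'L'")
  }
  if (screened) {
    ctr <- tab$group == "Ctr"
    if (any(ctr & (is.na(tab$mmse) | tab$mmse < 24))) {
      stopf("screened controls must have MMSE >= 24")
    }
  }
  dose_cols <- grep("^dose_", names(tab), value = TRUE)
  if (length(dose_cols) > 0L) {
    known <- gsub("/", "_", names(led_schedule()))
    unknown <- setdiff(sub("^dose_", "", dose_cols), known)
    if (length(unknown) > 0L) {
      stopf("unknown drug dose column(s): %s", paste(unknown, collapse = ", "))
    }
    doses <- as.matrix(tab[, dose_cols, drop = FALSE])
    if (any(doses[is.finite(doses)] < 0)) stopf("drug doses must be >= 0")
  }
  tab
}

#' @rdname read_subject_table
#' @param table Data frame to write.
#' @export
write_subject_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
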