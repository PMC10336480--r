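# Standard MDM case file: TNM staging, tumor sublocation, histology,
# per-modality feasibility, relapse flag and free-text poor-prognosis factors.

.TNM_T <- c("T1", "T2", "T3", "T4", "T4a", "T4b")
.TNM_N <- c("N0", "N1", "N2", "N2a", "N2b", "N2c", "N3")
.TNM_M <- c("M0", "M1")

.SITES <- c(
  "larynx_glottic", "larynx_supraglottic", "nasopharynx", "oral_tongue",
  "floor_of_mouth", "oropharynx", "tongue_base", "hypopharynx"
)

.HISTOLOGIES <- c("epidermoid_carcinoma", "ucnt", "other")

.MODALITIES <- c("surgery", "radiation", "chemotherapy")

.STAGE_CLASSES <- c("early", "locally_advanced", "metastatic")

#' Closed vocabularies of the case model
#'
#' The case file is built from closed enumerations: tumor sublocations of the
#' upper aerodigestive tract, histology labels, treatment modalities and the
#' TNM category sets. Unknown members are rejected at validation time.
#'
#' @return A character vector of the valid members, in canonical order.
#' @examples
#' tumor_sublocations()
#' mdm_modalities()
#' @export
tumor_sublocations <- function() .SITES

#' @rdname tumor_sublocations
#' @export
histology_labels <- function() .HISTOLOGIES

#' @rdname tumor_sublocations
#' @export
mdm_modalities <- function() .MODALITIES

#' @rdname tumor_sublocations
#' @export
stage_classes <- function() .STAGE_CLASSES

#' TNM stage triple
#'
#' Constructs a validated TNM stage from its three categories. T admits the
#' `T4a`/`T4b` subdivisions and N the `N2a`/`N2b`/`N2c` subdivisions used in
#' head-and-neck staging; M is binary.
#'
#' @param t,n,m Single category strings, e.g. `"T2"`, `"N2c"`, `"M0"`
#'   (case-insensitive).
#' @return An object of class `tnm_stage` with fields `t`, `n`, `m`.
#' @seealso [parse_tnm()], [classify_stage()]
#' @examples
#' tnm_stage("T3", "N1", "M0")
#' @export
tnm_stage <- function(t, n, m) {
  t <- .match_category(t, .TNM_T, "T")
  n <- .match_category(n, .TNM_N, "N")
  m <- .match_category(m, .TNM_M, "M")
  structure(list(t = t, n = n, m = m), class = "tnm_stage")
}

.match_category <- function(x, levels, axis) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("invalid %s category: expected a single non-empty string", axis),
         call. = FALSE)
  }
  hit <- match(tolower(x), tolower(levels))
  if (is.na(hit)) {
    stop(sprintf("unknown %s category: '%s'", axis, x), call. = FALSE)
  }
  levels[hit]
}

#' Parse a compact TNM stage string
#'
#' Accepts strings of the form `"T3N2cM0"`: the three categories concatenated,
#' case-insensitively, with surrounding whitespace ignored. Malformed input or
#' a category outside the closed enumeration raises an error naming the
#' offending token.
#'
#' @param text A single stage string.
#' @return A [tnm_stage()] object. `format()` on the result reproduces the
#'   canonical string, so `format(parse_tnm(x))` round-trips.
#' @examples
#' parse_tnm("T4N2cM1")
#' parse_tnm(" t1n0m0 ")
#' @export
parse_tnm <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("stage text must be a single string", call. = FALSE)
  }
  s <- trimws(text)
  if (!nzchar(s)) stop("stage text is empty", call. = FALSE)
  m <- regexec("^[Tt]([0-9]+[abAB]?)[Nn]([0-9]+[abcABC]?)[Mm]([0-9]+)$", s)
  parts <- regmatches(s, m)[[1]]
  if (length(parts) != 4L) {
    stop(sprintf("malformed TNM stage string: '%s' (expected e.g. 'T3N2cM0')", text),
         call. = FALSE)
  }
  tnm_stage(paste0("T", parts[2]), paste0("N", parts[3]), paste0("M", parts[4]))
}

#' @export
format.tnm_stage <- function(x, ...) paste0(x$t, x$n, x$m)

#' @export
print.tnm_stage <- function(x, ...) {
  cat("<TNM stage>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.tnm_stage <- function(x, ...) format(x)

is_tnm_stage <- function(x) inherits(x, "tnm_stage")

#' Classify a TNM stage into the engine's stage classes
#'
#' The rule table is keyed by a coarse stage class rather than AJCC stage
#' group numerals: `metastatic` iff M1; otherwise `early` iff T1/T2 with N0;
#' otherwise `locally_advanced`. N2 subdivisions (a/b/c) classify identically
#' to N2. Total and deterministic over all 84 valid TNM triples.
#'
#' @param tnm A [tnm_stage()] object or compact stage string.
#' @return One of `"early"`, `"locally_advanced"`, `"metastatic"`.
#' @examples
#' classify_stage("T1N0M0")
#' classify_stage(parse_tnm("T3N1M0"))
#' @export
classify_stage <- function(tnm) {
  if (is.character(tnm)) tnm <- parse_tnm(tnm)
  if (!is_tnm_stage(tnm)) stop("not a TNM stage", call. = FALSE)
  if (tnm$m == "M1") return("metastatic")
  if (tnm$t %in% c("T1", "T2") && tnm$n == "N0") return("early")
  "locally_advanced"
}

#' Construct a standard MDM patient case file
#'
#' Assembles the structured case record a resident submits for MDM review:
#' tumor sublocation, TNM stage, histology, per-modality feasibility flags,
#' relapse status and any poor-prognosis factors (free-text tags, recorded
#' and carried into reports but consuming no decision rule). A case without a
#' `submitted_at` timestamp is a draft and remains editable; submission (see
#' [submit_case()]) freezes it.
#'
#' The constructor stores fields as given so that incomplete or inconsistent
#' records can be represented and then diagnosed with [validate_case()];
#' only `tnm` is eagerly parsed when passed as a well-formed string.
#'
#' @param case_id Opaque case identifier, unique within a roster.
#' @param site Tumor sublocation, one of [tumor_sublocations()].
#' @param tnm Compact stage string (e.g. `"T2N0M0"`) or a [tnm_stage()].
#' @param histology One of [histology_labels()].
#' @param surgery_feasible,radiation_feasible,chemotherapy_feasible Logical
#'   flags; all three must be present (no tri-state).
#' @param relapse Logical: tumor recurrence after prior treatment.
#' @param poor_prognosis_factors Character vector of free-text tags (may be
#'   empty).
#' @param submitted_by Identifier of the submitting resident.
#' @param submitted_at `NULL` for a draft, else a timestamp (POSIXct or
#'   ISO-8601 string).
#' @return An object of class `patient_case`.
#' @examples
#' patient_case("case-1", "larynx_glottic", "T1N0M0", "epidermoid_carcinoma",
#'              submitted_by = "resident_a")
#' @export
patient_case <- function(case_id, site, tnm, histology,
                         surgery_feasible = TRUE,
                         radiation_feasible = TRUE,
                         chemotherapy_feasible = TRUE,
                         relapse = FALSE,
                         poor_prognosis_factors = character(),
                         submitted_by = "unknown",
                         submitted_at = NULL) {
  if (is.character(tnm) && length(tnm) == 1L && !is.na(tnm)) {
    parsed <- tryCatch(parse_tnm(tnm), error = function(e) tnm)
    tnm <- parsed
  }
  if (!is.null(submitted_at)) submitted_at <- as_timestamp(submitted_at)
  structure(list(
    case_id = case_id,
    site = site,
    tnm = tnm,
    histology = histology,
    surgery_feasible = surgery_feasible,
    radiation_feasible = radiation_feasible,
    chemotherapy_feasible = chemotherapy_feasible,
    relapse = relapse,
    poor_prognosis_factors = poor_prognosis_factors,
    submitted_by = submitted_by,
    submitted_at = submitted_at
  ), class = "patient_case")
}

is_patient_case <- function(x) inherits(x, "patient_case")

#' @export
print.patient_case <- function(x, ...) {
  tnm <- if (is_tnm_stage(x$tnm)) format(x$tnm) else as.character(x$tnm)
  cat(sprintf("<MDM case %s> %s %s, %s\n", x$case_id, x$site, tnm, x$histology))
  feas <- c(surgery = isTRUE(x$surgery_feasible),
            radiation = isTRUE(x$radiation_feasible),
            chemotherapy = isTRUE(x$chemotherapy_feasible))
  cat("  feasible:", if (any(feas)) paste(names(feas)[feas], collapse = ", ") else "none",
      "| relapse:", isTRUE(x$relapse), "\n")
  if (length(x$poor_prognosis_factors)) {
    cat("  poor prognosis:", paste(x$poor_prognosis_factors, collapse = "; "), "\n")
  }
  cat("  status:", if (is.null(x$submitted_at)) "draft"
      else paste0("submitted ", format(x$submitted_at, "%Y-%m-%d")), "\n")
  invisible(x)
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' Validate a patient case against the case-file schema
#'
#' Checks every field of a [patient_case()] against its type invariants and
#' returns the violations instead of raising: an empty character vector means
#' the case is well-formed. Each violation names the offending field and the
#' reason.
#'
#' @param case A [patient_case()] (or anything; non-cases yield a violation).
#' @return Character vector of `"field: reason"` strings; empty if valid.
#' @examples
#' ok <- patient_case("c1", "oropharynx", "T2N0M0", "epidermoid_carcinoma")
#' validate_case(ok)
#' bad <- patient_case("c2", "sinus", "T2N0M0", "epidermoid_carcinoma")
#' validate_case(bad)
#' @export
validate_case <- function(case) {
  if (!is_patient_case(case)) {
    return("case: not a patient_case object")
  }
  v <- character()
  add <- function(field, reason) v[[length(v) + 1L]] <<- paste0(field, ": ", reason)

  if (!is.character(case$case_id) || length(case$case_id) != 1L ||
      is.na(case$case_id) || !nzchar(case$case_id)) {
    add("case_id", "must be a non-empty string")
  }
  if (!is.character(case$site) || length(case$site) != 1L ||
      is.na(case$site) || !(case$site %in% .SITES)) {
    add("site", sprintf("unknown sublocation '%s' (expected one of: %s)",
                        paste(as.character(case$site), collapse = ","),
                        paste(.SITES, collapse = ", ")))
  }
  if (!is_tnm_stage(case$tnm)) {
    add("tnm", sprintf("not a valid TNM stage: '%s'",
                       paste(as.character(case$tnm), collapse = "")))
  }
  if (!is.character(case$histology) || length(case$histology) != 1L ||
      is.na(case$histology) || !(case$histology %in% .HISTOLOGIES)) {
    add("histology", sprintf("unknown histology '%s' (expected one of: %s)",
                             paste(as.character(case$histology), collapse = ","),
                             paste(.HISTOLOGIES, collapse = ", ")))
  }
  for (f in c("surgery_feasible", "radiation_feasible", "chemotherapy_feasible")) {
    if (!.is_flag(case[[f]])) add(f, "feasibility flag must be TRUE or FALSE")
  }
  if (!.is_flag(case$relapse)) add("relapse", "must be TRUE or FALSE")
  if (!is.character(case$poor_prognosis_factors) ||
      anyNA(case$poor_prognosis_factors)) {
    add("poor_prognosis_factors", "must be a character vector without NA")
  }
  if (!is.character(case$submitted_by) || length(case$submitted_by) != 1L ||
      is.na(case$submitted_by) || !nzchar(case$submitted_by)) {
    add("submitted_by", "must be a non-empty string")
  }
  v
}

#' Per-modality feasibility of a case as a named logical vector
#'
#' @param case A [patient_case()].
#' @return Named logical vector over `surgery`, `radiation`, `chemotherapy`.
#' @export
case_feasibility <- function(case) {
  stopifnot(is_patient_case(case))
  c(surgery = isTRUE(case$surgery_feasible),
    radiation = isTRUE(case$radiation_feasible),
    chemotherapy = isTRUE(case$chemotherapy_feasible))
}

# Timestamps are always injected (never read from the clock) so workflow
# behavior is replayable; stored as UTC POSIXct.
as_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = "UTC"))
  if (is.character(x) && length(x) == 1L && !is.na(x)) {
    out <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                       tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                      "%Y-%m-%d %H:%M:%S",
                                                      "%Y-%m-%d")))
    if (!is.na(out)) return(out)
  }
  stop(sprintf("invalid timestamp: '%s'", paste(as.character(x), collapse = " ")),
       call. = FALSE)
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
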