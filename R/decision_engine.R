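# Rule engine: (sublocation, stage class) -> candidate regimens, feasibility
# filtering, and escalation of complex cases to a face-to-face MDM.

#' Treatment regimen
#'
#' A regimen is an ordered, duplicate-free set of treatment modalities. Order
#' encodes treatment sequence where that matters clinically:
#' `regimen("surgery", "radiation")` is surgery with adjuvant radiation.
#' Combinations without surgery (concurrent chemoradiation) are compared as
#' unordered sets, so `regimen("chemotherapy", "radiation")` equals
#' `regimen("radiation", "chemotherapy")`; see [regimen_key()].
#'
#' @param ... Modality names, each one of [mdm_modalities()].
#' @return A character vector of modalities with class `mdm_regimen`.
#' @examples
#' regimen("surgery", "radiation")
#' regimen("radiation")
#' @export
regimen <- function(...) {
  comps <- as.character(c(...))
  if (length(comps) == 0L) stop("a regimen must contain at least one modality",
                                call. = FALSE)
  bad <- setdiff(comps, .MODALITIES)
  if (length(bad)) {
    stop(sprintf("unknown modality: %s", paste(sQuote(bad), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(comps)) stop("a regimen cannot repeat a modality", call. = FALSE)
  structure(comps, class = "mdm_regimen")
}

#' Canonical equality key of a regimen
#'
#' Regimens containing surgery keep their stated sequence (surgery followed by
#' adjuvant radiation is not radiation followed by salvage surgery); regimens
#' without surgery are unordered combinations and are keyed in fixed modality
#' order, so concurrent chemoradiation has a single key regardless of how its
#' components were listed.
#'
#' @param r A [regimen()] or plain character vector of modalities.
#' @return A single string; two regimens are the same treatment iff their
#'   keys are equal.
#' @examples
#' regimen_key(regimen("chemotherapy", "radiation"))  # same as radiation+chemotherapy
#' regimen_key(regimen("surgery", "radiation"))
#' @export
regimen_key <- function(r) {
  comps <- as.character(r)
  if (!("surgery" %in% comps)) comps <- intersect(.MODALITIES, comps)
  paste(comps, collapse = "+")
}

#' @export
format.mdm_regimen <- function(x, ...) {
  comps <- as.character(x)
  s <- paste(comps, collapse = " + ")
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' @export
print.mdm_regimen <- function(x, ...) {
  cat("<regimen>", format(x), "\n")
  invisible(x)
}

.ESCALATION_REASONS <- c("relapse", "metastatic", "no_feasible_option",
                         "non_unanimous")

#' Decision set: therapeutic options or a face-to-face escalation
#'
#' The engine's output is either a non-empty set of alternative regimens the
#' MDM members can validate, or an escalation to a face-to-face meeting with
#' the reasons that triggered it. [canonicalize_decision()] produces the same
#' structure from free-text decision strings (there the reason list may be
#' empty, since prose like "Face-to-face MDM" does not state one).
#'
#' @param kind `"options"` or `"face_to_face"`.
#' @param alternatives List of [regimen()]s; non-empty iff `kind = "options"`.
#' @param reasons Character vector of escalation reasons, each one of
#'   `relapse`, `metastatic`, `no_feasible_option`, `non_unanimous`; empty
#'   unless `kind = "face_to_face"`.
#' @return An object of class `mdm_decision`.
#' @export
decision_set <- function(kind = c("options", "face_to_face"),
                         alternatives = list(), reasons = character()) {
  kind <- match.arg(kind)
  alternatives <- lapply(alternatives, function(a) {
    if (inherits(a, "mdm_regimen")) a else do.call(regimen, as.list(a))
  })
  if (kind == "options") {
    if (length(alternatives) == 0L) {
      stop("an options decision must offer at least one regimen", call. = FALSE)
    }
    if (length(reasons)) {
      stop("an options decision carries no escalation reasons", call. = FALSE)
    }
  } else {
    if (length(alternatives)) {
      stop("a face-to-face decision carries no regimens", call. = FALSE)
    }
    bad <- setdiff(reasons, .ESCALATION_REASONS)
    if (length(bad)) {
      stop(sprintf("unknown escalation reason: %s",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
  }
  # alternatives are a set: deduplicate by key, stable order for rendering
  if (length(alternatives)) {
    keys <- vapply(alternatives, regimen_key, character(1))
    alternatives <- alternatives[!duplicated(keys)]
    alternatives <- .sort_regimens(alternatives)
  }
  structure(list(kind = kind, alternatives = alternatives,
                 reasons = as.character(reasons)),
            class = "mdm_decision")
}

# stable rendering order: shorter regimens first, then fixed modality order
.sort_regimens <- function(regimens) {
  ord <- order(vapply(regimens, length, integer(1)),
               vapply(regimens, function(r) {
                 paste(sprintf("%02d", match(as.character(r), .MODALITIES)),
                       collapse = "")
               }, character(1)))
  regimens[ord]
}

#' Canonical equality key of a decision
#'
#' Two decisions are in agreement iff their keys are equal: both face-to-face,
#' or the same unordered set of regimens (each regimen compared by
#' [regimen_key()]).
#'
#' @param d An `mdm_decision`.
#' @return A single string.
#' @export
decision_key <- function(d) {
  stopifnot(inherits(d, "mdm_decision"))
  if (d$kind == "face_to_face") return("face-to-face")
  paste(sort(vapply(d$alternatives, regimen_key, character(1))),
        collapse = " | ")
}

#' @export
format.mdm_decision <- function(x, ...) {
  if (x$kind == "face_to_face") return("Face-to-face MDM")
  s <- paste(vapply(x$alternatives, function(r) {
    paste(as.character(r), collapse = " + ")
  }, character(1)), collapse = " or ")
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' @export
print.mdm_decision <- function(x, ...) {
  cat("<MDM decision>", format(x), "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

## ---- rule table ------------------------------------------------------------

#' Read a rule table from a JSON config
#'
#' The rule table maps (tumor sublocation, stage class) to the set of
#' guideline-backed candidate regimens, before any feasibility filtering. It
#' is data, not code: the shipped table can be replaced by any JSON file of
#' the same shape (`version`, then `entries` with `site`, `stage`,
#' `regimens` as arrays of modality arrays, and an `anchored` flag marking
#' cells pinned directly to a published reference case).
#'
#' Structural requirements, checked on load: every sublocation has a
#' non-empty entry for both `early` and `locally_advanced`, and no entry for
#' `metastatic` (metastatic disease always escalates; see [decide()]).
#'
#' @param path Path to a rules JSON file.
#' @return An object of class `mdm_rule_table`.
#' @seealso [default_rule_table()]
#' @export
read_rule_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$entries)) stop("rules file has no 'entries'", call. = FALSE)
  entries <- list()
  anchored <- logical()
  for (e in raw$entries) {
    site <- e$site
    stage <- e$stage
    if (!(site %in% .SITES)) {
      stop(sprintf("rules file: unknown site '%s'", site), call. = FALSE)
    }
    if (identical(stage, "metastatic")) {
      stop("rules file: metastatic entries are not allowed (always escalates)",
           call. = FALSE)
    }
    if (!(stage %in% c("early", "locally_advanced"))) {
      stop(sprintf("rules file: unknown stage class '%s'", stage), call. = FALSE)
    }
    regs <- lapply(e$regimens, function(r) do.call(regimen, as.list(unlist(r))))
    if (length(regs) == 0L) {
      stop(sprintf("rules file: empty entry for (%s, %s)", site, stage),
           call. = FALSE)
    }
    key <- paste(site, stage, sep = "|")
    if (!is.null(entries[[key]])) {
      stop(sprintf("rules file: duplicate entry for (%s, %s)", site, stage),
           call. = FALSE)
    }
    entries[[key]] <- .sort_regimens(regs)
    anchored[[key]] <- isTRUE(e$anchored)
  }
  missing <- character()
  for (site in .SITES) {
    for (stage in c("early", "locally_advanced")) {
      if (is.null(entries[[paste(site, stage, sep = "|")]])) {
        missing <- c(missing, paste0("(", site, ", ", stage, ")"))
      }
    }
  }
  if (length(missing)) {
    stop(sprintf("rules file: missing entries for %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(version = raw$version, entries = entries, anchored = anchored),
            class = "mdm_rule_table")
}

#' The rule table shipped with the package
#'
#' Loaded once per session from `inst/extdata/rules.json` and cached. Cells
#' directly anchored to a published reference case carry `anchored = TRUE` in
#' the JSON; the remaining cells follow the table's general pattern (advanced
#' non-nasopharyngeal disease offers surgery with adjuvant radiation or
#' concurrent chemoradiation; the nasopharynx is never treated surgically).
#'
#' @return An `mdm_rule_table`.
#' @export
default_rule_table <- function() {
  if (is.null(.octomdm_env$rules)) {
    path <- system.file("extdata", "rules.json", package = "octomdm",
                        mustWork = TRUE)
    .octomdm_env$rules <- read_rule_table(path)
  }
  .octomdm_env$rules
}

#' @export
print.mdm_rule_table <- function(x, ...) {
  cat(sprintf("<MDM rule table v%s> %d entries\n",
              as.character(x$version), length(x$entries)))
  for (key in names(x$entries)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    dec <- decision_set("options", x$entries[[key]])
    cat(sprintf("  %-19s %-16s %s%s\n", parts[1], parts[2], format(dec),
                if (isTRUE(x$anchored[[key]])) "" else "  [unanchored]"))
  }
  invisible(x)
}

## ---- engine operations -----------------------------------------------------

#' Candidate regimens for a sublocation and stage class
#'
#' Looks up the rule-table entry before any feasibility filtering. Histology
#' is part of the lookup interface for forward compatibility, but the shipped
#' table needs no histology split: the characteristic nasopharyngeal
#' histology (UCNT) is carried implicitly by the nasopharynx site, whose
#' entries never include surgery.
#'
#' @param site One of [tumor_sublocations()].
#' @param stage `"early"` or `"locally_advanced"`. Metastatic disease has no
#'   table entry and must be routed to escalation by the caller; passing
#'   `"metastatic"` is an error.
#' @param histology One of [histology_labels()].
#' @param rules An `mdm_rule_table` (default: the shipped table).
#' @return List of [regimen()]s (non-empty).
#' @examples
#' candidate_regimens("larynx_glottic", "early")
#' @export
candidate_regimens <- function(site, stage, histology = "epidermoid_carcinoma",
                               rules = default_rule_table()) {
  if (!(site %in% .SITES)) {
    stop(sprintf("unknown sublocation '%s'", site), call. = FALSE)
  }
  if (identical(stage, "metastatic")) {
    stop("metastatic stage has no rule-table entry: route M1 cases to escalation",
         call. = FALSE)
  }
  if (!(stage %in% c("early", "locally_advanced"))) {
    stop(sprintf("unknown stage class '%s'", stage), call. = FALSE)
  }
  if (!(histology %in% .HISTOLOGIES)) {
    stop(sprintf("unknown histology '%s'", histology), call. = FALSE)
  }
  rules$entries[[paste(site, stage, sep = "|")]]
}

#' Filter regimens by treatment feasibility
#'
#' A regimen survives iff every one of its component modalities is flagged
#' feasible for the patient. The result is always a subset of the input;
#' flipping any flag from feasible to infeasible can only shrink it.
#'
#' @param regimens List of [regimen()]s.
#' @param feasibility Named logical vector over `surgery`, `radiation`,
#'   `chemotherapy` (see [case_feasibility()]), or a [patient_case()].
#' @return The surviving regimens (possibly an empty list).
#' @examples
#' regs <- candidate_regimens("floor_of_mouth", "locally_advanced")
#' filter_feasible(regs, c(surgery = FALSE, radiation = TRUE, chemotherapy = TRUE))
#' @export
filter_feasible <- function(regimens, feasibility) {
  if (is_patient_case(feasibility)) feasibility <- case_feasibility(feasibility)
  if (!is.logical(feasibility) || is.null(names(feasibility)) ||
      !all(.MODALITIES %in% names(feasibility))) {
    stop("feasibility must be a named logical vector over all three modalities",
         call. = FALSE)
  }
  keep <- vapply(regimens, function(r) all(feasibility[as.character(r)]),
                 logical(1))
  regimens[keep]
}

#' Generate the automatic therapeutic proposal for a case
#'
#' The engine's decision logic, a pure function of the case record:
#' \enumerate{
#'   \item a relapsed case escalates to a face-to-face MDM;
#'   \item a metastatic (M1) case escalates;
#'   \item otherwise the rule-table candidates for (site, stage class) are
#'     filtered by feasibility; if no regimen survives the case escalates,
#'     else the surviving regimens are proposed as alternatives for the MDM
#'     members to validate.
#' }
#' An escalation carries every applicable reason (see
#' [escalation_reasons()]), with the triggering one first.
#'
#' @param case A valid [patient_case()].
#' @param rules An `mdm_rule_table` (default: the shipped table).
#' @return An `mdm_decision`.
#' @examples
#' decide(patient_case("c1", "larynx_glottic", "T1N0M0", "epidermoid_carcinoma"))
#' @export
decide <- function(case, rules = default_rule_table()) {
  violations <- validate_case(case)
  if (length(violations)) {
    stop(paste0("invalid case: ", paste(violations, collapse = "; ")),
         call. = FALSE)
  }
  reasons <- escalation_reasons(case, rules)
  if (length(reasons)) {
    return(decision_set("face_to_face", reasons = reasons))
  }
  opts <- filter_feasible(
    candidate_regimens(case$site, classify_stage(case$tnm), case$histology, rules),
    case_feasibility(case))
  decision_set("options", opts)
}

#' All escalation reasons applicable to a case
#'
#' Explains a face-to-face outcome: applies each escalation check
#' independently and returns the reasons in trigger order (`relapse`,
#' `metastatic`, `no_feasible_option`). For the feasibility check on an M1
#' case, the stage class is taken from the T/N categories alone so the
#' metastasis-independent rule-table entry is the one filtered. Empty iff
#' [decide()] yields therapeutic options.
#'
#' @inheritParams decide
#' @return Character vector of reason tags (possibly empty).
#' @export
escalation_reasons <- function(case, rules = default_rule_table()) {
  violations <- validate_case(case)
  if (length(violations)) {
    stop(paste0("invalid case: ", paste(violations, collapse = "; ")),
         call. = FALSE)
  }
  reasons <- character()
  if (isTRUE(case$relapse)) reasons <- c(reasons, "relapse")
  if (case$tnm$m == "M1") reasons <- c(reasons, "metastatic")
  stage_m0 <- classify_stage(tnm_stage(case$tnm$t, case$tnm$n, "M0"))
  opts <- filter_feasible(
    candidate_regimens(case$site, stage_m0, case$histology, rules),
    case_feasibility(case))
  if (length(opts) == 0L) reasons <- c(reasons, "no_feasible_option")
  reasons
}
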