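# Consensus/validation workflow around the engine: submission, the 15-day
# review deadline, consultant votes, unanimity, escalation, messaging,
# reports and role-based visibility. All timestamps are injected, never read
# from the environment, so every run is replayable.

.ROLES <- c("otolaryngologist", "oncologist", "radiotherapist", "radiologist",
            "pathologist", "resident")
.CONSULTANTS <- .ROLES[.ROLES != "resident"]
.MESSAGE_KINDS <- c("imaging_review", "pathology_review", "expert_opinion")

#' MDM member roles
#'
#' The MDM faculty comprises five consultant roles — otolaryngologist,
#' oncologist, radiotherapist, radiologist and pathologist — who together
#' form the voting faculty, plus the resident role, which submits cases and
#' never votes.
#'
#' @return Character vector of role names.
#' @export
mdm_roles <- function() .ROLES

#' @rdname mdm_roles
#' @export
consultant_roles <- function() .CONSULTANTS

#' Open a draft review record for a case
#'
#' A draft record wraps an unsubmitted case: it can still be edited or
#' deleted by the submitting resident ([can_edit()]), has no engine decision
#' and accepts no votes. [submit_case()] moves it to `pending` (or straight
#' to `escalated` for complex cases).
#'
#' @param case A valid, unsubmitted [patient_case()].
#' @return An object of class `mdm_review` with `status = "draft"`.
#' @export
create_draft <- function(case) {
  violations <- validate_case(case)
  if (length(violations)) {
    stop(paste0("invalid case: ", paste(violations, collapse = "; ")),
         call. = FALSE)
  }
  if (!is.null(case$submitted_at)) {
    stop("case has already been submitted", call. = FALSE)
  }
  structure(list(case = case, engine_decision = NULL, options = list(),
                 votes = list(), status = "draft", deadline = NULL,
                 outcome = NULL, messages = list()),
            class = "mdm_review")
}

is_mdm_review <- function(x) inherits(x, "mdm_review")

#' Submit a case for MDM review
#'
#' Freezes the case, computes the engine's automatic proposal and opens the
#' review window. The record becomes `pending` with a deadline of
#' `review_window_days` after submission (default 15 days, matching a
#' face-to-face meeting cadence of every two weeks); if the engine escalates
#' immediately (relapse, metastasis, no feasible option), the record is
#' `escalated` at submission and takes no votes.
#'
#' @param case A valid draft [patient_case()], or a draft `mdm_review` from
#'   [create_draft()]. A case that already carries a submission timestamp is
#'   rejected: submitted cases are frozen.
#' @param now Submission time (POSIXct or ISO-8601 string).
#' @param rules Rule table passed to [decide()].
#' @param review_window_days Length of the review window in days.
#' @return An `mdm_review` record with status `pending` or `escalated`.
#' @examples
#' case <- patient_case("c1", "larynx_glottic", "T1N0M0", "epidermoid_carcinoma",
#'                      submitted_by = "resident_a")
#' rec <- submit_case(case, "2023-01-01")
#' rec$deadline
#' @export
submit_case <- function(case, now, rules = default_rule_table(),
                        review_window_days = 15) {
  if (is_mdm_review(case)) {
    if (case$status != "draft") {
      stop("only a draft record can be submitted", call. = FALSE)
    }
    case <- case$case
  }
  violations <- validate_case(case)
  if (length(violations)) {
    stop(paste0("invalid case: ", paste(violations, collapse = "; ")),
         call. = FALSE)
  }
  if (!is.null(case$submitted_at)) {
    stop("case has already been submitted: submitted cases are frozen",
         call. = FALSE)
  }
  now <- as_timestamp(now)
  case$submitted_at <- now
  dec <- decide(case, rules)
  rec <- structure(list(
    case = case,
    engine_decision = dec,
    options = dec$alternatives,   # proposed alternatives get appended here
    votes = list(),
    status = if (dec$kind == "face_to_face") "escalated" else "pending",
    deadline = now + review_window_days * 86400,
    outcome = if (dec$kind == "face_to_face") dec else NULL,
    messages = list()
  ), class = "mdm_review")
  rec
}

#' May an actor edit or delete a case file?
#'
#' A file can be edited or deleted only by the resident who created it, and
#' only as long as it has not been submitted to the MDM (i.e. the record is
#' still a draft).
#'
#' @param record An `mdm_review`.
#' @param role The actor's role, one of [mdm_roles()].
#' @param actor_id The actor's identifier.
#' @return `TRUE` or `FALSE`.
#' @export
can_edit <- function(record, role, actor_id) {
  stopifnot(is_mdm_review(record))
  identical(role, "resident") &&
    identical(actor_id, record$case$submitted_by) &&
    record$status == "draft"
}

#' Record a consultant's vote on a pending review
#'
#' Consultants can validate one of the proposed options, propose another
#' "more suitable" regimen — which becomes visible to the other members as a
#' votable option — or request that the case be discussed face-to-face.
#' One vote per consultant role: re-voting before resolution replaces the
#' earlier vote. Residents cannot vote, and votes are only accepted while
#' the record is `pending`.
#'
#' @param record A pending `mdm_review`.
#' @param role A consultant role (see [consultant_roles()]).
#' @param choice A [regimen()] (or character vector of modalities), or the
#'   string `"face_to_face"` to request in-person discussion.
#' @param now Time the vote is cast.
#' @return The updated record.
#' @export
record_vote <- function(record, role, choice, now) {
  stopifnot(is_mdm_review(record))
  if (record$status != "pending") {
    stop(sprintf("cannot vote on a %s record", record$status), call. = FALSE)
  }
  if (!(role %in% .CONSULTANTS)) {
    stop(sprintf("'%s' is not a voting consultant role", as.character(role)),
         call. = FALSE)
  }
  now <- as_timestamp(now)
  if (identical(choice, "face_to_face")) {
    vote <- list(role = role, kind = "face_to_face", regimen = NULL,
                 cast_at = now)
  } else {
    reg <- if (inherits(choice, "mdm_regimen")) choice
           else do.call(regimen, as.list(as.character(choice)))
    keys <- vapply(record$options, regimen_key, character(1))
    if (!(regimen_key(reg) %in% keys)) {
      # a proposed alternative becomes a votable option for the other members
      record$options <- c(record$options, list(reg))
    }
    vote <- list(role = role, kind = "regimen", regimen = reg, cast_at = now)
  }
  record$votes[[role]] <- vote
  record
}

#' Resolve a review once the full faculty has voted
#'
#' Requires a vote from each of the five consultant roles. If all five chose
#' the same regimen the record is `validated` with that regimen as the
#' unanimous outcome. Any split — different regimens, or any single
#' face-to-face request — escalates the case: a unanimous decision cannot be
#' reached, so the final report carries the face-to-face MDM option with
#' reason `non_unanimous`. The result does not depend on the order in which
#' votes arrived.
#'
#' @param record A pending `mdm_review` with all five consultant votes cast.
#' @return The resolved record (`validated` or `escalated`).
#' @export
resolve_votes <- function(record) {
  stopifnot(is_mdm_review(record))
  if (record$status != "pending") {
    stop(sprintf("cannot resolve a %s record", record$status), call. = FALSE)
  }
  missing <- setdiff(.CONSULTANTS, names(record$votes))
  if (length(missing)) {
    stop(sprintf("cannot resolve before all five consultants have voted (missing: %s)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  votes <- record$votes[.CONSULTANTS]
  kinds <- vapply(votes, `[[`, character(1), "kind")
  if (all(kinds == "regimen")) {
    keys <- vapply(votes, function(v) regimen_key(v$regimen), character(1))
    if (length(unique(keys)) == 1L) {
      record$status <- "validated"
      record$outcome <- votes[[1]]$regimen
      return(record)
    }
  }
  record$status <- "escalated"
  record$outcome <- decision_set("face_to_face", reasons = "non_unanimous")
  record
}

#' List pending reviews past their deadline
#'
#' The review deadline is inclusive: a record becomes overdue strictly after
#' its deadline. Only pending records count — validated and escalated
#' records are closed.
#'
#' @param records List of `mdm_review` records.
#' @param now Current time.
#' @return Character vector of case ids, ordered by deadline (earliest
#'   first).
#' @export
list_overdue <- function(records, now) {
  now <- as_timestamp(now)
  pending <- Filter(function(r) is_mdm_review(r) && r$status == "pending" &&
                      now > r$deadline, records)
  if (length(pending) == 0L) return(character())
  ord <- order(vapply(pending, function(r) as.numeric(r$deadline), numeric(1)))
  vapply(pending[ord], function(r) r$case$case_id, character(1))
}

#' Request another member's opinion on a case
#'
#' The internal mailing system lets a member ask another member for a
#' special opinion — a review of the patient's imaging or pathology, or a
#' local expert opinion. The message is appended to the case's message log
#' within the roster.
#'
#' @param records Roster: a list of `mdm_review` records.
#' @param case_ref Case id of an existing record in the roster.
#' @param from_role,to_role Member roles (see [mdm_roles()]).
#' @param kind One of `"imaging_review"`, `"pathology_review"`,
#'   `"expert_opinion"`.
#' @param body Message text.
#' @param now Time sent.
#' @return The updated roster.
#' @export
request_opinion <- function(records, case_ref, from_role, to_role, kind, body,
                            now) {
  ids <- vapply(records, function(r) r$case$case_id, character(1))
  idx <- match(case_ref, ids)
  if (is.na(idx)) {
    stop(sprintf("unknown case: '%s'", case_ref), call. = FALSE)
  }
  records[[idx]] <- send_message(records[[idx]], from_role, to_role, kind,
                                 body, now)
  records
}

#' @rdname request_opinion
#' @param record A single `mdm_review` record.
#' @export
send_message <- function(record, from_role, to_role, kind, body, now) {
  stopifnot(is_mdm_review(record))
  if (!(from_role %in% .ROLES) || !(to_role %in% .ROLES)) {
    stop("message roles must be MDM member roles", call. = FALSE)
  }
  if (!(kind %in% .MESSAGE_KINDS)) {
    stop(sprintf("unknown message kind '%s' (expected one of: %s)",
                 as.character(kind), paste(.MESSAGE_KINDS, collapse = ", ")),
         call. = FALSE)
  }
  msg <- list(from_role = from_role, to_role = to_role,
              case_ref = record$case$case_id, kind = kind,
              body = as.character(body), sent_at = as_timestamp(now))
  record$messages <- c(record$messages, list(msg))
  record
}

#' Generate the final report of a closed review
#'
#' Available once the review is `validated` or `escalated`. The report
#' collects the case summary, the engine's proposal, every consultant vote,
#' the outcome (the unanimous regimen, or the face-to-face MDM option with
#' its escalation reasons) and the message log. `format()` renders it as
#' markdown; [report_json()] serializes it.
#'
#' @param record A closed `mdm_review`.
#' @return An object of class `mdm_report`.
#' @export
generate_report <- function(record) {
  stopifnot(is_mdm_review(record))
  if (!(record$status %in% c("validated", "escalated"))) {
    stop(sprintf("no report for a %s record: resolve the review first",
                 record$status), call. = FALSE)
  }
  case <- record$case
  outcome <- record$outcome
  outcome_text <- if (inherits(outcome, "mdm_decision")) format(outcome)
                  else format(outcome)  # mdm_regimen
  reasons <- if (inherits(outcome, "mdm_decision")) outcome$reasons else character()
  votes <- lapply(record$votes, function(v) {
    list(role = v$role,
         choice = if (v$kind == "face_to_face") "Face-to-face MDM"
                  else format(v$regimen),
         cast_at = format_timestamp(v$cast_at))
  })
  structure(list(
    case_id = case$case_id,
    status = record$status,
    case_summary = list(
      site = case$site,
      tnm = format(case$tnm),
      stage_class = classify_stage(case$tnm),
      histology = case$histology,
      feasibility = as.list(case_feasibility(case)),
      relapse = isTRUE(case$relapse),
      poor_prognosis_factors = case$poor_prognosis_factors,
      submitted_by = case$submitted_by,
      submitted_at = format_timestamp(case$submitted_at)
    ),
    engine_decision = format(record$engine_decision),
    votes = unname(votes),
    outcome = outcome_text,
    escalation_reasons = reasons,
    messages = lapply(record$messages, function(m) {
      list(from_role = m$from_role, to_role = m$to_role, kind = m$kind,
           body = m$body, sent_at = format_timestamp(m$sent_at))
    })
  ), class = "mdm_report")
}

#' @export
format.mdm_report <- function(x, ...) {
  cs <- x$case_summary
  feas <- names(Filter(isTRUE, cs$feasibility))
  lines <- c(
    sprintf("# MDM report — case %s", x$case_id),
    "",
    sprintf("- Site: %s (%s, %s)", cs$site, cs$tnm, cs$stage_class),
    sprintf("- Histology: %s", cs$histology),
    sprintf("- Feasible modalities: %s",
            if (length(feas)) paste(feas, collapse = ", ") else "none"),
    sprintf("- Relapse: %s", if (cs$relapse) "yes" else "no"),
    if (length(cs$poor_prognosis_factors))
      sprintf("- Poor prognosis factors: %s",
              paste(cs$poor_prognosis_factors, collapse = "; ")),
    sprintf("- Submitted by %s on %s", cs$submitted_by, cs$submitted_at),
    "",
    sprintf("Automatic proposal: %s", x$engine_decision),
    ""
  )
  if (length(x$votes)) {
    lines <- c(lines, "Votes:",
               vapply(x$votes, function(v) sprintf("- %s: %s", v$role, v$choice),
                      character(1)), "")
  }
  lines <- c(lines, sprintf("**Outcome (%s): %s**", x$status, x$outcome))
  if (length(x$escalation_reasons)) {
    lines <- c(lines, sprintf("Escalation reasons: %s",
                              paste(x$escalation_reasons, collapse = ", ")))
  }
  if (length(x$messages)) {
    lines <- c(lines, "", "Messages:",
               vapply(x$messages, function(m) {
                 sprintf("- %s -> %s [%s]: %s", m$from_role, m$to_role,
                         m$kind, m$body)
               }, character(1)))
  }
  paste(lines[!vapply(lines, is.null, logical(1))], collapse = "\n")
}

#' @export
print.mdm_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname generate_report
#' @param report An `mdm_report`.
#' @return `report_json()`: a JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "mdm_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
}

#' May an actor view a final report?
#'
#' Consultants see every report; a resident sees only the reports of the
#' cases they submitted.
#'
#' @inheritParams can_edit
#' @return `TRUE` or `FALSE`.
#' @export
can_view_report <- function(record, role, actor_id) {
  stopifnot(is_mdm_review(record))
  if (role %in% .CONSULTANTS) return(TRUE)
  identical(role, "resident") && identical(actor_id, record$case$submitted_by)
}

#' @export
print.mdm_review <- function(x, ...) {
  cat(sprintf("<MDM review %s> status: %s\n", x$case$case_id, x$status))
  if (!is.null(x$engine_decision)) {
    cat("  engine:", format(x$engine_decision), "\n")
  }
  if (!is.null(x$deadline)) {
    cat("  deadline:", format_timestamp(x$deadline), "\n")
  }
  if (length(x$votes)) {
    cat("  votes:", paste(names(x$votes), collapse = ", "), "\n")
  }
  if (!is.null(x$outcome)) cat("  outcome:", format(x$outcome), "\n")
  invisible(x)
}
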