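test_that("submission freezes the case and opens a 15-day review window", {
  rec <- submit_case(make_case(), "2023-01-01")
  expect_equal(rec$status, "pending")
  expect_equal(rec$deadline, as.POSIXct("2023-01-16", tz = "UTC"))
  expect_equal(rec$case$submitted_at, as.POSIXct("2023-01-01", tz = "UTC"))

  # a submitted case is frozen
  expect_error(submit_case(rec$case, "2023-01-02"), "frozen")

  # configurable review window
  rec30 <- submit_case(make_case(), "2023-01-01", review_window_days = 30)
  expect_equal(rec30$deadline, as.POSIXct("2023-01-31", tz = "UTC"))
})

test_that("complex cases are escalated at submission and take no votes", {
  relapse <- make_case(site = "hypopharynx", tnm = "T3N2cM0", relapse = TRUE,
                       surgery = FALSE, radiation = FALSE)
  rec <- submit_case(relapse, "2023-01-01")
  expect_equal(rec$status, "escalated")
  expect_equal(rec$outcome$kind, "face_to_face")
  expect_true("relapse" %in% rec$outcome$reasons)
  expect_error(record_vote(rec, "oncologist", regimen("radiation"), "2023-01-02"),
               "escalated")
})

test_that("only the submitting resident can edit, and only while a draft", {
  draft <- create_draft(make_case(submitted_by = "resident_a"))
  expect_true(can_edit(draft, "resident", "resident_a"))
  expect_false(can_edit(draft, "resident", "resident_b"))
  expect_false(can_edit(draft, "oncologist", "resident_a"))

  rec <- submit_case(draft, "2023-01-01")
  expect_false(can_edit(rec, "resident", "resident_a"))
  expect_error(submit_case(rec, "2023-01-02"), "draft")
})

test_that("votes are one per consultant role, replaceable, resident excluded", {
  rec <- submit_case(make_case(site = "oropharynx", tnm = "T2N0M0"), "2023-01-01")

  rec <- record_vote(rec, "radiotherapist", regimen("radiation", "chemotherapy"),
                     "2023-01-02")
  expect_equal(names(rec$votes), "radiotherapist")

  # re-vote replaces
  rec <- record_vote(rec, "radiotherapist", regimen("surgery", "radiation"),
                     "2023-01-03")
  expect_length(rec$votes, 1)
  expect_equal(regimen_key(rec$votes$radiotherapist$regimen), "surgery+radiation")

  expect_error(record_vote(rec, "resident", regimen("radiation"), "2023-01-02"),
               "consultant")
})

test_that("a proposed alternative becomes a votable option for other members", {
  rec <- submit_case(make_case(), "2023-01-01")
  n_before <- length(rec$options)
  rec <- record_vote(rec, "oncologist", regimen("surgery", "radiation"),
                     "2023-01-02")
  expect_equal(length(rec$options), n_before + 1)
  expect_true("surgery+radiation" %in%
                vapply(rec$options, regimen_key, character(1)))
})

test_that("resolution requires all five votes and demands unanimity", {
  base <- submit_case(make_case(site = "oropharynx", tnm = "T2N0M0"), "2023-01-01")
  roles <- consultant_roles()

  # unanimity validates
  rec <- base
  for (r in roles) rec <- record_vote(rec, r, regimen("radiation", "chemotherapy"),
                                      "2023-01-02")
  rec <- resolve_votes(rec)
  expect_equal(rec$status, "validated")
  expect_equal(regimen_key(rec$outcome), "radiation+chemotherapy")

  # a 4-1 split escalates with reason non_unanimous
  rec <- base
  for (r in roles[1:4]) rec <- record_vote(rec, r, regimen("radiation", "chemotherapy"),
                                           "2023-01-02")
  rec <- record_vote(rec, roles[5], regimen("surgery", "radiation"), "2023-01-02")
  rec <- resolve_votes(rec)
  expect_equal(rec$status, "escalated")
  expect_equal(rec$outcome$reasons, "non_unanimous")

  # a single face-to-face request escalates
  rec <- base
  for (r in roles[1:4]) rec <- record_vote(rec, r, regimen("radiation", "chemotherapy"),
                                           "2023-01-02")
  rec <- record_vote(rec, roles[5], "face_to_face", "2023-01-02")
  rec <- resolve_votes(rec)
  expect_equal(rec$status, "escalated")

  # incomplete faculty cannot resolve
  rec <- record_vote(base, "oncologist", regimen("surgery", "radiation"),
                     "2023-01-02")
  expect_error(resolve_votes(rec), "all five")
})

test_that("resolution does not depend on vote arrival order", {
  set.seed(99)
  choices <- list(regimen("radiation", "chemotherapy"),
                  regimen("surgery", "radiation"),
                  "face_to_face")
  for (rep in 1:20) {
    picks <- sample(seq_along(choices), 5, replace = TRUE)
    outcomes <- vapply(1:3, function(.) {
      rec <- submit_case(make_case(site = "oropharynx", tnm = "T2N0M0"),
                         "2023-01-01")
      ord <- sample(5)
      for (i in ord) {
        rec <- record_vote(rec, consultant_roles()[i], choices[[picks[i]]],
                           "2023-01-02")
      }
      resolve_votes(rec)$status
    }, character(1))
    expect_length(unique(outcomes), 1)
  }
})

test_that("overdue listing is strict after an inclusive deadline, pending only", {
  r1 <- submit_case(make_case(case_id = "a"), "2023-01-01")
  r2 <- submit_case(make_case(case_id = "b"), "2023-01-05")
  r3 <- submit_case(make_case(case_id = "c"), "2023-01-01")
  for (r in consultant_roles()) r3 <- record_vote(r3, r, regimen("radiation"),
                                                  "2023-01-02")
  r3 <- resolve_votes(r3)  # validated, no longer counted

  expect_equal(list_overdue(list(r1, r2, r3), "2023-01-16"), character())
  expect_equal(list_overdue(list(r2, r1, r3), "2023-01-17"), "a")
  expect_equal(list_overdue(list(r2, r1, r3), "2023-02-01"), c("a", "b"))
})

test_that("opinion requests are logged against an existing case", {
  roster <- list(submit_case(make_case(case_id = "a"), "2023-01-01"))
  roster <- request_opinion(roster, "a", "oncologist", "pathologist",
                            "pathology_review", "please re-review the biopsy",
                            "2023-01-03")
  roster <- request_opinion(roster, "a", "otolaryngologist", "radiologist",
                            "imaging_review", "check node 2b on CT", "2023-01-04")
  expect_length(roster[[1]]$messages, 2)
  expect_equal(roster[[1]]$messages[[1]]$kind, "pathology_review")

  expect_error(request_opinion(roster, "zzz", "oncologist", "pathologist",
                               "pathology_review", "x", "2023-01-03"),
               "unknown case")
  expect_error(send_message(roster[[1]], "oncologist", "pathologist",
                            "gossip", "x", "2023-01-03"), "message kind")
})

test_that("reports exist only for closed reviews and carry the outcome", {
  rec <- submit_case(make_case(case_id = "a"), "2023-01-01")
  expect_error(generate_report(rec), "resolve")

  for (r in consultant_roles()) rec <- record_vote(rec, r, regimen("radiation"),
                                                   "2023-01-02")
  validated <- resolve_votes(rec)
  rep <- generate_report(validated)
  expect_equal(rep$status, "validated")
  expect_equal(rep$outcome, "Radiation")
  expect_match(format(rep), "Outcome \\(validated\\): Radiation")

  esc <- submit_case(make_case(case_id = "b", tnm = "T1N0M1"), "2023-01-01")
  rep2 <- generate_report(esc)
  expect_match(rep2$outcome, "Face-to-face")
  expect_equal(rep2$escalation_reasons, "metastatic")
  expect_match(format(rep2), "Face-to-face MDM")

  parsed <- jsonlite::fromJSON(report_json(rep))
  expect_equal(parsed$case_id, "a")
  expect_equal(parsed$outcome, "Radiation")
})

test_that("consultants see every report, residents only their own cases", {
  rec <- submit_case(make_case(submitted_by = "resident_a", tnm = "T1N0M1"),
                     "2023-01-01")
  expect_true(can_view_report(rec, "oncologist", "anyone"))
  expect_true(can_view_report(rec, "pathologist", "anyone"))
  expect_true(can_view_report(rec, "resident", "resident_a"))
  expect_false(can_view_report(rec, "resident", "resident_b"))
})

test_that("random legal operation sequences never take an illegal transition", {
  legal <- list(draft = c("draft", "pending", "escalated"),
                pending = c("pending", "validated", "escalated"),
                validated = character(), escalated = character())
  vote_pool <- list(regimen("radiation"), regimen("surgery", "radiation"),
                    regimen("radiation", "chemotherapy"), "face_to_face")
  set.seed(123)
  pool <- generate_cases(100, seed = 123)
  for (rep in 1:300) {
    case <- pool[[sample.int(length(pool), 1)]]
    res <- run_random_review(case, vote_pool)
    st <- res$statuses
    for (i in seq_len(length(st) - 1)) {
      expect_true(st[i + 1] %in% legal[[st[i]]])
    }
    final <- res$record
    expect_true(final$status %in% c("validated", "escalated"))
    if (final$status == "escalated") {
      expect_equal(final$outcome$kind, "face_to_face")
      expect_gte(length(final$outcome$reasons), 1)
    }
  }
})
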