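test_that("regimen keys treat chemoradiation as a set but keep surgery sequence", {
  expect_equal(regimen_key(regimen("radiation", "chemotherapy")),
               regimen_key(regimen("chemotherapy", "radiation")))
  expect_equal(regimen_key(regimen("surgery", "radiation")), "surgery+radiation")
  expect_false(regimen_key(regimen("surgery", "radiation")) ==
                 regimen_key(regimen("radiation", "surgery")))
  expect_error(regimen(), "at least one")
  expect_error(regimen("surgery", "surgery"), "repeat")
  expect_error(regimen("immunotherapy"), "unknown modality")
})

test_that("candidate_regimens returns the rule-table entry and rejects metastatic lookups", {
  keys <- function(regs) sort(vapply(regs, regimen_key, character(1)))

  expect_equal(keys(candidate_regimens("larynx_glottic", "early")),
               c("radiation", "surgery"))
  expect_equal(keys(candidate_regimens("nasopharynx", "locally_advanced", "ucnt")),
               "radiation+chemotherapy")
  expect_equal(keys(candidate_regimens("oropharynx", "early")),
               c("radiation+chemotherapy", "surgery+radiation"))

  expect_error(candidate_regimens("larynx_glottic", "metastatic"),
               "escalation")
  expect_error(candidate_regimens("sinus", "early"), "unknown sublocation")
})

test_that("the shipped rule table covers every curable cell and excludes surgery for nasopharynx", {
  rules <- default_rule_table()
  for (site in tumor_sublocations()) {
    for (stage in c("early", "locally_advanced")) {
      regs <- candidate_regimens(site, stage, rules = rules)
      expect_gt(length(regs), 0)
      if (site == "nasopharynx") {
        expect_false(any(vapply(regs, function(r) "surgery" %in% r, logical(1))))
      }
    }
  }
})

test_that("filter_feasible keeps exactly the regimens whose every modality is feasible", {
  regs <- list(regimen("surgery", "radiation"), regimen("radiation", "chemotherapy"))
  all_ok <- c(surgery = TRUE, radiation = TRUE, chemotherapy = TRUE)

  expect_length(filter_feasible(regs, replace(all_ok, "radiation", FALSE)), 0)

  no_surgery <- filter_feasible(regs, replace(all_ok, "surgery", FALSE))
  expect_length(no_surgery, 1)
  expect_equal(regimen_key(no_surgery[[1]]), "radiation+chemotherapy")

  expect_identical(filter_feasible(regs, all_ok), regs)
})

test_that("decide reproduces the reference behaviors", {
  d1 <- decide(make_case(site = "larynx_glottic", tnm = "T1N0M0"))
  expect_equal(d1$kind, "options")
  expect_equal(decision_key(d1),
               decision_key(canonicalize_decision("Radiation or surgery")))

  d2 <- decide(make_case(site = "oropharynx", tnm = "T3N1M0", radiation = FALSE))
  expect_equal(d2$kind, "face_to_face")
  expect_equal(d2$reasons, "no_feasible_option")

  d3 <- decide(make_case(site = "hypopharynx", tnm = "T3N2cM0", relapse = TRUE,
                         surgery = FALSE, radiation = FALSE))
  expect_equal(d3$kind, "face_to_face")
  expect_equal(d3$reasons[1], "relapse")

  d4 <- decide(make_case(site = "tongue_base", tnm = "T4N2cM1"))
  expect_equal(d4$kind, "face_to_face")
  expect_equal(d4$reasons[1], "metastatic")

  expect_error(decide(make_case(site = "sinus")), "invalid case")
})

test_that("escalation_reasons lists every applicable trigger in order", {
  # metastatic case whose T/N-based rule entry is also emptied by feasibility
  row5 <- make_case(site = "tongue_base", tnm = "T4N2cM1",
                    surgery = FALSE, chemotherapy = FALSE)
  expect_equal(escalation_reasons(row5), c("metastatic", "no_feasible_option"))

  expect_length(escalation_reasons(make_case()), 0)

  relapsed_m1 <- make_case(tnm = "T2N1M1", relapse = TRUE)
  expect_equal(escalation_reasons(relapsed_m1)[1:2], c("relapse", "metastatic"))

  # reasons empty exactly when decide yields options
  for (case in generate_cases(100, seed = 7)) {
    expect_equal(length(escalation_reasons(case)) == 0,
                 decide(case)$kind == "options")
  }
})

test_that("removing feasibility never enlarges the option set (monotonicity)", {
  option_keys <- function(case) {
    d <- decide(case)
    if (d$kind == "face_to_face") character()
    else sort(vapply(d$alternatives, regimen_key, character(1)))
  }
  flags <- c("surgery_feasible", "radiation_feasible", "chemotherapy_feasible")
  violations <- 0L
  for (case in generate_cases(300, seed = 11)) {
    before <- option_keys(case)
    for (flag in flags) {
      if (!case[[flag]]) next
      worse <- case
      worse[[flag]] <- FALSE
      after <- option_keys(worse)
      if (!all(after %in% before)) violations <- violations + 1L
    }
  }
  expect_equal(violations, 0L)
})

test_that("with all modalities feasible, M0 and no relapse, decide never escalates", {
  for (site in tumor_sublocations()) {
    for (tnm in c("T1N0M0", "T3N2cM0")) {  # one early, one locally advanced
      d <- decide(make_case(site = site, tnm = tnm))
      expect_equal(d$kind, "options")
    }
  }
})

test_that("decide is a pure function of the case record", {
  case <- make_case(site = "oropharynx", tnm = "T2N0M0")
  expect_identical(decide(case), decide(case))
})

test_that("rule tables are validated structurally on load", {
  path <- withr::local_tempfile(fileext = ".json")

  writeLines('{"version": 1, "entries": [
    {"site": "larynx_glottic", "stage": "early", "regimens": [["radiation"]]}
  ]}', path)
  expect_error(read_rule_table(path), "missing entries")

  writeLines('{"version": 1, "entries": [
    {"site": "larynx_glottic", "stage": "metastatic", "regimens": [["radiation"]]}
  ]}', path)
  expect_error(read_rule_table(path), "metastatic")

  writeLines('{"version": 1, "entries": [
    {"site": "larynx_glottic", "stage": "early", "regimens": []}
  ]}', path)
  expect_error(read_rule_table(path), "empty entry")
})
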