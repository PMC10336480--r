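# shared fixtures built in code

make_case <- function(case_id = "c1", site = "larynx_glottic", tnm = "T1N0M0",
                      histology = "epidermoid_carcinoma",
                      surgery = TRUE, radiation = TRUE, chemotherapy = TRUE,
                      relapse = FALSE, submitted_by = "resident_a", ...) {
  patient_case(case_id, site, tnm, histology,
               surgery_feasible = surgery, radiation_feasible = radiation,
               chemotherapy_feasible = chemotherapy, relapse = relapse,
               submitted_by = submitted_by, ...)
}

# brute-force Cohen's kappa oracle: chance agreement from a double loop over
# all (i, j) pair combinations, no marginal tabulation
kappa_oracle <- function(a, b) {
  n <- length(a)
  p_o <- sum(a == b) / n
  agree <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (a[i] == b[j]) agree <- agree + 1L
    }
  }
  p_e <- agree / n^2
  (p_o - p_e) / (1 - p_e)
}

# one random but legal pass through the review workflow; returns the visited
# status sequence so tests can assert on legal transitions only
run_random_review <- function(case, vote_pool) {
  statuses <- character()
  rec <- create_draft(case)
  statuses <- c(statuses, rec$status)
  rec <- submit_case(rec, "2024-03-01")
  statuses <- c(statuses, rec$status)
  if (rec$status == "pending") {
    roles <- sample(consultant_roles())
    extra <- sample(roles, sample(0:2, 1))  # some members re-vote
    for (role in c(roles, extra)) {
      rec <- record_vote(rec, role, sample(vote_pool, 1)[[1]], "2024-03-02")
      statuses <- c(statuses, rec$status)
    }
    rec <- resolve_votes(rec)
    statuses <- c(statuses, rec$status)
  }
  list(record = rec, statuses = statuses)
}
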