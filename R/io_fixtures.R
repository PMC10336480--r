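# Packaged reference cases, the seeded synthetic case generator, and
# JSON/CSV case I/O.

.CASE_FIELDS <- c("case_id", "site", "tnm", "histology", "surgery_feasible",
                  "radiation_feasible", "chemotherapy_feasible", "relapse",
                  "poor_prognosis_factors", "submitted_by", "submitted_at")

#' Load the packaged reference cases
#'
#' Ten fictitious head-and-neck cases used to validate the engine against a
#' blinded expert, packaged with both raw decision strings. The automatic
#' decision column is reproduced by running [decide()] on each case; the
#' expert column is what the blinded expert chose for the same case. Unicode
#' dash variants in the original strings are normalized to ASCII hyphens.
#'
#' @return A list of 10 fixtures, in original row order. Each element has
#'   `case` (a valid [patient_case()]), `expected_auto` and `expected_expert`
#'   (raw decision strings).
#' @examples
#' fx <- load_table1_fixtures()
#' fx[[1]]$expected_auto
#' @export
load_table1_fixtures <- function() {
  path <- system.file("extdata", "table1_cases.json", package = "octomdm",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fixtures <- lapply(raw$fixtures, function(fx) {
    list(case = .record_to_case(fx$case, "packaged fixture"),
         expected_auto = fx$expected_auto,
         expected_expert = fx$expected_expert)
  })
  if (length(fixtures) != 10L) {
    stop("packaged fixtures are corrupted: expected exactly 10 cases",
         call. = FALSE)
  }
  for (fx in fixtures) {
    v <- validate_case(fx$case)
    if (length(v)) {
      stop(sprintf("packaged fixtures are corrupted: case %s invalid (%s)",
                   fx$case$case_id, paste(v, collapse = "; ")), call. = FALSE)
    }
  }
  fixtures
}

## ---- synthetic case generator ---------------------------------------------

.PPF_POOL <- c("extracapsular_extension", "positive_margins",
               "perineural_invasion", "lymphovascular_invasion")

#' Generate synthetic patient cases
#'
#' Seeded generator of valid draft case files for testing and simulation.
#' Every sublocation is drawn with positive probability; the stage-class mix
#' defaults to half early, 40% locally advanced and 10% metastatic disease,
#' mirroring the composition of the packaged reference cases. Each modality
#' is independently infeasible at `infeasibility_rate`, and cases relapse at
#' `relapse_rate`. The same seed yields the identical case list; the caller's
#' RNG state is left untouched.
#'
#' @param n Number of cases (non-negative).
#' @param seed Optional integer seed for reproducible output.
#' @param site_weights Optional named non-negative weights over
#'   [tumor_sublocations()]; default uniform. Normalized to sum to 1.
#' @param stage_weights Named non-negative weights over [stage_classes()].
#' @param infeasibility_rate Probability, per modality, that it is flagged
#'   infeasible.
#' @param relapse_rate Probability a case is a relapse.
#' @return A list of `n` valid draft [patient_case()]s.
#' @examples
#' cases <- generate_cases(5, seed = 1)
#' vapply(cases, function(x) x$site, character(1))
#' @export
generate_cases <- function(n, seed = NULL, site_weights = NULL,
                           stage_weights = c(early = 0.5,
                                             locally_advanced = 0.4,
                                             metastatic = 0.1),
                           infeasibility_rate = 0.1, relapse_rate = 0.1) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  if (is.null(site_weights)) {
    site_weights <- stats::setNames(rep(1, length(.SITES)), .SITES)
  }
  site_weights <- .check_weights(site_weights, .SITES, "site_weights")
  stage_weights <- .check_weights(stage_weights, .STAGE_CLASSES, "stage_weights")
  for (p in c(infeasibility_rate = infeasibility_rate,
              relapse_rate = relapse_rate)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("rates must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (n == 0L) return(list())

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }

  # all valid T x N combinations per stage class (M fixed by the class)
  grid <- expand.grid(t = .TNM_T, n = .TNM_N, stringsAsFactors = FALSE)
  early_grid <- grid[grid$t %in% c("T1", "T2") & grid$n == "N0", ]
  adv_grid <- grid[!(grid$t %in% c("T1", "T2") & grid$n == "N0"), ]

  lapply(seq_len(n), function(i) {
    site <- sample(.SITES, 1L, prob = site_weights)
    cls <- sample(.STAGE_CLASSES, 1L, prob = stage_weights)
    tnm <- switch(cls,
      early = {
        row <- early_grid[sample.int(nrow(early_grid), 1L), ]
        tnm_stage(row$t, row$n, "M0")
      },
      locally_advanced = {
        row <- adv_grid[sample.int(nrow(adv_grid), 1L), ]
        tnm_stage(row$t, row$n, "M0")
      },
      metastatic = {
        row <- grid[sample.int(nrow(grid), 1L), ]
        tnm_stage(row$t, row$n, "M1")
      })
    histology <- if (site == "nasopharynx") "ucnt"
                 else sample(c("epidermoid_carcinoma", "other"), 1L,
                             prob = c(0.9, 0.1))
    feas <- stats::runif(3) >= infeasibility_rate
    n_ppf <- sample(0:2, 1L, prob = c(0.7, 0.2, 0.1))
    patient_case(
      case_id = sprintf("SYN-%05d", i),
      site = site,
      tnm = tnm,
      histology = histology,
      surgery_feasible = feas[1],
      radiation_feasible = feas[2],
      chemotherapy_feasible = feas[3],
      relapse = stats::runif(1) < relapse_rate,
      poor_prognosis_factors = if (n_ppf > 0) sample(.PPF_POOL, n_ppf) else character(),
      submitted_by = sample(paste0("resident_", 1:4), 1L)
    )
  })
}

.check_weights <- function(w, levels, what) {
  if (!is.numeric(w) || is.null(names(w)) || !setequal(names(w), levels) ||
      anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop(sprintf("%s must be non-negative named weights over: %s",
                 what, paste(levels, collapse = ", ")), call. = FALSE)
  }
  w <- w[levels]
  w / sum(w)
}

## ---- readers / writers -----------------------------------------------------

#' Read and write case rosters
#'
#' Case lists are exchanged as a JSON array of case objects or as a CSV
#' roster (UTF-8, comma-separated, header row required, booleans as
#' `true`/`false`, poor-prognosis factors joined with `;`). The TNM stage
#' travels as the compact string (e.g. `"T3N2cM0"`) and timestamps as
#' ISO-8601; a missing/empty `submitted_at` marks a draft. `read_cases()`
#' after `write_cases()` reproduces the case list exactly.
#'
#' Malformed records are rejected with the record number, case id and
#' offending field; duplicate case ids are an error.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @param cases A list of [patient_case()]s.
#' @return `read_cases()`: a list of validated [patient_case()]s.
#'   `write_cases()`: the path, invisibly.
#' @export
read_cases <- function(path, format = c("auto", "json", "csv")) {
  format <- .resolve_format(match.arg(format), path)
  if (!file.exists(path)) {
    stop(sprintf("cannot read cases: no such file '%s'", path), call. = FALSE)
  }
  records <- if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(raw)) stop("case JSON must be an array of case objects",
                            call. = FALSE)
    raw
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
    required <- setdiff(.CASE_FIELDS, c("submitted_at"))
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("CSV roster is missing required column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- lapply(rec, as.character)
      for (f in c("surgery_feasible", "radiation_feasible",
                  "chemotherapy_feasible", "relapse")) {
        rec[[f]] <- .parse_bool(rec[[f]], f, i)
      }
      ppf <- rec$poor_prognosis_factors
      rec$poor_prognosis_factors <-
        if (is.na(ppf) || !nzchar(ppf)) character()
        else strsplit(ppf, ";", fixed = TRUE)[[1]]
      if (!is.null(rec$submitted_at) &&
          (is.na(rec$submitted_at) || !nzchar(rec$submitted_at))) {
        rec$submitted_at <- NULL
      }
      rec
    })
  }

  cases <- vector("list", length(records))
  for (i in seq_along(records)) {
    cases[[i]] <- .record_to_case(records[[i]], sprintf("record %d", i))
    v <- validate_case(cases[[i]])
    if (length(v)) {
      stop(sprintf("invalid case in record %d ('%s'): %s", i,
                   as.character(cases[[i]]$case_id),
                   paste(v, collapse = "; ")), call. = FALSE)
    }
  }
  ids <- vapply(cases, function(x) x$case_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate case_id in roster: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  cases
}

#' @rdname read_cases
#' @export
write_cases <- function(cases, path, format = c("auto", "json", "csv")) {
  format <- .resolve_format(match.arg(format), path)
  for (case in cases) {
    v <- validate_case(case)
    if (length(v)) {
      stop(sprintf("refusing to write invalid case '%s': %s",
                   as.character(case$case_id), paste(v, collapse = "; ")),
           call. = FALSE)
    }
  }
  if (format == "json") {
    recs <- lapply(cases, .case_to_record)
    jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  } else {
    rows <- lapply(cases, function(case) {
      rec <- .case_to_record(case)
      data.frame(
        case_id = rec$case_id, site = rec$site, tnm = rec$tnm,
        histology = rec$histology,
        surgery_feasible = tolower(rec$surgery_feasible),
        radiation_feasible = tolower(rec$radiation_feasible),
        chemotherapy_feasible = tolower(rec$chemotherapy_feasible),
        relapse = tolower(rec$relapse),
        poor_prognosis_factors = paste(rec$poor_prognosis_factors,
                                       collapse = ";"),
        submitted_by = rec$submitted_by,
        submitted_at = if (is.null(rec$submitted_at)) "" else rec$submitted_at,
        stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

.resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  stop(sprintf("cannot infer format from '%s': pass format = 'json' or 'csv'",
               path), call. = FALSE)
}

.parse_bool <- function(x, field, row) {
  lx <- tolower(trimws(x))
  if (lx %in% c("true", "1")) return(TRUE)
  if (lx %in% c("false", "0")) return(FALSE)
  stop(sprintf("record %d: field '%s' must be true/false, got '%s'",
               row, field, x), call. = FALSE)
}

# flat exchange record (JSON object / CSV row) -> patient_case
.record_to_case <- function(rec, where) {
  required <- setdiff(.CASE_FIELDS, c("submitted_at", "poor_prognosis_factors"))
  missing <- required[!vapply(required, function(f) !is.null(rec[[f]]),
                              logical(1))]
  if (length(missing)) {
    stop(sprintf("%s: missing field(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ppf <- rec$poor_prognosis_factors
  ppf <- if (is.null(ppf)) character() else as.character(unlist(ppf))
  patient_case(
    case_id = rec$case_id,
    site = rec$site,
    tnm = rec$tnm,
    histology = rec$histology,
    surgery_feasible = rec$surgery_feasible,
    radiation_feasible = rec$radiation_feasible,
    chemotherapy_feasible = rec$chemotherapy_feasible,
    relapse = rec$relapse,
    poor_prognosis_factors = ppf,
    submitted_by = rec$submitted_by,
    submitted_at = rec$submitted_at
  )
}

.case_to_record <- function(case) {
  rec <- list(
    case_id = case$case_id,
    site = case$site,
    tnm = format(case$tnm),
    histology = case$histology,
    surgery_feasible = case$surgery_feasible,
    radiation_feasible = case$radiation_feasible,
    chemotherapy_feasible = case$chemotherapy_feasible,
    relapse = case$relapse,
    poor_prognosis_factors = case$poor_prognosis_factors,
    submitted_by = case$submitted_by
  )
  if (!is.null(case$submitted_at)) {
    rec$submitted_at <- format_timestamp(case$submitted_at)
  }
  rec
}
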