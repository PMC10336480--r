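# Canonicalization of free-text decision strings and Cohen's kappa between
# automatic and expert decisions.

.MODALITY_SYNONYMS <- c(
  surgery = "surgery",
  radiation = "radiation",
  radiotherapy = "radiation",
  chemotherapy = "chemotherapy",
  chemo = "chemotherapy",
  chemoradiation = "radiation+chemotherapy"
)

# all unicode hyphen/dash variants collapse to ASCII "-"
.normalize_dashes <- function(s) {
  gsub("[‐‑‒–—―−]", "-", s)
}

#' Canonicalize a free-text therapeutic decision string
#'
#' Parses the decision-string dialect used in MDM reports into a canonical
#' [decision_set()] so that differently-worded equivalent decisions compare
#' equal:
#' \itemize{
#'   \item `"and"` and `"+"` both combine modalities into one regimen;
#'   \item `"or"` separates alternative regimens;
#'   \item `"X ± Y"` expands to two alternatives, with and without `Y`;
#'   \item any capitalization/pluralization of "face-to-face MDM" (with any
#'     dash variant) is the face-to-face escalation;
#'   \item case, surrounding whitespace and unicode dash variants are
#'     ignored.
#' }
#'
#' @param text A single non-empty decision string.
#' @return An `mdm_decision`. An unrecognized token raises an error naming it.
#' @examples
#' canonicalize_decision("Radiation + chemotherapy")
#' canonicalize_decision("Radiation and chemotherapy")  # same decision
#' canonicalize_decision("Surgery ± radiation")
#' canonicalize_decision("Face-to-face MDMs")
#' @export
canonicalize_decision <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("decision text must be a single non-empty string", call. = FALSE)
  }
  s <- tolower(trimws(.normalize_dashes(text)))
  s <- gsub("\\s+", " ", s)

  if (grepl("face[ -]?to[ -]?face", s)) {
    if (!grepl("face[ -]?to[ -]?face mdms?$", s)) {
      stop(sprintf("unrecognized face-to-face decision string: '%s'", text),
           call. = FALSE)
    }
    return(decision_set("face_to_face"))
  }

  if (grepl("^\\s*or\\b", s) || grepl("\\bor\\s*$", s)) {
    stop(sprintf("empty alternative in decision string: '%s'", text),
         call. = FALSE)
  }
  alts <- list()
  for (branch in strsplit(s, "\\bor\\b")[[1]]) {
    branch <- trimws(branch)
    if (!nzchar(branch)) {
      stop(sprintf("empty alternative in decision string: '%s'", text),
           call. = FALSE)
    }
    if (grepl("±", branch)) {
      halves <- strsplit(branch, "±", fixed = TRUE)[[1]]
      if (length(halves) != 2L) {
        stop(sprintf("cannot parse '±' construct in: '%s'", text),
             call. = FALSE)
      }
      base <- .parse_components(halves[1], text)
      extra <- .parse_components(halves[2], text)
      alts <- c(alts, list(base, c(base, extra)))
    } else {
      alts <- c(alts, list(.parse_components(branch, text)))
    }
  }
  decision_set("options", lapply(alts, function(a) do.call(regimen, as.list(a))))
}

.parse_components <- function(branch, full_text) {
  branch <- gsub("\\band\\b", "+", branch)
  tokens <- trimws(strsplit(branch, "+", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop(sprintf("empty regimen in decision string: '%s'", full_text),
         call. = FALSE)
  }
  comps <- character()
  for (tok in tokens) {
    hit <- unname(.MODALITY_SYNONYMS[tok])
    if (is.na(hit)) {
      stop(sprintf("unrecognized token '%s' in decision string: '%s'",
                   tok, full_text), call. = FALSE)
    }
    comps <- c(comps, strsplit(hit, "+", fixed = TRUE)[[1]])
  }
  unique(comps)
}

#' Cohen's kappa for paired nominal decisions
#'
#' Chance-corrected agreement between two raters (here: the automatic engine
#' and a blinded expert) over the same items. Each distinct canonical
#' decision observed in either column is one nominal category; agreement on
#' an item requires exact equality of the canonical decisions (no partial
#' credit for overlapping option sets). With observed agreement
#' \eqn{p_o} and chance agreement \eqn{p_e = \sum_c p_{1c} p_{2c}} from the
#' two raters' marginals, \eqn{\kappa = (p_o - p_e)/(1 - p_e)}.
#'
#' The degenerate table in which both raters use a single shared category
#' (\eqn{p_e = 1}) has \eqn{\kappa} defined as 1 when agreement is perfect
#' and undefined (an error) otherwise.
#'
#' @param x,y The two raters' decisions over the same items, as lists of
#'   `mdm_decision`s (compared by [decision_key()]) or as character vectors
#'   of category labels. At least 2 items.
#' @return An object of class `agreement_result` with fields `p_observed`,
#'   `p_expected`, `kappa`, `n_items` and the Landis-Koch `label`.
#' @examples
#' cohen_kappa(c("A", "B", "A"), c("A", "B", "B"))
#' @export
cohen_kappa <- function(x, y) {
  x <- .as_labels(x)
  y <- .as_labels(y)
  if (length(x) != length(y)) {
    stop("the two decision columns must have the same length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("at least 2 paired decisions are required", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("decisions must not be missing", call. = FALSE)

  p_o <- mean(x == y)
  cats <- union(x, y)
  p1 <- tabulate(match(x, cats), nbins = length(cats)) / n
  p2 <- tabulate(match(y, cats), nbins = length(cats)) / n
  p_e <- sum(p1 * p2)

  if (p_e >= 1 - 1e-15) {
    if (p_o == 1) {
      kappa <- 1
    } else {
      stop("kappa is undefined: a single shared category with disagreement",
           call. = FALSE)
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
    if (p_o == 1) kappa <- 1  # guard against rounding below exactness
  }
  structure(list(p_observed = p_o, p_expected = p_e, kappa = kappa,
                 n_items = n, label = interpret_kappa(kappa)),
            class = "agreement_result")
}

.as_labels <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "mdm_decision")) x <- list(x)
  if (is.list(x)) {
    return(vapply(x, function(d) {
      if (inherits(d, "mdm_decision")) decision_key(d)
      else if (is.character(d) && length(d) == 1L) d
      else stop("decisions must be mdm_decision objects or label strings",
                call. = FALSE)
    }, character(1)))
  }
  stop("decisions must be mdm_decision objects or label strings", call. = FALSE)
}

#' @export
format.agreement_result <- function(x, ...) {
  sprintf("Cohen's kappa = %.3f (%s); p_o = %.3f, p_e = %.3f, n = %d",
          x$kappa, x$label, x$p_observed, x$p_expected, x$n_items)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: kappa <= 0 "poor"; (0, 0.2] "slight"; (0.2, 0.4] "fair";
#' (0.4, 0.6] "moderate"; (0.6, 0.8] "substantial"; (0.8, 1] "almost perfect".
#'
#' @param kappa A number in \[-1, 1\].
#' @return The interpretation label.
#' @examples
#' interpret_kappa(0.625)
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa < -1 - 1e-12 || kappa > 1 + 1e-12) {
    stop("kappa must be a single number in [-1, 1]", call. = FALSE)
  }
  if (kappa <= 0) "poor"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}
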