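#' Default mapping of cognitive tests to domains
#'
#' Four cognitive domains: verbal learning and memory (Selective Reminding
#' Test triple), visuospatial learning and memory (Spatial Recall Test
#' pair), attention / information-processing speed (Trail Making Test A, B
#' and Symbol Digit Modalities Test), and expressive language (semantic and
#' phonemic fluency). Every test belongs to exactly one domain.
#'
#' @return Named list, domain -> character vector of test names.
#' @export
default_domain_map <- function() {
  list(
    verbal_learning_memory = c("SRT_lts", "SRT_cltr", "SRT_recall"),
    visuospatial_learning_memory = c("SPART", "SPART_recall"),
    attention_processing_speed = c("TMT_A", "TMT_B", "SDMT"),
    expressive_language = c("semantic_fluency", "phonemic_fluency")
  )
}

check_domain_map <- function(map) {
  if (length(map) == 0L || any(lengths(map) == 0L))
    stop("domains must be non-empty")
  tests <- unlist(map, use.names = FALSE)
  if (anyDuplicated(tests))
    stop("each test may appear in exactly one domain")
  invisible(map)
}

#' Z-score raw metric values against scanner-matched healthy controls
#'
#' For each subject, `z = (x - mean(HC on same scanner)) / sd(HC on same
#' scanner)`, with the sample SD (n - 1 denominator). Healthy controls
#' themselves may be passed through the same rule, putting all groups on
#' one scale.
#'
#' @param values named numeric vector, subject -> raw metric value.
#' @param scanner_of named character vector, subject -> scanner id.
#' @param hc_reference named list, scanner -> numeric vector of raw HC
#'   values (>= 2 values, SD > 0).
#' @return `data.frame` with `subject_id` and `z`; attribute `reference` is
#'   `"HC-by-scanner"`.
#' @export
#' @examples
#' zscore_vs_hc(c(p1 = 7), c(p1 = "S1"), list(S1 = c(8, 10, 12)))  # z = -1.5
zscore_vs_hc <- function(values, scanner_of, hc_reference) {
  subj <- names(values)
  if (is.null(subj)) stop("values must be a named vector")
  sc <- scanner_of[subj]
  if (anyNA(sc)) stop("every subject needs a scanner assignment")
  missing_ref <- setdiff(unique(sc), names(hc_reference))
  if (length(missing_ref))
    stop("no HC reference for scanner(s): ", paste(missing_ref, collapse = ", "))
  mu <- vapply(hc_reference, mean, numeric(1))
  sig <- vapply(hc_reference, sd, numeric(1))
  short <- lengths(hc_reference) < 2L
  if (any(short[unique(sc)]))
    stop("HC reference needs >= 2 values per scanner")
  if (any(sig[unique(sc)] <= 0))
    stop("degenerate HC reference: zero SD")
  z <- (values - mu[sc]) / sig[sc]
  structure(data.frame(subject_id = subj, z = unname(z),
                       stringsAsFactors = FALSE),
            reference = "HC-by-scanner")
}

#' Z-score of log lesion volume within the patient cohort
#'
#' T2 lesion volumes are log-transformed (natural log; any base yields the
#' same z after standardization) and standardized against the patient
#' cohort's own mean and sample SD, so the output has mean 0 and SD 1 by
#' construction.
#'
#' @param lv named numeric vector, patient -> lesion volume (mL, > 0).
#' @return `data.frame` with `subject_id` and `z`; attribute `reference` is
#'   `"patient-cohort"`.
#' @export
lesion_volume_z <- function(lv) {
  if (is.null(names(lv))) stop("lv must be a named vector")
  if (any(lv <= 0)) stop("lesion volumes must be > 0")
  loglv <- log(lv)
  s <- sd(loglv)
  if (!is.finite(s) || s == 0)
    stop("degenerate reference: lesion volumes have zero spread")
  structure(data.frame(subject_id = names(lv),
                       z = unname((loglv - mean(loglv)) / s),
                       stringsAsFactors = FALSE),
            reference = "patient-cohort")
}

#' Cognitive domain scores as unweighted means of test z-scores
#'
#' Each domain score is the arithmetic mean of the z-scores of the tests
#' mapped to that domain.
#'
#' @param test_z matrix or data.frame of test z-scores (subjects x tests),
#'   columns named by test.
#' @param map domain map as in [default_domain_map()].
#' @return Numeric matrix, subjects x domains.
#' @export
domain_scores <- function(test_z, map = default_domain_map()) {
  check_domain_map(map)
  test_z <- as.matrix(test_z)
  missing <- setdiff(unlist(map, use.names = FALSE), colnames(test_z))
  if (length(missing))
    stop("missing test column(s): ", paste(missing, collapse = ", "))
  out <- vapply(map, function(tests)
    rowMeans(test_z[, tests, drop = FALSE]), numeric(nrow(test_z)))
  out <- matrix(out, nrow = nrow(test_z),
                dimnames = list(rownames(test_z), names(map)))
  out
}
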