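#' Construct a cluster specification for the cognitive-cohort generator
#'
#' A `cluster_spec` bundles the generative parameters of one planted
#' cognitive phenotype: its size, the per-test mean and SD of the normative
#' z-scores, and covariate distributions (age, proportion of girls,
#' education, EDSS, disease duration, T2 lesion volume).
#'
#' @param name cluster label, e.g. `"PC"`.
#' @param size number of subjects (>= 1).
#' @param test_means named numeric vector, one mean z per test in
#'   [cognitive_tests()].
#' @param test_sds named numeric vector of SDs (> 0), same names.
#' @param covariate_params list with elements `age_mean`, `age_sd`,
#'   `prop_female`, `edu_mean`, `edu_sd`, `edss_mean`, `edss_sd`,
#'   `dd_meanlog`, `dd_sdlog`, `lv_meanlog`, `lv_sdlog`.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(name, size, test_means, test_sds,
                         covariate_params = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(size) || length(size) != 1L || size < 1)
    stop("cluster size must be >= 1")
  tests <- cognitive_tests()
  if (!setequal(names(test_means), tests) || !setequal(names(test_sds), tests))
    stop("test_means and test_sds must be named by the 10 cognitive tests")
  test_means <- test_means[tests]
  test_sds <- test_sds[tests]
  if (any(test_sds <= 0)) stop("all test SDs must be > 0")
  defaults <- list(age_mean = 15.5, age_sd = 1.8, prop_female = 0.67,
                   edu_mean = 9.3, edu_sd = 1.8, edss_mean = 1.2,
                   edss_sd = 0.7, dd_meanlog = 0.35, dd_sdlog = 0.8,
                   lv_meanlog = 1.0, lv_sdlog = 1.0)
  cp <- modifyList(defaults, covariate_params)
  structure(list(name = name, size = as.integer(size),
                 test_means = test_means, test_sds = test_sds,
                 covariate_params = cp),
            class = "cluster_spec")
}

#' Default cluster specifications (three published phenotypes)
#'
#' Per-cluster means and SDs of the 10 test z-scores for the three
#' phenotypes — preserved cognition (PC, n = 27), mild verbal learning and
#' memory / semantic fluency involvement (MVS, n = 28), and multidomain
#' involvement (MI, n = 18) — together with covariate distributions matched
#' to the reported cohort demographics (median age ~15.9 y, 67% girls,
#' median EDSS 1.0-1.5, median disease duration ~1.4 y).
#'
#' @return A named list of three [cluster_spec()] objects.
#' @export
default_cluster_specs <- function() {
  tests <- cognitive_tests()
  mk <- function(m, s) list(means = setNames(m, tests), sds = setNames(s, tests))
  pc <- mk(c(1.0, 0.7, 1.0, 0.4, 0.4, 0.2, 0.2, 0.4, 0.4, 0.3),
           c(0.5, 0.8, 0.5, 1.2, 0.8, 0.7, 0.7, 1.0, 0.8, 1.0))
  mvs <- mk(c(-0.4, -0.7, -0.5, 0.6, 0.5, 0.1, 0.2, 0.0, -0.3, 0.0),
            c(0.8, 0.7, 1.0, 0.8, 0.7, 0.7, 0.7, 0.6, 0.4, 0.7))
  mi <- mk(c(-1.2, -1.2, -1.2, -1.8, -2.0, -0.9, -1.2, -0.5, -0.6, -0.2),
           c(1.1, 1.0, 1.3, 2.0, 1.6, 1.0, 1.5, 0.6, 0.5, 1.2))
  list(
    PC = cluster_spec("PC", 27, pc$means, pc$sds,
                      list(prop_female = 0.78, edss_mean = 0.9)),
    MVS = cluster_spec("MVS", 28, mvs$means, mvs$sds,
                       list(prop_female = 0.61, edss_mean = 1.1)),
    MI = cluster_spec("MI", 18, mi$means, mi$sds,
                      list(prop_female = 0.61, edss_mean = 1.6))
  )
}

edss_grid <- function(x) pmin(pmax(round(x * 2) / 2, 0), 6.5)

#' Generate a synthetic patient cohort with planted cognitive phenotypes
#'
#' Draws, for each [cluster_spec()], `size` patients whose 10 test z-scores
#' come from a multivariate normal with the spec's marginal means/SDs.
#' Cross-test correlation defaults to 0 (independent normals); a common
#' correlation matrix can be supplied for robustness experiments.
#' Demographics, scanner assignment (Bernoulli `p_scanner1` for scanner S1),
#' EDSS (on the 0.5-point ordinal grid), disease duration, and raw T2 lesion
#' volume (lognormal, mL) are drawn per the spec's covariate parameters.
#'
#' @param cluster_specs list of [cluster_spec()]; default
#'   [default_cluster_specs()].
#' @param seed integer seed; the draw is fully reproducible.
#' @param cross_corr optional 10 x 10 cross-test correlation matrix
#'   (default identity).
#' @param p_scanner1 probability a patient is scanned on scanner S1
#'   (default 0.75, the published patient split 55/17).
#' @return A `data.frame` with one row per patient: `subject_id`, `group`
#'   (`"patient"`), `scanner` (`"S1"`/`"S2"`), `age`, `sex`, `education`,
#'   `EDSS`, `disease_duration`, `lesion_volume_ml`, `planted_cluster`,
#'   and one column per cognitive test.
#' @export
#' @examples
#' cohort <- generate_cognitive_cohort(seed = 1)
#' table(cohort$planted_cluster)
generate_cognitive_cohort <- function(cluster_specs = default_cluster_specs(),
                                      seed, cross_corr = NULL,
                                      p_scanner1 = 0.75) {
  if (length(cluster_specs) == 0L) stop("cluster_specs must be non-empty")
  lapply(cluster_specs, function(s)
    if (!inherits(s, "cluster_spec")) stop("all specs must be cluster_spec"))
  tests <- cognitive_tests()
  p <- length(tests)
  if (is.null(cross_corr)) cross_corr <- diag(p)
  stopifnot(nrow(cross_corr) == p, ncol(cross_corr) == p)
  with_seed(seed, {
    rows <- lapply(cluster_specs, function(spec) {
      n <- spec$size
      S <- diag(spec$test_sds) %*% cross_corr %*% diag(spec$test_sds)
      z <- MASS::mvrnorm(n, mu = spec$test_means, Sigma = S)
      z <- matrix(z, nrow = n, dimnames = list(NULL, tests))
      cp <- spec$covariate_params
      df <- data.frame(
        group = "patient",
        scanner = ifelse(rbinom(n, 1, p_scanner1) == 1, "S1", "S2"),
        age = round(rnorm(n, cp$age_mean, cp$age_sd), 1),
        sex = ifelse(runif(n) < cp$prop_female, "F", "M"),
        education = pmax(round(rnorm(n, cp$edu_mean, cp$edu_sd)), 5),
        EDSS = edss_grid(rnorm(n, cp$edss_mean, cp$edss_sd)),
        disease_duration = round(rlnorm(n, cp$dd_meanlog, cp$dd_sdlog), 2),
        lesion_volume_ml = round(rlnorm(n, cp$lv_meanlog, cp$lv_sdlog), 3),
        planted_cluster = spec$name,
        stringsAsFactors = FALSE
      )
      cbind(df, as.data.frame(z))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out <- cbind(subject_id = sprintf("P%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    out
  })
}

#' Generate a healthy-control reference sample per scanner
#'
#' Draws raw MRI-metric values for healthy controls on each scanner, to
#' serve as the reference distribution for scanner-wise z-scoring of
#' patient metrics.
#'
#' @param n_per_scanner named integer vector, scanner -> count (each >= 3).
#'   Default `c(S1 = 21, S2 = 9)`, the published HC split.
#' @param metric_params named list, metric -> `c(mean, sd)`. Default: five
#'   normalized brain-volume metrics on arbitrary raw scales.
#' @param seed integer seed.
#' @return `data.frame` of HC rows: `subject_id`, `group` (`"HC"`),
#'   `scanner`, `age`, `sex`, `education`, plus one raw column per metric.
#' @export
generate_hc_reference <- function(n_per_scanner = c(S1 = 21, S2 = 9),
                                  metric_params = list(
                                    n_brain_volume = c(1450, 60),
                                    n_wm_volume = c(680, 40),
                                    n_cgm_volume = c(620, 35),
                                    n_hippocampal_volume = c(8.2, 0.6),
                                    n_thalamic_volume = c(16.0, 1.1)),
                                  seed) {
  if (any(n_per_scanner < 3)) stop("each scanner needs >= 3 HCs")
  if (is.null(names(n_per_scanner))) stop("n_per_scanner must be named")
  with_seed(seed, {
    rows <- lapply(names(n_per_scanner), function(sc) {
      n <- n_per_scanner[[sc]]
      df <- data.frame(
        group = "HC", scanner = sc,
        age = round(rnorm(n, 15.2, 2.5), 1),
        sex = ifelse(runif(n) < 0.5, "F", "M"),
        education = pmax(round(rnorm(n, 8.7, 2.0)), 5),
        stringsAsFactors = FALSE
      )
      for (m in names(metric_params)) {
        pm <- metric_params[[m]]
        df[[m]] <- rnorm(n, pm[1], pm[2])
      }
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    cbind(subject_id = sprintf("HC%03d", seq_len(nrow(out))), out,
          stringsAsFactors = FALSE)
  })
}
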