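#' Default planted MRI-metric z-shifts per phenotype
#'
#' Planted group means, in healthy-control SD units, of the five normalized
#' brain-volume metrics for the three phenotypes — the published marginal
#' pattern of graded atrophy (preserved cognition near HC, multidomain
#' involvement most atrophic).
#'
#' @return metric x phenotype numeric matrix.
#' @export
default_mri_shifts <- function() {
  m <- rbind(
    n_brain_volume = c(PC = -0.4, MVS = -0.6, MI = -1.4),
    n_wm_volume = c(PC = 0.0, MVS = 0.0, MI = -1.1),
    n_cgm_volume = c(PC = -0.4, MVS = -0.6, MI = -1.0),
    n_hippocampal_volume = c(PC = -0.1, MVS = -0.2, MI = -0.5),
    n_thalamic_volume = c(PC = -0.4, MVS = -0.5, MI = -1.2))
  m
}

#' Draw raw MRI metrics for patients with planted phenotype shifts
#'
#' For each patient, each metric is drawn `Normal(mu_m + shift * sd_m,
#' sd_m)` where `(mu_m, sd_m)` are the healthy-control generative
#' parameters and `shift` is the planted z-shift of the patient's
#' phenotype. Patients of unknown phenotype get shift 0.
#'
#' @param cohort a [generate_cognitive_cohort()] table.
#' @param metric_params named list metric -> `c(mean, sd)` (same defaults
#'   as [generate_hc_reference()]).
#' @param shifts metric x phenotype matrix (default
#'   [default_mri_shifts()]).
#' @param seed integer seed.
#' @return The cohort with one added raw column per metric.
#' @export
generate_patient_mri <- function(cohort,
                                 metric_params = list(
                                   n_brain_volume = c(1450, 60),
                                   n_wm_volume = c(680, 40),
                                   n_cgm_volume = c(620, 35),
                                   n_hippocampal_volume = c(8.2, 0.6),
                                   n_thalamic_volume = c(16.0, 1.1)),
                                 shifts = default_mri_shifts(), seed) {
  with_seed(seed, {
    n <- nrow(cohort)
    for (m in names(metric_params)) {
      pm <- metric_params[[m]]
      sh <- rep(0, n)
      if (m %in% rownames(shifts)) {
        known <- cohort$planted_cluster %in% colnames(shifts)
        sh[known] <- shifts[m, cohort$planted_cluster[known]]
      }
      cohort[[m]] <- rnorm(n, pm[1] + sh * pm[2], pm[2])
    }
    cohort
  })
}

#' Build and validate a pipeline configuration
#'
#' One configuration object drives the full pipeline; every stage draws
#' its randomness from a named substream of `master_seed`
#' ([substream_seed()]), so any stage can be rerun independently.
#'
#' @param master_seed integer master seed.
#' @param cluster_specs phenotype generative specs
#'   ([default_cluster_specs()]).
#' @param p_scanner1 patient probability of scanner S1 (default 0.75).
#' @param hc_n named HC counts per scanner (default `c(S1 = 21, S2 = 9)`).
#' @param k_range candidate cluster numbers (default 2:8).
#' @param panel validity-index panel (default: all nine).
#' @param restarts K-means restarts (default 50).
#' @param n_regions,streamlines_per_pair,lesion_fraction toy-world
#'   parameters.
#' @param n_timepoints,tau,band BOLD length, correlation threshold, and
#'   band-pass edges in Hz.
#' @param fc_loading factor loading of the planted within-network BOLD
#'   signal (default 1).
#' @param fdr_q,fdr_family FDR level and family policy (see
#'   [compare_metrics()]).
#' @param out_dir output directory for [run_pipeline()].
#' @return Object of class `cogphen_config`.
#' @export
cogphen_config <- function(master_seed = 1,
                           cluster_specs = default_cluster_specs(),
                           p_scanner1 = 0.75,
                           hc_n = c(S1 = 21, S2 = 9),
                           k_range = 2:8,
                           panel = validity_indices()$name,
                           restarts = 50,
                           n_regions = 20, streamlines_per_pair = 5,
                           lesion_fraction = 0.1,
                           n_timepoints = 128, tau = 0,
                           band = c(0.01, 0.1),
                           fc_loading = 1,
                           fdr_q = 0.05, fdr_family = "per-table",
                           out_dir = tempfile("cogphen_run_")) {
  cfg <- list(master_seed = as.integer(master_seed),
              cluster_specs = cluster_specs, p_scanner1 = p_scanner1,
              hc_n = hc_n, k_range = as.integer(k_range), panel = panel,
              restarts = as.integer(restarts),
              n_regions = as.integer(n_regions),
              streamlines_per_pair = as.integer(streamlines_per_pair),
              lesion_fraction = lesion_fraction,
              n_timepoints = as.integer(n_timepoints), tau = tau,
              band = band, fc_loading = fc_loading, fdr_q = fdr_q,
              fdr_family = fdr_family, out_dir = out_dir)
  stopifnot(cfg$lesion_fraction >= 0, cfg$lesion_fraction <= 1,
            length(cfg$band) == 2L, cfg$band[1] > 0,
            cfg$band[1] < cfg$band[2], cfg$fdr_q > 0, cfg$fdr_q < 1,
            all(cfg$panel %in% validity_indices()$name))
  structure(cfg, class = "cogphen_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML document override [cogphen_config()]
#' defaults; the domain map and cluster specs retain their defaults.
#'
#' @param path YAML file.
#' @return A `cogphen_config`.
#' @export
cogphen_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(cogphen_config)), "cluster_specs")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$hc_n)) raw$hc_n <- unlist(raw$hc_n)
  if (!is.null(raw$k_range) && is.character(raw$k_range)) {
    kr <- as.integer(strsplit(raw$k_range, ":")[[1L]])
    raw$k_range <- seq.int(kr[1L], kr[2L])
  }
  do.call(cogphen_config, raw)
}

#' Run the full phenotyping pipeline
#'
#' Orchestrates simulate -> normalize -> cluster -> disconnect -> fc ->
#' stats from one configuration: generates the patient cohort, HC
#' reference, toy lesion world and ROI BOLD series; z-scores MRI metrics
#' against scanner-matched HCs and log lesion volume within patients;
#' selects k by consensus and labels phenotypes (for k = 3); scores
#' structural disconnection per network; computes HC-referenced network
#' degree z-scores; and emits FDR-corrected comparison tables. All numeric
#' outputs are written as TSV/JSON under `config$out_dir` together with a
#' manifest; the run is deterministic given the master seed.
#'
#' @param config a [cogphen_config()].
#' @return Invisibly, a list with all stage results (`cohort`, `hc`,
#'   `zscores`, `consensus`, `model`, `labeling`, `disconnection`,
#'   `fc_degree`, `comparisons`, `manifest`).
#' @export
run_pipeline <- function(config = cogphen_config()) {
  stopifnot(inherits(config, "cogphen_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  ms <- config$master_seed
  stages <- character(0)

  # -- stage 1: simulate -----------------------------------------------------
  cohort <- generate_cognitive_cohort(config$cluster_specs,
                                      seed = substream_seed(ms, "cohort"),
                                      p_scanner1 = config$p_scanner1)
  cohort <- generate_patient_mri(cohort, seed = substream_seed(ms, "mri"))
  hc <- generate_hc_reference(config$hc_n, seed = substream_seed(ms, "hc"))
  world <- generate_toy_world(config$n_regions, config$streamlines_per_pair,
                              config$lesion_fraction,
                              n_subjects = nrow(cohort),
                              seed = substream_seed(ms, "world"))
  names(world$lesion_masks) <- cohort$subject_id
  write_tsv(cohort, out("cohort.tsv"))
  write_tsv(hc, out("hc_reference.tsv"))
  write_streamlines_jsonl(world, out("streamlines.jsonl"))
  stages <- c(stages, "simulate")

  # -- stage 2: normalize ----------------------------------------------------
  metrics <- rownames(default_mri_shifts())
  scanner_of <- setNames(c(cohort$scanner, hc$scanner),
                         c(cohort$subject_id, hc$subject_id))
  zs <- data.frame(subject_id = c(cohort$subject_id, hc$subject_id),
                   group = c(rep("patient", nrow(cohort)),
                             rep("HC", nrow(hc))),
                   stringsAsFactors = FALSE)
  for (m in metrics) {
    vals <- setNames(c(cohort[[m]], hc[[m]]), zs$subject_id)
    ref <- split(hc[[m]], hc$scanner)
    zs[[paste0("z_", m)]] <- zscore_vs_hc(vals, scanner_of, ref)$z
  }
  lvz <- lesion_volume_z(setNames(cohort$lesion_volume_ml, cohort$subject_id))
  zs$z_t2_lesion_volume <- lvz$z[match(zs$subject_id, lvz$subject_id)]
  write_tsv(zs, out("zscores.tsv"))
  stages <- c(stages, "normalize")

  # -- stage 3: cluster ------------------------------------------------------
  test_z <- as.matrix(cohort[, cognitive_tests()])
  consensus <- consensus_k(test_z, k_range = config$k_range,
                           panel = config$panel,
                           restarts = config$restarts,
                           seed = substream_seed(ms, "kmeans"))
  model <- consensus$fits[[as.character(consensus$winner)]]
  labeling <- if (model$k == 3L) label_phenotypes(model) else NULL
  dom <- domain_scores(test_z)
  labels_df <- data.frame(subject_id = cohort$subject_id,
                          cluster = model$labels,
                          phenotype = if (is.null(labeling)) NA_character_
                                      else labeling$subject_labels,
                          planted_cluster = cohort$planted_cluster,
                          dom, stringsAsFactors = FALSE)
  write_tsv(labels_df, out("labels.tsv"))
  write_matrix_tsv(model$centroids, out("centroids.tsv"), "cluster")
  jsonlite::write_json(
    list(k_range = consensus$k_range,
         index_votes = as.list(consensus$index_votes),
         winner = consensus$winner, vote_count = consensus$vote_count,
         vote_fraction = consensus$vote_fraction),
    out("consensus.json"), auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "cluster")

  # -- stage 4: disconnect ---------------------------------------------------
  disc <- cohort_disconnection(world$lesion_masks, world)
  write_tsv(disc, out("disconnection.tsv"))
  stages <- c(stages, "disconnect")

  # -- stage 5: fc -----------------------------------------------------------
  net_labels <- unname(world$network_labels)
  all_ids <- c(cohort$subject_id, hc$subject_id)
  Sigma <- Reduce(`+`, lapply(yeo7_networks(), function(net)
    factor_covariance(config$n_regions, which(net_labels == net),
                      loading = config$fc_loading)))
  fc_rows <- lapply(all_ids, function(id) {
    bold <- generate_bold(config$n_regions, Sigma,
                          n_timepoints = config$n_timepoints,
                          seed = substream_seed(ms, paste0("bold-", id)))
    fc_profile(bold, net_labels, tau = config$tau,
               low = config$band[1], high = config$band[2])$network_degree
  })
  fc_deg <- as.data.frame(do.call(rbind, fc_rows))
  fc_deg <- cbind(subject_id = all_ids,
                  group = c(rep("patient", nrow(cohort)),
                            rep("HC", nrow(hc))),
                  fc_deg, stringsAsFactors = FALSE)
  hc_rows <- fc_deg$group == "HC"
  for (net in yeo7_networks()) {
    vals <- setNames(fc_deg[[net]], fc_deg$subject_id)
    ref <- split(fc_deg[[net]][hc_rows], scanner_of[fc_deg$subject_id[hc_rows]])
    fc_deg[[paste0("z_", net)]] <- zscore_vs_hc(vals, scanner_of, ref)$z
  }
  write_tsv(fc_deg, out("fc_network_degree.tsv"))
  stages <- c(stages, "fc")

  # -- stage 6: stats --------------------------------------------------------
  grp <- rep("HC", length(all_ids))
  grp[seq_len(nrow(cohort))] <- if (is.null(labeling))
    paste0("C", model$labels) else labeling$subject_labels
  stat_df <- data.frame(subject_id = all_ids, group = grp,
                        age = c(cohort$age, hc$age),
                        sex = c(cohort$sex, hc$sex),
                        stringsAsFactors = FALSE)
  for (m in paste0("z_", metrics))
    stat_df[[m]] <- zs[[m]][match(stat_df$subject_id, zs$subject_id)]
  for (net in paste0("z_", yeo7_networks()))
    stat_df[[net]] <- fc_deg[[net]][match(stat_df$subject_id,
                                          fc_deg$subject_id)]
  mri_cmp <- compare_metrics(stat_df,
                             c(paste0("z_", metrics),
                               paste0("z_", yeo7_networks())),
                             q = config$fdr_q, family = config$fdr_family)
  disc_df <- data.frame(subject_id = disc$subject_id,
                        group = grp[match(disc$subject_id, all_ids)],
                        age = cohort$age[match(disc$subject_id,
                                               cohort$subject_id)],
                        sex = cohort$sex[match(disc$subject_id,
                                               cohort$subject_id)],
                        disc[, yeo7_networks()],
                        stringsAsFactors = FALSE)
  disc_cmp <- compare_metrics(disc_df, yeo7_networks(),
                              q = config$fdr_q, family = config$fdr_family)
  write_tsv(mri_cmp$contrasts, out("comparisons_mri_fc.tsv"))
  write_tsv(mri_cmp$emmeans, out("emmeans_mri_fc.tsv"))
  write_tsv(disc_cmp$contrasts, out("comparisons_disconnection.tsv"))
  stages <- c(stages, "stats")

  manifest <- list(package = "cogphen",
                   version = as.character(utils::packageVersion("cogphen")),
                   master_seed = ms, stages = stages,
                   n_patients = nrow(cohort), n_hc = nrow(hc),
                   winner_k = consensus$winner,
                   files = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(cohort = cohort, hc = hc, zscores = zs,
                 consensus = consensus, model = model, labeling = labeling,
                 disconnection = disc, fc_degree = fc_deg,
                 comparisons = list(mri_fc = mri_cmp,
                                    disconnection = disc_cmp),
                 manifest = manifest, world = world))
}
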