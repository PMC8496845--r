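#' Pipeline configuration
#'
#' One structured configuration for the full design - simulate - quantify
#' - stats - model pipeline. All classification thresholds are explicit
#' and echoed into the run log: junction positive threshold 0.8, cryptic
#' normalized-score threshold 0.7 with its comparison direction, mismatch
#' bound 6 (strict), per-variant read floor 10, DNA artifact threshold
#' 0.05, cryptic reporting floor 0.01. The global seed fans out to
#' per-stage sub-seeds via [derive_seed()].
#'
#' @param seed Global seed (mandatory for every stochastic stage).
#' @param library Arguments for [build_library()].
#' @param truth Arguments for [simulate_ground_truth()].
#' @param n_reads_rna,n_reads_dna,error_rate Simulation settings.
#' @param junction_threshold,cryptic_score_threshold,cryptic_score_cmp,cryptic_max_mismatch
#'   Classification thresholds.
#' @param min_reads,dna_threshold,cryptic_floor Filtering thresholds.
#' @param model_cfg A [model_config()].
#' @param run_model Fit the splicing-efficiency model stage.
#' @param run_avoidance Run the avoidance statistic on a simulated
#'   depleted genome.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            library = list(n_combinatorial = 60L,
                                           n_negative = 8L, n_natural = 10L,
                                           two_intron_pool = 3L),
                            truth = list(), n_reads_rna = 40000L,
                            n_reads_dna = 10000L, error_rate = 0.001,
                            junction_threshold = 0.8,
                            cryptic_score_threshold = 0.7,
                            cryptic_score_cmp = "lt",
                            cryptic_max_mismatch = 6,
                            min_reads = 10L, dna_threshold = 0.05,
                            cryptic_floor = 0.01,
                            model_cfg = model_config(n_boot = 200L),
                            run_model = TRUE, run_avoidance = TRUE) {
  if (missing(seed)) stop("a global seed is mandatory")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline into an output directory
#'
#' Stages: library design, ground-truth draw, read simulation (2 RNA
#' repeats + DNA control), quantification, summary statistics (designed /
#' cryptic SE, abundance correlation, randomized control, avoidance test
#' on a simulated motif-depleted genome), and the predictive model on the
#' simulated single-intron variants with their true designed fractions as
#' targets. Writes TSV tables, a run log, and a machine-readable
#' `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; all artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("splicelib_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  log_line("seed=%d", config$seed)
  for (k in c("junction_threshold", "cryptic_score_threshold",
              "cryptic_score_cmp", "cryptic_max_mismatch", "min_reads",
              "dna_threshold", "cryptic_floor", "error_rate"))
    log_line("%s=%s", k, as.character(config[[k]]))

  manifest <- do.call(build_library,
                      c(config$library, list(seed = derive_seed(config$seed, "design"))))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"),
                 fasta = file.path(out_dir, "library.fasta"))
  log_line("designed %d variants", nrow(manifest))

  truth <- do.call(simulate_ground_truth,
                   c(list(manifest = manifest,
                          seed = derive_seed(config$seed, "truth")),
                     config$truth))
  utils::write.table(truth$isoforms, file.path(out_dir, "truth_isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sim <- simulate_experiment(manifest, truth, config$n_reads_rna,
                             config$n_reads_dna, error_rate = config$error_rate,
                             seed = derive_seed(config$seed, "reads"))
  log_line("simulated %d reads", nrow(sim$reads))

  q <- quantify_experiment(sim$reads, manifest,
                           min_reads = config$min_reads,
                           cryptic_floor = config$cryptic_floor,
                           dna_threshold = config$dna_threshold,
                           junction_threshold = config$junction_threshold,
                           cryptic_score_threshold = config$cryptic_score_threshold,
                           cryptic_max_mismatch = config$cryptic_max_mismatch,
                           cryptic_score_cmp = config$cryptic_score_cmp)
  utils::write.table(q$se, file.path(out_dir, "splicing_efficiency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(q$abundance))
    utils::write.table(q$abundance, file.path(out_dir, "abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  se_designed <- q$se[q$se$isoform == "designed" & !q$se$low_reads, ]
  single_ids <- manifest$variant_id[!is.na(manifest$i1_start) &
                                      is.na(manifest$i2_start) &
                                      manifest$subset != "negative_control"]
  sd_single <- se_designed[se_designed$variant_id %in% single_ids, ]
  frac_spliced <- mean(sd_single$se > 0, na.rm = TRUE)
  median_se <- stats::median(sd_single$se[sd_single$se > 0], na.rm = TRUE)
  cryptic_rows <- q$se[startsWith(q$se$isoform, "cryptic:"), ]
  frac_cryptic <- length(unique(cryptic_rows$variant_id)) /
    max(1L, length(single_ids))

  ab_cor <- NA_real_
  if (!is.null(q$abundance)) {
    tot_se <- tapply(q$se$se[!q$se$isoform %in%
                               c("unspliced", "undetermined", "unclassified")],
                     q$se$variant_id[!q$se$isoform %in%
                                       c("unspliced", "undetermined", "unclassified")],
                     sum)
    m <- match(names(tot_se), q$abundance$variant_id)
    ok <- !is.na(m) & !is.na(q$abundance$abundance[m]) & !is.na(tot_se)
    if (sum(ok) >= 3)
      ab_cor <- stats::cor(tot_se[ok], q$abundance$abundance[m][ok])
  }

  ctrl <- randomized_abundance_control(seed = derive_seed(config$seed, "ctrl"))

  avoidance <- NULL
  if (config$run_avoidance) {
    g <- simulate_genome(n_introns = 60L, mode = "depleted",
                         seed = derive_seed(config$seed, "genome"))
    avoidance <- avoidance_test(g$genome, g$introns, g$cds,
                                n_controls = 2000L,
                                seed = derive_seed(config$seed, "avoid"))
  }

  model_r <- NA_real_
  if (config$run_model) {
    fm <- extract_feature_matrix(manifest)
    fm <- fm[fm$variant_id %in% single_ids, ]
    des <- truth$isoforms[truth$isoforms$isoform == "designed", ]
    y <- des$fraction[match(fm$variant_id, des$variant_id)]
    y[is.na(y)] <- 0
    if (nrow(fm) >= 40) {
      mdl <- train_cv(fm, y, config$model_cfg,
                      seed = derive_seed(config$seed, "model"))
      model_r <- mdl$r
    }
  }

  summary <- list(n_variants = nrow(manifest),
                  n_reads = nrow(sim$reads),
                  fraction_spliced = frac_spliced,
                  median_se_designed = median_se,
                  fraction_with_cryptic = frac_cryptic,
                  abundance_se_correlation = ab_cor,
                  randomized_control_p = ctrl$p_value,
                  avoidance_p_upstream = if (is.null(avoidance)) NA else
                    avoidance$p_upstream,
                  avoidance_p_downstream = if (is.null(avoidance)) NA else
                    avoidance$p_downstream,
                  model_test_r = model_r)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(c(summary, list(out_dir = out_dir, se = q$se,
                            manifest = manifest, truth = truth)))
}
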