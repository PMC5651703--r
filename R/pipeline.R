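# Pipeline orchestration: simulate -> count -> activity -> allelic ->
# enrichment as one reproducible run driven by a plain-text (YAML) config,
# with a run log and a consistency-checked run report.

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage derives its randomness from it.
#' @param stages Named logical list enabling stages: `simulate`, `count`,
#'   `activity`, `allelic`, `enrich`.
#' @param sim A [sim_config()] (or list of its arguments) for the simulate
#'   stage; its seed is overridden by `seed`.
#' @param emit_fragments Passed to [simulate_dataset()]; when `TRUE` the
#'   count stage re-derives matrices from fragment records.
#' @param panel_file,counts_file,allele_counts_file,fragments_file,peaks_file
#'   Input paths used by stages whose upstream stage is disabled.
#' @param min_len,max_len,min_base_quality Fragment filters.
#' @param activity_fdr,min_base_mean Activity-calling thresholds.
#' @param allelic_fdr,min_pooled Allelic-test thresholds.
#' @param annotation_or,annotation_baseline Planted odds ratio and baseline
#'   in-peak rate when the enrich stage simulates its own peaks.
#' @return A `starr_run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       stages = list(),
                       sim = sim_config(),
                       emit_fragments = FALSE,
                       panel_file = NULL, counts_file = NULL,
                       allele_counts_file = NULL, fragments_file = NULL,
                       peaks_file = NULL,
                       min_len = 400, max_len = 600, min_base_quality = 20,
                       activity_fdr = 0.01, min_base_mean = 10,
                       allelic_fdr = 0.1, min_pooled = 10,
                       annotation_or = 3, annotation_baseline = 0.05) {
  check_number(seed, "seed", integerish = TRUE)
  defaults <- list(simulate = TRUE, count = TRUE, activity = TRUE,
                   allelic = TRUE, enrich = TRUE)
  stages <- modifyList(defaults, as.list(stages))
  if (is.list(sim) && !inherits(sim, "starr_sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  sim$seed <- as.integer(seed)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages, sim = sim,
    emit_fragments = isTRUE(emit_fragments),
    panel_file = panel_file, counts_file = counts_file,
    allele_counts_file = allele_counts_file, fragments_file = fragments_file,
    peaks_file = peaks_file,
    min_len = min_len, max_len = max_len, min_base_quality = min_base_quality,
    activity_fdr = activity_fdr, min_base_mean = min_base_mean,
    allelic_fdr = allelic_fdr, min_pooled = min_pooled,
    annotation_or = annotation_or, annotation_baseline = annotation_baseline
  )
  structure(cfg, class = "starr_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the arguments of [run_config()]; `sim:` is a mapping of
#' [sim_config()] arguments.
#'
#' @param path YAML config path.
#' @return A `starr_run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

run_log <- function(con, msg) {
  inform(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full screening pipeline
#'
#' Executes the enabled stages in dependency order. Before any computation,
#' every input file a disabled-upstream stage needs is checked to exist (an
#' error names the missing path). Identical config and seed give
#' byte-identical outputs. Stage tables, the resolved config, a run log and
#' a run report are written under `config$out_dir`.
#'
#' @param config A `starr_run_config` from [run_config()] or
#'   [read_run_config()].
#' @return A `starr_run` list: `report` plus the in-memory stage results
#'   (`dataset`, `counts`, `allele_counts`, `activity`, `allelic`,
#'   `enrichment`).
#' @export
run_all <- function(config) {
  if (!inherits(config, "starr_run_config")) {
    abort("`config` must be created with run_config() or read_run_config().")
  }
  st <- config$stages
  # Validate referenced inputs before touching anything.
  require_input <- function(nm) {
    path <- config[[nm]]
    if (is.null(path)) {
      abort(sprintf("`%s` is required when the simulate stage is disabled.", nm))
    }
    if (!file.exists(path)) {
      abort(sprintf("Input file for `%s` does not exist: %s", nm, path))
    }
  }
  if (!st$simulate) {
    require_input("panel_file")
    if (st$count && is.null(config$fragments_file)) {
      require_input("counts_file")
      require_input("allele_counts_file")
    }
  }
  if (!is.null(config$peaks_file) && !file.exists(config$peaks_file)) {
    abort(sprintf("Input file for `peaks_file` does not exist: %s",
                  config$peaks_file))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  n_warnings <- 0L
  result <- withCallingHandlers(
    run_all_impl(config, con),
    warning = function(w) {
      n_warnings <<- n_warnings + 1L
      writeLines(paste("WARNING:", conditionMessage(w)), con)
      invokeRestart("muffleWarning")
    }
  )
  result$report$warnings <- n_warnings
  yaml::write_yaml(result$report, file.path(config$out_dir, "report.yaml"))
  run_log(con, sprintf("Run complete: %d warning(s).", n_warnings))
  result
}

run_all_impl <- function(config, con) {
  st <- config$stages
  report <- list(seed = config$seed, stages_run = names(which(unlist(st))))
  dataset <- NULL
  panel <- NULL
  counts <- NULL
  allele_counts <- NULL
  fragments <- NULL
  peaks <- NULL

  if (st$simulate) {
    run_log(con, "stage simulate: generating synthetic screen")
    dataset <- simulate_dataset(config$sim, emit_fragments = config$emit_fragments)
    panel <- dataset$panel
    counts <- dataset$counts
    allele_counts <- dataset$allele_counts
    fragments <- dataset$fragments
    write_panel(panel, file.path(config$out_dir, "panel.tsv"))
    write_pool(dataset$pool, file.path(config$out_dir, "pool.tsv"))
    write_starr_tsv(dataset$truth, file.path(config$out_dir, "truth.tsv"),
                    meta = c(nb_dispersion = config$sim$nb_dispersion,
                             seed = config$seed))
    if (!is.null(fragments)) {
      write_starr_tsv(fragments, file.path(config$out_dir, "fragments.tsv"))
    }
    report$simulate <- list(
      snps = nrow(panel),
      planted_pre = sum(dataset$truth$class == "PRE"),
      planted_nre = sum(dataset$truth$class == "NRE"),
      planted_allelic = sum(dataset$truth$allelic_effect != 1)
    )
  } else {
    panel <- read_panel(config$panel_file)
    if (!is.null(config$fragments_file)) {
      fragments <- read_starr_tsv(config$fragments_file)
    }
  }

  if (st$count) {
    if (!is.null(fragments)) {
      run_log(con, "stage count: filtering fragments and counting")
      kept <- load_fragments(fragments, panel,
                             min_len = config$min_len, max_len = config$max_len,
                             min_base_quality = config$min_base_quality)
      mats <- count_matrices(kept, panel)
      counts <- mats$counts
      allele_counts <- mats$allele_counts
      report$count <- as.list(attr(kept, "starr_filter_stats"))
    } else if (is.null(counts)) {
      run_log(con, "stage count: loading count tables")
      counts <- read_starr_tsv(config$counts_file)
      allele_counts <- read_starr_tsv(config$allele_counts_file)
    }
    write_starr_tsv(counts, file.path(config$out_dir, "region_counts.tsv"))
    write_starr_tsv(allele_counts, file.path(config$out_dir, "allele_counts.tsv"))
  }

  activity <- NULL
  if (st$activity) {
    run_log(con, "stage activity: NB Wald test and PRE/NRE classification")
    activity <- call_activity(counts, fdr_alpha = config$activity_fdr,
                              min_base_mean = config$min_base_mean)
    write_starr_tsv(activity, file.path(config$out_dir, "activity.tsv"),
                    meta = c(fdr = config$activity_fdr,
                             min_base_mean = config$min_base_mean))
    g <- glance(activity)
    report$activity <- as.list(g[, c("regions", "filtered", "tested",
                                     "pre", "nre", "inactive")])
  }

  allelic <- NULL
  if (st$allelic) {
    run_log(con, "stage allelic: pooling and Fisher exact tests")
    pooled <- pooled_allele_table(allele_counts, min_pooled = config$min_pooled)
    allelic <- allelic_test(pooled, activity = activity,
                            fdr_alpha = config$allelic_fdr)
    write_starr_tsv(allelic, file.path(config$out_dir, "allelic.tsv"),
                    meta = c(fdr = config$allelic_fdr,
                             min_pooled = config$min_pooled))
    report$allelic <- c(
      as.list(attr(pooled, "starr_pool_stats")),
      list(regulatory = sum(allelic$regulatory))
    )
  }

  enrichment <- NULL
  if (st$enrich && !is.null(activity)) {
    run_log(con, "stage enrich: peak overlap enrichment")
    if (!is.null(config$peaks_file)) {
      peaks <- read_bed(config$peaks_file)
    } else if (!is.null(dataset)) {
      peaks <- simulate_annotations(panel, dataset$truth,
                                    target_or = config$annotation_or,
                                    baseline_rate = config$annotation_baseline,
                                    seed = derive_seed(config$seed, 7L))
      write_bed(peaks, file.path(config$out_dir, "peaks.bed"))
    }
    if (!is.null(peaks)) {
      snps <- dplyr::inner_join(
        dplyr::select(panel, "snp_id", "chrom", "pos"),
        dplyr::select(as_tibble(activity), "snp_id", "class"),
        by = "snp_id"
      )
      if (any(snps$class %in% c("PRE", "NRE")) && any(snps$class == "inactive")) {
        enrichment <- overlap_enrichment(snps, peaks,
                                         test_class = c("PRE", "NRE"),
                                         reference_class = "inactive")
        write_starr_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
        report$enrich <- list(odds_ratio = enrichment$odds_ratio,
                              p_value = enrichment$p_value)
      } else {
        run_log(con, "stage enrich: skipped (no called elements to compare)")
      }
    }
  }

  cfg_echo <- config
  cfg_echo$sim <- unclass(cfg_echo$sim)
  yaml::write_yaml(unclass(cfg_echo), file.path(config$out_dir, "config_resolved.yaml"))

  structure(list(report = report, dataset = dataset, counts = counts,
                 allele_counts = allele_counts, activity = activity,
                 allelic = allelic, enrichment = enrichment,
                 out_dir = config$out_dir),
            class = "starr_run")
}

#' @export
print.starr_run <- function(x, ...) {
  cat("Reporter screen pipeline run\n")
  cat(sprintf("  output: %s\n", x$out_dir))
  if (!is.null(x$report$activity)) {
    a <- x$report$activity
    cat(sprintf("  activity: %s regions -> %s PRE, %s NRE, %s inactive, %s filtered\n",
                a$regions, a$pre, a$nre, a$inactive, a$filtered))
  }
  if (!is.null(x$report$allelic)) {
    cat(sprintf("  allelic: %s SNPs tested, %s regulatory\n",
                x$report$allelic$snps_kept, x$report$allelic$regulatory))
  }
  if (!is.null(x$report$enrich)) {
    cat(sprintf("  enrichment OR = %.3g (p = %.3g)\n",
                x$report$enrich$odds_ratio, x$report$enrich$p_value))
  }
  invisible(x)
}
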