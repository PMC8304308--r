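# End-to-end orchestration: simulate (or load) -> scan -> call -> overlap ->
# candidates, with a machine-readable manifest of parameters and stage
# counts so any run can be reproduced exactly.

#' Build a pipeline run configuration
#'
#' All analysis parameters with their package defaults (1 Mb window, 1 kb
#' step, 1000 null replicates, 95% level, delta threshold 0.7, DEG
#' thresholds |log2FC| >= 1 and FDR <= 0.001). A `seed` is mandatory: every
#' stochastic stage derives its own stream from it.
#'
#' @param seed Integer seed (required).
#' @param out_dir Output directory for all artifacts.
#' @param variants Optional path to an existing variant table (TSV/VCF);
#'   when absent a synthetic cross is simulated from the `cross` settings.
#' @param cross Named list of [cross_config()] overrides for the simulated
#'   cross.
#' @param intervals Optional path to a TSV of QTL intervals from other
#'   experiments, intersected with this run's chromosome-1 call.
#' @param window_bp,step_bp,min_sites Window-scan settings.
#' @param reps,level,band_method Null-band settings (see [add_null_band()]).
#' @param min_depth Minimum per-pool depth for a defined SNP-index.
#' @param min_run Minimum consecutive exceeding windows for a QTL call.
#' @param delta_threshold Candidate-cascade delta threshold.
#' @param lfc_min,fdr_max Differential-expression thresholds.
#' @param candidates `"simulate"` to run the cascade on a planted-truth
#'   fixture, `"skip"`, or a named list of paths
#'   (`sites`, `genes`, `cds`, `panel`, `region`) for user data.
#' @return A `run_config` list.
#' @export
run_config <- function(seed,
                       out_dir = "bsaqtl_run",
                       variants = NULL,
                       cross = list(),
                       intervals = NULL,
                       window_bp = 1e6, step_bp = 1e3, min_sites = 3,
                       reps = 1000, level = 95,
                       band_method = "linkage",
                       min_depth = 7, min_run = 10,
                       delta_threshold = 0.7,
                       lfc_min = 1, fdr_max = 0.001,
                       candidates = "simulate") {
  if (missing(seed) || is.null(seed) || !is.finite(suppressWarnings(as.numeric(seed)))) {
    stop("a 'seed' is required in the run configuration", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 variants = variants, cross = cross, intervals = intervals,
                 window_bp = window_bp, step_bp = step_bp,
                 min_sites = min_sites, reps = reps, level = level,
                 band_method = band_method, min_depth = min_depth,
                 min_run = min_run, delta_threshold = delta_threshold,
                 lfc_min = lfc_min, fdr_max = fdr_max,
                 candidates = candidates),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; a missing `seed` is rejected before any work.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

.log_stage <- function(name) {
  message(sprintf("[bsaqtl] stage %s", name))
}

#' Run the full QTL-seq pipeline
#'
#' Executes simulate (or load) -> scan -> call -> overlap -> candidates,
#' writes every artifact atomically under `config$out_dir`, and always emits
#' `manifest.json` holding the package version, the full parameter set and
#' per-stage counts — enough to re-run the pipeline identically.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("'config' must be created by run_config() or read_run_config()",
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  manifest <- list(
    package = "bsaqtl",
    version = as.character(utils::packageVersion("bsaqtl")),
    seed = config$seed,
    parameters = unclass(config),
    stages = list())
  run_stage <- function(name, expr) {
    .log_stage(name)
    counts <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "completed"), counts)
  }

  sites_raw <- NULL
  run_stage("simulate", {
    if (is.null(config$variants)) {
      cc <- do.call(cross_config, c(config$cross, list(seed = seeds[1])))
      pop <- simulate_f2(cc)
      bulks <- make_bulks(pop, cc$bulk_size)
      sites_raw <- sample_depths(pop, bulks, seed = seeds[2])
      write_phenotypes(pop, file.path(config$out_dir, "phenotypes.tsv"))
      write_variant_table(sites_raw, file.path(config$out_dir, "variants.tsv"))
      write_variant_table(sites_raw, file.path(config$out_dir, "variants.vcf"))
      list(mode = "simulated", n_individuals = cc$n_individuals,
           n_sites = nrow(sites_raw))
    } else {
      sites_raw <- read_variant_table(config$variants)
      list(mode = "loaded", n_sites = nrow(sites_raw))
    }
  })

  profile <- NULL
  indexed <- NULL
  run_stage("scan", {
    pol <- polarize_sites(sites_raw)
    indexed <- index_sites(pol$sites, min_depth = config$min_depth)
    bulk_size <- config$cross$bulk_size %||% 17L
    profile <- window_scan(indexed, window_bp = config$window_bp,
                            step_bp = config$step_bp,
                            min_sites = config$min_sites)
    profile <- add_null_band(profile, indexed, bulk_size = bulk_size,
                              reps = config$reps, level = config$level,
                              method = config$band_method,
                              bp_per_cm = config$cross$bp_per_cm %||% 250000,
                              seed = seeds[3])
    write_profile(profile, file.path(config$out_dir, "profile.tsv"))
    list(n_polarized = nrow(indexed), n_rejected = nrow(pol$rejected),
         n_windows = nrow(profile))
  })

  qtls <- NULL
  run_stage("call", {
    qtls <- call_qtls(profile, min_run = config$min_run)
    write_qtls(qtls, file.path(config$out_dir, "qtls.tsv"))
    write_qtls(qtls, file.path(config$out_dir, "qtls.bed"))
    list(n_qtls = nrow(qtls))
  })

  run_stage("overlap", {
    ivs <- qtls_to_intervals(qtls)
    if (!is.null(config$intervals)) {
      ivs <- rbind(ivs, read_intervals(config$intervals))
    }
    consensus <- if (nrow(ivs)) intersect_intervals(ivs) else .empty_interval()
    write_intervals(rbind(ivs, consensus),
                    file.path(config$out_dir, "overlap.tsv"))
    list(n_intervals = nrow(ivs), consensus_found = nrow(consensus) > 0,
         consensus_width_mb = if (nrow(consensus)) interval_width(consensus) else NA)
  })

  run_stage("candidates", {
    if (identical(config$candidates, "skip")) {
      list(mode = "skipped")
    } else {
      if (identical(config$candidates, "simulate")) {
        fx <- simulate_candidate_truth(threshold = config$delta_threshold,
                                       seed = seeds[4])
      } else {
        fx <- list(
          sites = utils::read.delim(config$candidates$sites, comment.char = "#",
                                    stringsAsFactors = FALSE),
          genes = utils::read.delim(config$candidates$genes, comment.char = "#",
                                    stringsAsFactors = FALSE),
          cds_set = as.list(read_cds_fasta(config$candidates$cds)),
          panel = NULL, region = NULL)
        panel <- read_panel(config$candidates$panel)
        fx$panel <- panel$calls
        fx$groups <- panel$groups
        fx$region <- read_intervals(config$candidates$region)[1, , drop = FALSE]
        fx$annotations <- NULL
      }
      casc <- candidate_cascade(fx$sites, fx$genes, fx$cds_set, fx$panel,
                                fx$groups, fx$region,
                                threshold = config$delta_threshold,
                                annotations = fx$annotations,
                                annotation_keyword = if (is.null(fx$annotations)) NULL else "NF-YA")
      write_atomic(file.path(config$out_dir, "cascade_stages.tsv"), function(tmp) {
        utils::write.table(casc$stages, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      write_atomic(file.path(config$out_dir, "candidates.tsv"), function(tmp) {
        utils::write.table(casc$candidates, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      counts <- stats::setNames(as.list(casc$stages$n_genes),
                                paste0("genes_", casc$stages$stage))
      c(list(mode = if (identical(config$candidates, "simulate")) "simulated" else "user"),
        counts)
    }
  })

  write_atomic(file.path(config$out_dir, "manifest.json"), function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  })
  invisible(manifest)
}
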