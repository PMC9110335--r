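#' Pipeline configuration
#'
#' Assembles every knob of the full analysis into one validated list. Input
#' is either a `simulate` block (a [group_config()]) or paths to approach
#' and focal CSVs.
#'
#' @param simulate Optional [group_config()] generating the study in silico.
#' @param approaches_csv,focals_csv Input CSV paths (ignored when
#'   `simulate` is given).
#' @param threshold_mode `"pooled-median"`, `"per-year-median"`, or a fixed
#'   numeric threshold in metres.
#' @param rope ROPE interval (default `c(-0.1, 0.1)`).
#' @param hdi_mass HDI mass (default 0.89).
#' @param n_perm Mantel permutations (default 999).
#' @param backend Occurrence-model backend (`"bootstrap"` or `"glmm"`).
#' @param n_draws Draws / bootstrap resamples per occurrence model.
#' @param exclude Individuals to drop entirely before any counting.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param output_dir Optional directory: when given, every table is written
#'   as CSV with a JSON manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL,
                            approaches_csv = NULL, focals_csv = NULL,
                            threshold_mode = "pooled-median",
                            rope = c(-0.1, 0.1), hdi_mass = 0.89,
                            n_perm = 999L,
                            backend = c("bootstrap", "glmm"),
                            n_draws = 1000L,
                            exclude = character(),
                            seed = 1L, output_dir = NULL) {
  backend <- match.arg(backend)
  if (is.null(simulate) && (is.null(approaches_csv) || is.null(focals_csv))) {
    stop("configuration error: provide either a simulate block or both input CSVs")
  }
  structure(list(simulate = simulate, approaches_csv = approaches_csv,
                 focals_csv = focals_csv, threshold_mode = threshold_mode,
                 rope = rope, hdi_mass = hdi_mass, n_perm = as.integer(n_perm),
                 backend = backend, n_draws = as.integer(n_draws),
                 exclude = exclude, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  # deterministic per-stage seeds derived from the master seed
  offsets <- c(downsample = 11L, occurrence = 23L, mantel = 37L)
  (config$seed * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full observer-bias analysis pipeline
#'
#' Stages, in order: simulate or ingest -> tolerance estimation (mixed model
#' on log FID, conditional modes) -> exclusion, stratification at the median
#' observer distance and down-sampling -> occurrence counts with exposures
#' -> one occurrence model per buffer -> association matrices (buffer x
#' stratum x year) -> paired close/far Mantel tests per buffer and year ->
#' centrality rank concordance. When `config$output_dir` is set, all tables
#' are written as CSV together with a JSON manifest carrying seeds and
#' file hashes.
#'
#' @param config A [pipeline_config()].
#' @param year_plan Down-sampling plan; defaults to the simulate block's
#'   plan, or the per-year minimum focal count for ingested data.
#' @return List of class `pipeline_result`: `tolerances`, `fid_fit`,
#'   `validation`, `records` (stratified, down-sampled), `counts`,
#'   `occurrence` (per buffer), `matrices` (per buffer x stratum x year),
#'   `mantel` (per buffer x year), `concordance` (per buffer x year),
#'   `threshold`, `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulate = group_config(n_individuals = 12,
#'                                                seed = 7),
#'                        n_draws = 100, n_perm = 99)
#' res <- run_pipeline(cfg)
#' res$mantel[["n5.2018"]]
#' }
run_pipeline <- function(config, year_plan = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    study <- stage("simulate", simulate_study(config$simulate))
    approaches <- study$approaches
    focals <- study$focals
    truth <- study$truth
    if (is.null(year_plan)) year_plan <- config$simulate$year_plan
  } else {
    approaches <- stage("ingest", utils::read.csv(
      config$approaches_csv, stringsAsFactors = FALSE))
    focals <- stage("ingest", read_focal_csv(config$focals_csv))
    truth <- NULL
    if (is.null(year_plan)) {
      tab <- table(focals$focal_id, focals$year)
      year_plan <- apply(tab, 2L, min)
    }
  }

  fid_fit <- stage("fid_model", fit_fid_model(approaches))
  tol <- stage("fid_model", conditional_modes(fid_fit))
  validation <- stage("fid_model", validate_modes(tol, approaches))

  focals <- stage("exclude", exclude_individuals(focals, config$exclude))
  tol <- tol[!tol$individual_id %in% config$exclude, , drop = FALSE]
  if (is.numeric(config$threshold_mode)) {
    focals <- stage("stratify", split_by_distance(focals,
                                                  config$threshold_mode))
  } else {
    focals <- stage("stratify", split_by_distance(
      focals, threshold_mode = config$threshold_mode))
  }
  threshold <- attr(focals, "threshold")
  focals <- stage("downsample", downsample_focals(
    focals, year_plan, seed = stage_seed(config, "downsample")))

  buffers <- detect_buffer_cols(focals)
  ids <- sort(unique(focals$focal_id))
  counts <- stage("count", count_all_occurrences(focals, buffers, ids))

  occ <- stage("occurrence", {
    out <- lapply(buffers, function(b) {
      fit_occurrence_model(counts[counts$buffer == b, ], tol,
                           backend = config$backend,
                           n_draws = config$n_draws,
                           seed = stage_seed(config, "occurrence"))
    })
    names(out) <- buffers
    out
  })

  years <- unique(as.character(focals$year))
  mats <- stage("matrices", {
    out <- list()
    for (b in buffers) for (s in c("close", "far")) for (y in years) {
      out[[paste(b, s, y, sep = ".")]] <-
        build_association_matrix(focals, b, s, y, ids = ids)
    }
    out
  })

  mant <- stage("mantel", {
    out <- list()
    for (b in buffers) for (y in years) {
      # near-empty matrices (small groups, narrow buffers) cannot carry a
      # permutation test; record a flagged result instead of aborting
      out[[paste(b, y, sep = ".")]] <- tryCatch(
        mantel(mats[[paste(b, "close", y, sep = ".")]],
               mats[[paste(b, "far", y, sep = ".")]],
               n_perm = config$n_perm, seed = stage_seed(config, "mantel")),
        error = function(e) {
          structure(list(r = NA_real_, p = NA_real_,
                         n_perm = config$n_perm, method = "spearman",
                         perm_r = numeric(), exact = FALSE,
                         degenerate = TRUE, note = conditionMessage(e)),
                    class = "mantel_result")
        })
    }
    out
  })

  conc <- stage("centrality", {
    out <- list()
    for (b in buffers) for (y in years) {
      out[[paste(b, y, sep = ".")]] <- compare_centralities(
        centralities(mats[[paste(b, "close", y, sep = ".")]]),
        centralities(mats[[paste(b, "far", y, sep = ".")]]))
    }
    out
  })

  res <- structure(list(tolerances = tol, fid_fit = fid_fit,
                        validation = validation, records = focals,
                        counts = counts, occurrence = occ,
                        matrices = mats, mantel = mant,
                        concordance = conc, threshold = threshold,
                        truth = truth, config = config),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res)
  res
}

write_pipeline_outputs <- function(res) {
  dir <- res$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    files[[name]] <<- unname(tools::md5sum(path))
  }
  put("tolerances.csv", function(p) write_tolerance_csv(res$tolerances, p))
  put("focals.csv", function(p) write_focal_csv(res$records, p))
  put("counts.csv", function(p) utils::write.csv(res$counts, p,
                                                 row.names = FALSE))
  for (nm in names(res$matrices)) {
    put(paste0("matrix_", nm, ".csv"),
        function(p) write_matrix_csv(res$matrices[[nm]], p))
  }
  mant <- do.call(rbind, lapply(names(res$mantel), function(nm) {
    m <- res$mantel[[nm]]
    data.frame(cell = nm, r = m$r, p = m$p, n_perm = m$n_perm,
               method = m$method)
  }))
  put("mantel.csv", function(p) utils::write.csv(mant, p, row.names = FALSE))
  conc <- do.call(rbind, lapply(names(res$concordance), function(nm) {
    cbind(cell = nm, res$concordance[[nm]])
  }))
  put("concordance.csv", function(p) utils::write.csv(conc, p,
                                                      row.names = FALSE))
  for (nm in names(res$occurrence)) {
    put(paste0("occurrence_", nm, "_summary.csv"),
        function(p) utils::write.csv(res$occurrence[[nm]]$summary, p,
                                     row.names = FALSE))
  }
  manifest <- list(seed = res$config$seed,
                   backend = res$config$backend,
                   threshold = res$threshold,
                   package_version = as.character(
                     utils::packageVersion("proxbias")),
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
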