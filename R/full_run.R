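#' Configuration for a one-shot analysis run
#'
#' Bundles every tunable of the pipeline: input paths (or a simulator
#' configuration when no input is given), classification thresholds, the
#' selection-intensity constant, the phenotypic-variance convention, era
#' cuts and the bin specification.
#'
#' @param input Path to a panel CSV, or `NULL` to simulate from `sim`.
#' @param registry Optional path to a registry CSV (ignored when
#'   simulating; the simulator provides its own registry).
#' @param out_dir Output directory for the report bundle.
#' @param tolerant_cut,susceptible_cut HSI class boundaries
#'   (`0 < tolerant_cut < susceptible_cut`).
#' @param k Selection intensity constant (default 2.06, 5% intensity).
#' @param phenotypic_basis `"plot"` or `"mean"`, see [variance_components()].
#' @param era An [era_rule()].
#' @param bins A bin specification, see [default_bins()].
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param seed Integer seed forwarded to the simulator.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, registry = NULL, out_dir = "heattol-run",
                       tolerant_cut = 0.5, susceptible_cut = 1, k = 2.06,
                       phenotypic_basis = c("plot", "mean"),
                       era = era_rule(), bins = default_bins(),
                       sim = sim_config(), seed = 1L) {
  phenotypic_basis <- match.arg(phenotypic_basis)
  if (!(tolerant_cut > 0 && tolerant_cut < susceptible_cut)) {
    stop("thresholds must satisfy 0 < tolerant_cut < susceptible_cut",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole pipeline and write a report bundle
#'
#' Chains input (or simulation) -> susceptibility screening -> combined
#' factorial ANOVA -> genetic parameters per condition -> descriptive
#' reports, and writes every table as CSV plus a JSON manifest (package
#' version, configuration, input checksums, record counts). The bundle is
#' deterministic for a fixed configuration and seed.
#'
#' Files written: `hsi.csv`, `class_counts.csv`, `stable_tolerant.csv`,
#' `anova.csv`, `genetics.csv`, `bins.csv`, `correlations.csv`, `era.csv`
#' (when a registry is available), `descriptives.csv`, `panel.csv` (when
#' simulated) and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects and the bundle
#'   `paths`.
#' @export
full_run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    write_table(df, p)
    paths[[file]] <<- p
  }

  simulated <- is.null(config$input)
  panel <- stage("input", {
    if (simulated) {
      sim <- simulate_panel(config$sim, seed = config$seed)
      sim$panel
    } else {
      read_panel(config$input, config$registry)
    }
  })
  if (simulated) emit(panel$records, "panel.csv")

  screen <- stage("screen", screen_panel(panel, config$tolerant_cut,
                                         config$susceptible_cut))
  emit(screen$results, "hsi.csv")
  emit(screen$class_counts, "class_counts.csv")
  if (dplyr::n_distinct(screen$results$season) >= 2) {
    st <- stage("screen", stable_tolerant(screen))
    emit(tibble(genotype = st$stable_tolerant), "stable_tolerant.csv")
  } else st <- NULL

  aov_tab <- stage("anova", anova_combined(panel))
  emit(aov_tab, "anova.csv")

  genetics <- stage("genetics", dplyr::bind_rows(lapply(
    TREATMENT_LEVELS, function(cond) {
      genetics_report(panel, cond, phenotypic_basis = config$phenotypic_basis,
                      k = config$k)
    })))
  emit(genetics, "genetics.csv")

  means <- genotype_means(panel)
  bins <- stage("report", dplyr::bind_rows(lapply(
    unique(means$season), function(s) {
      dplyr::bind_rows(lapply(TREATMENT_LEVELS, function(cond) {
        b <- viability_bins(means, cond, s, bins = config$bins)
        dplyr::mutate(b, season = s, treatment = cond, .before = 1)
      }))
    })))
  emit(bins, "bins.csv")

  correlations <- stage("report", hsi_correlations(screen))
  emit(correlations, "correlations.csv")

  era <- NULL
  if (!is.null(panel$registry)) {
    era <- stage("report", era_trend(screen, panel$registry, config$era))
    emit(era$summary, "era.csv")
  }
  emit(descriptive_stats(panel), "descriptives.csv")

  manifest <- list(
    package = "heattol",
    version = as.character(utils::packageVersion("heattol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    simulated = simulated,
    config_hash = unname(config_hash(config)),
    n_records = nrow(panel$records),
    n_genotypes = panel$design$n_genotypes,
    balanced = panel$balanced,
    file_md5 = as.list(tools::md5sum(unlist(paths))) |>
      stats::setNames(names(paths)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- manifest_path

  invisible(list(panel = panel, screen = screen, stable = st,
                 anova = aov_tab, genetics = genetics, bins = bins,
                 correlations = correlations, era = era, paths = paths))
}

config_hash <- function(config) {
  flat <- config
  flat$bins <- as.list(flat$bins)
  json <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  tools::md5sum(tmp)
}
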