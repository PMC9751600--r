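#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

TREATMENT_LEVELS <- c("normal", "stress")
PANEL_COLUMNS <- c("genotype", "season", "treatment", "replicate", "viability")
REGISTRY_COLUMNS <- c("genotype", "release_year", "era", "pedigree")

#' Construct a validated trial panel
#'
#' A trial panel holds plot-level percent pollen viability records from a
#' randomized-complete-block screening trial, keyed by genotype, season,
#' treatment (`normal` or `stress`) and replicate, plus an optional genotype
#' registry (release year, breeding era, pedigree).
#'
#' Validation enforces the panel invariants: viability in \[0, 100\] (exactly
#' 0 is legal: fully heat-sterile pollen is observed in the field), treatment
#' one of exactly two levels (matched case-insensitively, no other coercion),
#' and uniqueness of the (genotype, season, treatment, replicate) key.
#' Unbalanced panels are accepted here and flagged; the factorial ANOVA
#' refuses them downstream.
#'
#' @param records Data frame with columns `genotype`, `season`, `treatment`,
#'   `replicate`, `viability`.
#' @param registry Optional data frame with columns `genotype`,
#'   `release_year` (integer year, `NA` for advanced lines), `era`, `pedigree`.
#' @return An object of class `trial_panel`: a list with tibbles `records`
#'   and `registry`, a `design` summary (level counts, replicates per cell)
#'   and a logical `balanced` flag, true iff every genotype x season x
#'   treatment cell has the same replicate count.
#' @seealso [read_panel()], [genotype_means()], [simulate_panel()]
#' @export
#' @examples
#' recs <- expand.grid(genotype = c("A", "B"), season = "s1",
#'                     treatment = c("normal", "stress"), replicate = 1:2)
#' recs$viability <- c(95, 90, 96, 91, 80, 85, 82, 87)
#' trial_panel(recs)
trial_panel <- function(records, registry = NULL) {
  records <- validate_records(records)
  if (!is.null(registry)) registry <- validate_registry(registry)

  cells <- dplyr::count(records, .data$genotype, .data$season, .data$treatment,
                        name = "n_rep")
  design <- list(
    n_genotypes  = dplyr::n_distinct(records$genotype),
    n_seasons    = dplyr::n_distinct(records$season),
    n_treatments = dplyr::n_distinct(records$treatment),
    n_replicates = max(cells$n_rep),
    n_records    = nrow(records)
  )
  full_cross <- design$n_genotypes * design$n_seasons * design$n_treatments
  structure(
    list(records = records, registry = registry, design = design,
         balanced = dplyr::n_distinct(cells$n_rep) == 1L &&
           nrow(cells) == full_cross),
    class = "trial_panel"
  )
}

validate_records <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(PANEL_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[PANEL_COLUMNS]
  records$genotype <- as.character(records$genotype)
  records$season <- as.character(records$season)

  tr <- tolower(trimws(as.character(records$treatment)))
  bad <- which(!tr %in% TREATMENT_LEVELS)
  if (length(bad) > 0) {
    stop("invalid treatment level(s) ",
         paste(unique(records$treatment[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         "; expected 'normal' or 'stress'", call. = FALSE)
  }
  records$treatment <- tr

  rep_num <- suppressWarnings(as.integer(records$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1)
  if (length(bad) > 0) {
    stop("replicate must be an integer >= 1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  records$replicate <- rep_num

  v <- suppressWarnings(as.numeric(records$viability))
  bad <- which(!is.finite(v) | v < 0 | v > 100)
  if (length(bad) > 0) {
    stop("viability must be a percentage in [0, 100]; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value(s) ", paste(utils::head(records$viability[bad], 5),
                              collapse = ", "), ")", call. = FALSE)
  }
  records$viability <- v

  dup <- duplicated(records[c("genotype", "season", "treatment", "replicate")])
  if (any(dup)) {
    stop("duplicate (genotype, season, treatment, replicate) key(s) at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  records
}

validate_registry <- function(registry) {
  registry <- as_tibble(registry)
  if (!"genotype" %in% names(registry)) {
    stop("registry is missing required column: genotype", call. = FALSE)
  }
  for (col in setdiff(REGISTRY_COLUMNS, names(registry))) {
    registry[[col]] <- NA
  }
  registry <- registry[REGISTRY_COLUMNS]
  registry$genotype <- as.character(registry$genotype)
  registry$release_year <- suppressWarnings(as.integer(registry$release_year))
  registry$era <- as.character(registry$era)
  registry$pedigree <- as.character(registry$pedigree)
  if (anyDuplicated(registry$genotype)) {
    stop("registry has duplicated genotype ids", call. = FALSE)
  }
  registry
}

#' @export
print.trial_panel <- function(x, ...) {
  d <- x$design
  cat("<trial_panel> ", d$n_records, " records: ",
      d$n_genotypes, " genotypes x ", d$n_seasons, " season(s) x ",
      d$n_treatments, " treatment(s), up to ", d$n_replicates,
      " replicate(s)\n", sep = "")
  cat("  balanced: ", x$balanced,
      if (!is.null(x$registry)) paste0("; registry: ", nrow(x$registry),
                                       " genotypes") else "", "\n", sep = "")
  invisible(x)
}

#' Read a trial panel from CSV
#'
#' Reads long-format plot-level records (header
#' `genotype,season,treatment,replicate,viability`; RFC-4180 CSV, UTF-8,
#' `.` decimal separator) and optionally a genotype registry
#' (`genotype,release_year,era,pedigree`, empty `release_year` allowed for
#' advanced lines), then validates both (see [trial_panel()]).
#'
#' @param path Path to the panel CSV.
#' @param registry_path Optional path to the registry CSV.
#' @return A validated [trial_panel()].
#' @export
read_panel <- function(path, registry_path = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  registry <- NULL
  if (!is.null(registry_path)) {
    if (!file.exists(registry_path)) {
      stop("registry file not found: ", registry_path, call. = FALSE)
    }
    registry <- utils::read.csv(registry_path, stringsAsFactors = FALSE)
  }
  trial_panel(records, registry)
}

#' Write a trial panel (or any result table) to CSV
#'
#' Columns are written in the documented order at full precision (15
#' significant digits), so that `read_panel(write_panel(p))` round-trips
#' every field.
#'
#' @param panel A `trial_panel`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "trial_panel"))
  write_table(panel$records, path)
}

#' @rdname write_panel
#' @param x A data frame.
#' @export
write_table <- function(x, path) {
  ok <- tryCatch({
    df <- as.data.frame(x)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(col) format(col, digits = 15,
                                                    trim = TRUE,
                                                    scientific = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Mean viability per genotype, season and treatment
#'
#' Averages plot-level viability over replicates. These cell means are the
#' X values entering the heat susceptibility index and the per-condition
#' genotype analyses.
#'
#' @param panel A `trial_panel`.
#' @return Tibble with one row per genotype x season x treatment present in
#'   the data: columns `genotype`, `season`, `treatment`, `mean_viability`,
#'   `n_rep`. Empty cells are simply absent.
#' @export
genotype_means <- function(panel) {
  stopifnot(inherits(panel, "trial_panel"))
  if (nrow(panel$records) == 0) stop("panel is empty", call. = FALSE)
  panel$records |>
    dplyr::group_by(.data$genotype, .data$season, .data$treatment) |>
    dplyr::summarise(mean_viability = mean(.data$viability),
                     n_rep = dplyr::n(), .groups = "drop")
}
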