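#' Combined factorial ANOVA of a balanced two-treatment trial
#'
#' Fits the fixed-effects decomposition
#' `viability ~ treatment + year + genotype + treatment:genotype`
#' on a balanced genotype x treatment x season x replicate panel. No block
#' term and no year interactions are modelled: replicate-to-replicate and
#' year-interaction variation pool into the residual, so with G genotypes,
#' S seasons and r replicates the degrees of freedom are
#' 1, S-1, G-1, G-1 and the remainder of N-1. All F tests are against the
#' residual mean square. Sequential sums of squares coincide with the
#' orthogonal decomposition because the design is balanced; unbalanced
#' panels are refused (the expected-mean-square algebra used downstream for
#' variance components requires balance).
#'
#' @param panel A balanced `trial_panel` with two treatments and at least
#'   two seasons and two genotypes.
#' @return An `anova_table`: tibble with columns `source`, `df`, `sum_sq`,
#'   `mean_sq`, `f_value`, `p_value` (rows Treatment, Year, Genotypes,
#'   Treatment x Genotypes, Residuals), with attributes `total_ss`,
#'   `total_df` and `model`.
#' @export
anova_combined <- function(panel) {
  stopifnot(inherits(panel, "trial_panel"))
  refuse_unbalanced(panel)
  d <- panel$records
  for (f in c("treatment", "season", "genotype")) {
    if (dplyr::n_distinct(d[[f]]) < 2) {
      stop("factor '", f, "' has a single level; the combined ANOVA needs ",
           "at least two", call. = FALSE)
    }
  }
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment, levels = TREATMENT_LEVELS)
  d$season <- factor(d$season)
  fit <- stats::lm(viability ~ treatment + season + genotype +
                     treatment:genotype, data = d)
  tab <- quiet_perfect_fit(stats::anova(fit))
  rownames(tab)[rownames(tab) == "treatment"] <- "Treatment"
  rownames(tab)[rownames(tab) == "season"] <- "Year"
  rownames(tab)[rownames(tab) == "genotype"] <- "Genotypes"
  rownames(tab)[rownames(tab) == "treatment:genotype"] <- "Treatment x Genotypes"
  as_anova_table(tab, model = "combined")
}

#' One-way genotype ANOVA for a single condition
#'
#' Restricts the panel to one treatment (optionally one season; by default
#' the seasons are pooled so that each genotype contributes
#' seasons x replicates observations) and partitions the variation into
#' Genotypes and Residuals. The two mean squares feed the variance-component
#' estimators in [variance_components()].
#'
#' @param panel A balanced `trial_panel`.
#' @param treatment `"normal"` or `"stress"`.
#' @param season Optional single season label; `NULL` pools all seasons.
#' @return An `anova_table` with rows Genotypes and Residuals.
#' @export
anova_oneway_genotype <- function(panel, treatment, season = NULL) {
  stopifnot(inherits(panel, "trial_panel"))
  treatment <- match.arg(treatment, TREATMENT_LEVELS)
  refuse_unbalanced(panel)
  d <- panel$records[panel$records$treatment == treatment, ]
  if (!is.null(season)) d <- d[d$season %in% season, ]
  if (nrow(d) == 0) stop("no records for treatment '", treatment, "'",
                         if (!is.null(season)) paste0(" in season '", season, "'"),
                         call. = FALSE)
  if (dplyr::n_distinct(d$genotype) < 2) {
    stop("one-way genotype ANOVA needs at least two genotypes", call. = FALSE)
  }
  n_per <- table(d$genotype)
  if (dplyr::n_distinct(as.integer(n_per)) != 1 || min(n_per) < 2) {
    stop("one-way genotype ANOVA requires the same number (>= 2) of ",
         "observations per genotype", call. = FALSE)
  }
  d$genotype <- factor(d$genotype)
  tab <- quiet_perfect_fit(stats::anova(stats::lm(viability ~ genotype,
                                                  data = d)))
  rownames(tab)[rownames(tab) == "genotype"] <- "Genotypes"
  out <- as_anova_table(tab, model = paste0("oneway:", treatment))
  attr(out, "n_obs_per_genotype") <- as.integer(n_per[1])
  out
}

# lm warns on zero-residual fits; that case is legal here (identical
# replicates) and handled by the +Inf F sentinel below
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

as_anova_table <- function(tab, model) {
  out <- tibble(
    source = rownames(tab), df = as.integer(tab$Df), sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`, f_value = tab$`F value`, p_value = tab$`Pr(>F)`)
  # zero residual MS (identical replicates): report F as +Inf rather than
  # lm's NaN; "zero" is relative, lm leaves ~1e-25 of numerical residue
  res_ms <- out$mean_sq[out$source == "Residuals"]
  scale_ms <- max(out$mean_sq, 1)
  if (length(res_ms) == 1 && res_ms <= 1e-12 * scale_ms) {
    out$sum_sq[out$source == "Residuals"] <- 0
    out$mean_sq[out$source == "Residuals"] <- 0
    res_ms <- 0
  }
  if (length(res_ms) == 1 && res_ms == 0) {
    eff <- out$source != "Residuals"
    out$f_value[eff] <- ifelse(out$mean_sq[eff] > 0, Inf, NaN)
    out$p_value[eff] <- ifelse(out$mean_sq[eff] > 0, 0, NaN)
  }
  structure(out, class = c("anova_table", class(out)),
            total_ss = sum(out$sum_sq), total_df = sum(out$df), model = model)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Analysis of variance (", attr(x, "model"), " model)\n", sep = "")
  NextMethod()
  invisible(x)
}

refuse_unbalanced <- function(panel) {
  if (panel$balanced) return(invisible(TRUE))
  cells <- dplyr::count(panel$records, .data$genotype, .data$season,
                        .data$treatment, name = "n_rep")
  mode_n <- as.integer(names(which.max(table(cells$n_rep))))
  off <- cells[cells$n_rep != mode_n, ]
  stop("panel is unbalanced: ", nrow(off), " cell(s) deviate from ", mode_n,
       " replicate(s), e.g. ",
       paste(utils::head(sprintf("%s/%s/%s (n=%d)", off$genotype, off$season,
                                 off$treatment, off$n_rep), 3),
             collapse = "; "),
       ". The factorial ANOVA accepts balanced designs only.", call. = FALSE)
}

#' Upper-tail F probability
#'
#' @param f Observed F statistic (non-negative).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return `P(F(df1, df2) > f)`.
#' @export
f_pvalue <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1",
                                         call. = FALSE)
  if (any(f < 0, na.rm = TRUE)) stop("F statistic must be non-negative",
                                     call. = FALSE)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}
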