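#' Variance components from one-way genotype mean squares
#'
#' In a balanced design with `r` observations per genotype, the expected
#' mean squares are `E[MS_error] = sigma2_e` and
#' `E[MS_genotype] = sigma2_e + r * sigma2_g`, giving the moment estimators
#' `sigma2_e = MS_error` and `sigma2_g = (MS_genotype - MS_error) / r`.
#' A negative genotypic estimate is truncated at zero and flagged.
#'
#' Phenotypic variance follows one of two conventions common in the
#' PCV/GCV literature: on a plot basis `sigma2_p = sigma2_g + sigma2_e`
#' (the default; more conservative, lower heritability) or on a
#' genotype-mean basis `sigma2_p = sigma2_g + sigma2_e / r`.
#'
#' @param ms_genotype,ms_error Genotype and residual mean squares (>= 0).
#' @param r Observations per genotype (>= 2).
#' @param phenotypic_basis `"plot"` or `"mean"`.
#' @return List of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `sigma2_p`, `r`, `phenotypic_basis`, `truncated` flag.
#' @export
variance_components <- function(ms_genotype, ms_error, r,
                                phenotypic_basis = c("plot", "mean")) {
  phenotypic_basis <- match.arg(phenotypic_basis)
  if (r < 2) stop("variance components are unidentifiable with r < 2",
                  call. = FALSE)
  if (ms_genotype < 0 || ms_error < 0) stop("mean squares must be >= 0",
                                            call. = FALSE)
  sigma2_g <- (ms_genotype - ms_error) / r
  truncated <- sigma2_g < 0
  if (truncated) sigma2_g <- 0
  sigma2_e <- ms_error
  sigma2_p <- sigma2_g + if (phenotypic_basis == "plot") sigma2_e else sigma2_e / r
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, sigma2_p = sigma2_p,
                 r = r, phenotypic_basis = phenotypic_basis,
                 truncated = truncated),
            class = "variance_components")
}

#' Phenotypic and genotypic coefficients of variation
#'
#' `PCV% = 100 * sqrt(sigma2_p) / mean`, `GCV% = 100 * sqrt(sigma2_g) / mean`.
#'
#' @param vc A `variance_components`.
#' @param mean Trait grand mean (must be positive).
#' @return Named list `pcv_pct`, `gcv_pct`; always `gcv_pct <= pcv_pct`.
#' @export
pcv_gcv <- function(vc, mean) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.finite(mean) || mean <= 0) {
    stop("coefficients of variation need a positive trait mean", call. = FALSE)
  }
  list(pcv_pct = 100 * sqrt(vc$sigma2_p) / mean,
       gcv_pct = 100 * sqrt(vc$sigma2_g) / mean)
}

#' Broad-sense heritability (percent)
#'
#' `h2 = 100 * sigma2_g / sigma2_p`, the share of phenotypic variance
#' attributable to all genetic effects; always in \[0, 100\].
#'
#' @param vc A `variance_components` with `sigma2_p > 0`.
#' @return Heritability in percent.
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma2_p <= 0) {
    stop("heritability undefined: phenotypic variance is zero", call. = FALSE)
  }
  100 * vc$sigma2_g / vc$sigma2_p
}

#' Genetic advance under truncation selection
#'
#' Expected gain from selecting the best fraction of genotypes,
#' `GA = k * sqrt(sigma2_p) * h2`, with `h2` the broad-sense heritability as
#' a fraction and `k` the standardized selection differential (2.06 at 5%
#' selection intensity). Reported in trait units (percent viability).
#'
#' @param vc A `variance_components`.
#' @param k Selection intensity constant; default 2.06.
#' @return Genetic advance in trait units.
#' @export
genetic_advance <- function(vc, k = 2.06) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma2_p == 0) return(0)
  k * sqrt(vc$sigma2_p) * (vc$sigma2_g / vc$sigma2_p)
}

#' Genetic-parameter summary for one condition
#'
#' Chains the one-way genotype ANOVA, variance components, coefficients of
#' variation, heritability and genetic advance for the records under one
#' treatment. By default the seasons are pooled (each genotype then has
#' seasons x replicates observations); pass `season` to analyse one season.
#'
#' @param panel A balanced `trial_panel`.
#' @param condition `"normal"` or `"stress"`.
#' @param season Optional single season; `NULL` pools seasons.
#' @param phenotypic_basis Passed to [variance_components()].
#' @param k Passed to [genetic_advance()].
#' @return One-row tibble: `condition`, `mean`, `sigma2_g`, `sigma2_e`,
#'   `sigma2_p`, `pcv_pct`, `gcv_pct`, `h2_bs_pct`, `ga`, `ga_over_mean_pct`,
#'   `truncated`.
#' @export
genetics_report <- function(panel, condition = c("normal", "stress"),
                            season = NULL,
                            phenotypic_basis = c("plot", "mean"), k = 2.06) {
  condition <- match.arg(condition)
  phenotypic_basis <- match.arg(phenotypic_basis)
  aov_tab <- anova_oneway_genotype(panel, condition, season = season)
  ms <- stats::setNames(aov_tab$mean_sq, aov_tab$source)
  vc <- variance_components(ms[["Genotypes"]], ms[["Residuals"]],
                            r = attr(aov_tab, "n_obs_per_genotype"),
                            phenotypic_basis = phenotypic_basis)
  d <- panel$records[panel$records$treatment == condition, ]
  if (!is.null(season)) d <- d[d$season %in% season, ]
  xbar <- mean(d$viability)
  cv <- pcv_gcv(vc, xbar)
  ga <- genetic_advance(vc, k = k)
  tibble(condition = condition, mean = xbar,
         sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e, sigma2_p = vc$sigma2_p,
         pcv_pct = cv$pcv_pct, gcv_pct = cv$gcv_pct,
         h2_bs_pct = heritability(vc), ga = ga,
         ga_over_mean_pct = 100 * ga / xbar, truncated = vc$truncated)
}
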