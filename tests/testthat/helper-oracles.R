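# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's computation paths: plain loops and
# textbook formulas only.

make_random_panel <- function(G = 4, S = 2, r = 3, seed = 1,
                              treatments = c("normal", "stress")) {
  set.seed(seed)
  grid <- expand.grid(genotype = sprintf("g%02d", seq_len(G)),
                      season = sprintf("s%d", seq_len(S)),
                      treatment = treatments,
                      replicate = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$treatment == "stress", 80, 92)
  grid$viability <- pmin(100, pmax(0, base + stats::rnorm(nrow(grid), 0, 4)))
  trial_panel(grid)
}

# group means by explicit looping
bf_genotype_means <- function(records) {
  key <- interaction(records$genotype, records$season, records$treatment,
                     drop = TRUE)
  out <- lapply(levels(key), function(k) {
    rows <- records[key == k, ]
    data.frame(genotype = rows$genotype[1], season = rows$season[1],
               treatment = rows$treatment[1],
               mean_viability = sum(rows$viability) / nrow(rows),
               n_rep = nrow(rows))
  })
  do.call(rbind, out)
}

# HSI per genotype for one season, straight from raw records
bf_hsi <- function(records, season) {
  rec <- records[records$season == season, ]
  genos <- sort(unique(rec$genotype))
  xn <- sapply(genos, function(g)
    mean(rec$viability[rec$genotype == g & rec$treatment == "normal"]))
  xs <- sapply(genos, function(g)
    mean(rec$viability[rec$genotype == g & rec$treatment == "stress"]))
  keep <- is.finite(xn) & is.finite(xs) & xn > 0
  d_bar <- 1 - mean(xs[keep]) / mean(xn[keep])
  hsi <- (1 - xs[keep] / xn[keep]) / d_bar
  stats::setNames(hsi, genos[keep])
}

bf_classify <- function(hsi) {
  ifelse(hsi < 0.5, "tolerant",
         ifelse(hsi < 1, "moderately_tolerant", "susceptible"))
}

# orthogonal mean decomposition for the balanced combined factorial
bf_anova_combined_ss <- function(records) {
  y <- records$viability
  m <- mean(y)
  ss_of <- function(f) {
    sum(sapply(unique(f), function(lv) {
      n <- sum(f == lv); n * (mean(y[f == lv]) - m)^2
    }))
  }
  ss_t <- ss_of(records$treatment)
  ss_s <- ss_of(records$season)
  ss_g <- ss_of(records$genotype)
  tg <- interaction(records$treatment, records$genotype, drop = TRUE)
  ss_tg <- sum(sapply(levels(tg), function(lv) {
    rows <- tg == lv
    n <- sum(rows)
    cell <- mean(y[rows])
    mt <- mean(y[records$treatment == records$treatment[rows][1]])
    mg <- mean(y[records$genotype == records$genotype[rows][1]])
    n * (cell - mt - mg + m)^2
  }))
  ss_total <- sum((y - m)^2)
  c(Treatment = ss_t, Year = ss_s, Genotypes = ss_g,
    `Treatment x Genotypes` = ss_tg,
    Residuals = ss_total - ss_t - ss_s - ss_g - ss_tg, Total = ss_total)
}

bf_anova_oneway_ss <- function(records) {
  y <- records$viability
  g <- records$genotype
  m <- mean(y)
  ss_b <- sum(sapply(unique(g), function(lv) {
    sum(g == lv) * (mean(y[g == lv]) - m)^2
  }))
  ss_w <- sum(sapply(unique(g), function(lv) {
    sum((y[g == lv] - mean(y[g == lv]))^2)
  }))
  c(Genotypes = ss_b, Residuals = ss_w)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}
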