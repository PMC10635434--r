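#' Generations elapsed between dilution and sampling
#'
#' `g = log2(od_at_sampling / od_after_dilution)`; negative growth is
#' clipped to zero generations with a warning.
#'
#' @param od_after_dilution optical density immediately after dilution.
#' @param od_at_sampling optical density when sampled.
#' @return generations (vectorised).
#' @export
generations_from_od <- function(od_after_dilution, od_at_sampling) {
  stopifnot(all(od_after_dilution > 0), all(od_at_sampling > 0))
  g <- log2(od_at_sampling / od_after_dilution)
  if (any(g < 0)) {
    warning("od_at_sampling below od_after_dilution; clipping generations at 0")
    g <- pmax(g, 0)
  }
  g
}

#' Selection coefficient from a competition time series
#'
#' Ordinary least squares of `ln(query/competitor)` on cumulative
#' generations; the slope is the per-generation selection coefficient `s`.
#' Cumulative generations are the running sum of per-transfer generations
#' computed from the OD columns (transfer 0 contributes none). Time points
#' with a zero count on either side are dropped with a warning.
#'
#' @param series a `competition_series` data.frame with columns `transfer`,
#'   `od_after_dilution`, `od`, `query_count`, `competitor_count` (see
#'   [simulate_competition()] and [read_competition_tsv()]).
#' @return a `fitness_record` list: `s`, `se`, `r_squared`, `intercept`,
#'   `n_points`, `ci` (95%, t-based).
#' @export
selection_coefficient <- function(series) {
  x <- as.data.frame(series)
  need <- c("transfer", "od_after_dilution", "od", "query_count",
            "competitor_count")
  stopifnot(all(need %in% names(x)))
  if (any(diff(x$transfer) <= 0)) stop("transfers must be strictly increasing")
  g_step <- ifelse(x$transfer == 0, 0,
                   generations_from_od(x$od_after_dilution, x$od))
  gens <- cumsum(g_step)
  usable <- x$query_count > 0 & x$competitor_count > 0
  if (any(!usable))
    warning(sum(!usable), " time point(s) with a zero count dropped")
  if (sum(usable) < 3)
    stop("need at least 3 time points with both counts positive")
  y <- log(x$query_count[usable] / x$competitor_count[usable])
  fit <- stats::lm(y ~ gens[usable])
  sm <- summary(fit)
  s <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tq <- stats::qt(0.975, df = fit$df.residual)
  structure(list(s = s, se = se, r_squared = sm$r.squared,
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = sum(usable), ci = c(s - tq * se, s + tq * se)),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> s=%.4f (SE %.4f, R2=%.3f, %d points)\n",
              x$s, x$se, x$r_squared, x$n_points))
  invisible(x)
}

# Mann-Whitney U statistic: number of (a, b) pairs with a > b, ties 1/2.
mwu_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Compare fitness between two genotype groups (Mann-Whitney U)
#'
#' Exact two-sided p-value from the null permutation distribution of U when
#' the combined sample size is at most 25 and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param records data.frame with a numeric column `s` and a grouping
#'   column.
#' @param group_a,group_b group labels to compare (a vs b).
#' @param group_col name of the grouping column (default "group").
#' @param alternative "two.sided" (default), "greater" (a tends larger),
#'   or "less".
#' @return list with `median_diff` (median(a) - median(b)), `U`, `p`,
#'   `method`.
#' @export
compare_groups <- function(records, group_a, group_b, group_col = "group",
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(records), "s" %in% names(records),
            group_col %in% names(records))
  a <- records$s[records[[group_col]] == group_a]
  b <- records$s[records[[group_col]] == group_b]
  if (!length(a) || !length(b)) stop("empty group")
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 records")
  m <- length(a); n <- length(b)
  U <- mwu_statistic(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (m + n <= 25 && !ties) {
    # exact null: P(U >= u) etc. from the Wilcoxon distribution
    p <- switch(alternative,
      two.sided = {
        lo <- stats::pwilcox(U, m, n)
        hi <- 1 - stats::pwilcox(U - 1, m, n)
        min(1, 2 * min(lo, hi))
      },
      greater = 1 - stats::pwilcox(U - 1, m, n),
      less = stats::pwilcox(U, m, n))
    method <- "exact"
  } else {
    mu <- m * n / 2
    r <- rank(c(a, b))
    tie_tab <- table(r)
    N <- m + n
    sig2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- U - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z - cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(median_diff = stats::median(a) - stats::median(b), U = U, p = p,
       method = method)
}

#' Decompose fitness into ploidy, mating-type and cell-type effects
#'
#' Multiple linear regression of the selection coefficient on three binary
#' factors: cell type (haploid-like vs diploid-like expression program),
#' ploidy (1 vs 2), and mating type collapsed to whether the genotype
#' expresses any mating-type-specific genes. Reports coefficients with
#' t-based 95% confidence intervals and p-values, plus the proportion of
#' total sum of squares attributable to each factor (type II by default;
#' type I also returned).
#'
#' @param records data.frame with columns `s`, `ploidy` (1 or 2),
#'   `mating_type` (one of "a", "alpha", "a/alpha", "null"), `cell_type`
#'   ("haploid-like" or "diploid-like").
#' @return an `effect_estimates` list: `coefficients` data.frame (term,
#'   estimate, ci_lo, ci_hi, p), `ss_proportion` (type II), `ss_proportion_type1`,
#'   `r_squared`, `df_residual`.
#' @export
decompose_effects <- function(records) {
  need <- c("s", "ploidy", "mating_type", "cell_type")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  d <- data.frame(
    s = records$s,
    cell_type = factor(records$cell_type, c("diploid-like", "haploid-like")),
    ploidy = factor(records$ploidy, c(2, 1)),
    mating = factor(records$mating_type %in% c("a", "alpha"), c(FALSE, TRUE),
                    labels = c("none", "any")))
  for (f in c("cell_type", "ploidy", "mating"))
    if (nlevels(droplevels(d[[f]])) < 2)
      stop("factor does not vary across records: ", f)
  full <- stats::lm(s ~ cell_type + ploidy + mating, data = d)
  if (full$rank < 4) {
    al <- stats::alias(full)$Complete
    stop("rank-deficient design; confounded terms: ",
         paste(rownames(al), collapse = ", "))
  }
  sm <- summary(full)
  ci <- stats::confint(full)
  terms <- c("cell_typehaploid-like", "ploidy1", "matingany")
  coefs <- data.frame(
    term = c("cell_type", "ploidy", "mating_type"),
    estimate = stats::coef(full)[terms],
    ci_lo = ci[terms, 1], ci_hi = ci[terms, 2],
    p = sm$coefficients[terms, 4], row.names = NULL)
  tot_ss <- sum((d$s - mean(d$s))^2)
  # type II: SS of each factor adjusted for the other two
  rss_full <- sum(stats::residuals(full)^2)
  ss2 <- vapply(c("cell_type", "ploidy", "mating"), function(f) {
    red <- stats::lm(stats::reformulate(setdiff(c("cell_type", "ploidy", "mating"), f),
                                        response = "s"), data = d)
    sum(stats::residuals(red)^2) - rss_full
  }, numeric(1))
  a1 <- stats::anova(full)
  ss1 <- a1[c("cell_type", "ploidy", "mating"), "Sum Sq"]
  names(ss1) <- c("cell_type", "ploidy", "mating")
  structure(list(coefficients = coefs,
                 ss_proportion = ss2 / tot_ss,
                 ss_proportion_type1 = ss1 / tot_ss,
                 r_squared = sm$r.squared,
                 df_residual = full$df.residual),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat("<effect_estimates> R2 =", round(x$r_squared, 3),
      " df =", x$df_residual, "\n")
  print(cbind(x$coefficients,
              ss_prop = round(x$ss_proportion[c("cell_type", "ploidy", "mating")], 3)))
  invisible(x)
}

#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over time.
#'
#' @param times hours, strictly increasing, at least 2 points.
#' @param od optical densities, same length.
#' @return area in OD x hours.
#' @export
growth_auc <- function(times, od) {
  stopifnot(length(times) == length(od), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od))) stop("OD series contains non-finite values")
  sum(diff(times) * (utils::head(od, -1) + utils::tail(od, -1)) / 2)
}
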