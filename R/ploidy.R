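#' Fit a constrained 1C/2C/4C DNA-content mixture
#'
#' Maximum-likelihood fit of a 3-component Gaussian mixture to single-cell
#' fluorescence with means constrained to `(mu, 2*mu, 4*mu)`, a shared
#' coefficient of variation, and component weights parameterised by the
#' haploid fraction `h` and a G1 fraction `alpha` shared across ploidies
#' (see [ploidy_mixture_weights()]). Sharing `alpha` makes `h` identifiable
#' from the three peak weights of an asynchronous culture, up to the
#' inherent swap symmetry between `h` and `alpha`; the swap is resolved by
#' picking the orientation whose G1 fraction is closer to `alpha_hint`.
#'
#' The likelihood is maximised by quasi-Newton ascent on transformed
#' parameters (log `mu`, log `cv`, logit `h`, logit `alpha`), multi-started
#' over a grid of `mu` values spanning the 5th to 50th percentile of the
#' intensities. Intensities are binned (default 512 bins) for speed; with
#' peak CVs of a few percent the binned likelihood is numerically
#' indistinguishable from the exact one.
#'
#' @param sample numeric vector of positive fluorescence intensities,
#'   `n >= 500` (a `fluorescence_sample` works as-is).
#' @param init optional list with elements `mu` and `cv` used as the single
#'   starting point instead of the grid.
#' @param n_starts number of `mu` grid starts (default 10).
#' @param alpha_hint expected G1 fraction used to orient the `h`/`alpha`
#'   swap (default 0.6, typical for asynchronous budding yeast).
#' @param mu_bounds optional length-2 vector bounding the 1C peak location.
#'   A sample with only two occupied peaks fits equally well as
#'   `(mu, h = 0)` and `(2 mu, h = 1)`; bounding `mu` — typically from a
#'   ploidy control via [estimate_1c_peak()], mirroring the controls run
#'   alongside every acquisition — removes the ambiguity.
#' @param n_bins histogram bins for the binned likelihood.
#' @return an object of class `ploidy_mixture_fit`: list with `mu`, `cv`,
#'   `h`, `alpha`, `weights`, `loglik`, `converged`, `n`.
#' @export
fit_dna_content_mixture <- function(sample, init = NULL, n_starts = 10,
                                    alpha_hint = 0.6, mu_bounds = NULL,
                                    n_bins = 512) {
  x <- as.numeric(sample)
  if (length(x) < 500) stop("mixture fitting needs at least 500 cells")
  if (any(!is.finite(x)) || any(x <= 0)) stop("intensities must be positive")
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mid <- (br[-1] + br[-length(br)]) / 2
  use <- cnt > 0
  mid <- mid[use]; cnt <- cnt[use]
  k <- c(1, 2, 4)

  nll <- function(par) {
    mu <- exp(par[1]); cv <- exp(par[2])
    h <- stats::plogis(par[3]); a <- stats::plogis(par[4])
    w <- ploidy_mixture_weights(h, a)
    f <- 0
    for (i in 1:3)
      f <- f + w[i] * stats::dnorm(mid, mu * k[i], cv * mu * k[i])
    -sum(cnt * log(f + 1e-300))
  }

  mu_grid <- if (!is.null(init)) init$mu
  else if (!is.null(mu_bounds))
    seq(mu_bounds[1], mu_bounds[2], length.out = min(n_starts, 5))
  else stats::quantile(x, probs = seq(0.05, 0.5, length.out = n_starts))
  cv0 <- if (!is.null(init)) init$cv else 0.08
  lower <- c(if (is.null(mu_bounds)) -Inf else log(mu_bounds[1]),
             rep(-Inf, 3))
  upper <- c(if (is.null(mu_bounds)) Inf else log(mu_bounds[2]),
             rep(Inf, 3))
  best <- NULL
  for (mu0 in mu_grid) {
    for (h0 in c(0.2, 0.8)) {
      par0 <- c(log(mu0), log(cv0), stats::qlogis(h0),
                stats::qlogis(alpha_hint))
      fit <- tryCatch(
        if (is.null(mu_bounds))
          stats::optim(par0, nll, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-10))
        else
          stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) stop("mixture fit failed from every start")
  mu <- exp(best$par[1]); cv <- exp(best$par[2])
  h <- stats::plogis(best$par[3]); a <- stats::plogis(best$par[4])
  # resolve the h <-> alpha swap: the weight map is symmetric in (h, alpha)
  if (abs(h - alpha_hint) < abs(a - alpha_hint)) { tmp <- h; h <- a; a <- tmp }
  structure(list(mu = mu, cv = cv, h = h, alpha = a,
                 weights = ploidy_mixture_weights(h, a),
                 loglik = -best$value, converged = best$convergence == 0,
                 n = length(x)),
            class = "ploidy_mixture_fit")
}

#' @export
print.ploidy_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<ploidy_mixture_fit> n=%d  mu(1C)=%.3g  cv=%.3f  ",
                     "h=%.3f  alpha=%.3f  logLik=%.1f%s\n"),
              x$n, x$mu, x$cv, x$h, x$alpha, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Estimate the G1 peak location of a fluorescence sample
#'
#' The G1 peak (1C peak when the fitted haploid fraction exceeds 0.5, 2C
#' otherwise) is invariant to the two-peak `(mu, h=0)` / `(2 mu, h=1)`
#' ambiguity, so it is the right anchor to extract from a ploidy control.
#'
#' @param sample a `fluorescence_sample`.
#' @return the fitted G1 peak location (same units as the intensities).
#' @export
estimate_1c_peak <- function(sample) {
  f <- fit_dna_content_mixture(sample)
  if (f$h >= 0.5) f$mu else 2 * f$mu
}

#' Classify the ploidy of a clonal sample against a haploid control
#'
#' Fits the DNA-content mixture to both sample and control, takes each
#' fit's G1 peak location (the 1C peak when the fitted haploid fraction
#' exceeds 0.5, the 2C peak otherwise), and rounds the sample/control peak
#' ratio to an integer ploidy. Invariant to a common linear gain applied to
#' both acquisitions.
#'
#' @param sample a `fluorescence_sample` for the query clone.
#' @param haploid_control a `fluorescence_sample` for the 1C control.
#' @param tolerance maximum distance of the peak ratio from an integer
#'   (default 0.25); beyond it the call is indeterminate.
#' @return list with `ploidy` (integer or NA), `ratio`, `status`
#'   ("ok" or "indeterminate").
#' @export
classify_clonal_ploidy <- function(sample, haploid_control, tolerance = 0.25) {
  ratio <- estimate_1c_peak(sample) / estimate_1c_peak(haploid_control)
  pl <- round(ratio)
  if (pl < 1 || abs(ratio - pl) > tolerance)
    return(list(ploidy = NA_integer_, ratio = ratio, status = "indeterminate"))
  list(ploidy = as.integer(pl), ratio = ratio, status = "ok")
}

#' Haploid frequency from colony genotyping with a Wilson interval
#'
#' Pools haploid counts across platings and reports the pooled proportion
#' with a Wilson score 95% interval; per-plating proportions are retained.
#' Because homothallic mating can convert haploids to diploids before
#' genotyping, the estimate is best read as a conservative lower bound on
#' the haploid frequency at sampling.
#'
#' @param n_haploid integer vector of haploid colonies per plating.
#' @param n_total integer vector of total colonies per plating.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `ci` (length-2), `per_plating` data.frame.
#' @export
haploid_frequency_from_colonies <- function(n_haploid, n_total, conf = 0.95) {
  stopifnot(length(n_haploid) == length(n_total), all(n_total >= 1),
            all(n_haploid >= 0), all(n_haploid <= n_total))
  K <- sum(n_haploid); N <- sum(n_total)
  p <- K / N
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / N
  centre <- (p + z^2 / (2 * N)) / denom
  half <- z / denom * sqrt(p * (1 - p) / N + z^2 / (4 * N^2))
  list(estimate = p,
       ci = c(max(0, centre - half), min(1, centre + half)),
       per_plating = data.frame(n_haploid = n_haploid, n_total = n_total,
                                proportion = n_haploid / n_total))
}

#' Exact two-sided binomial test of allele balance
#'
#' Tests observed alternate-allele read counts against an expected fraction
#' `p0` (0.5 for a heterozygous site in a diploid). The two-sided p-value
#' sums the probabilities of all outcomes no more probable than the
#' observed one. With `pooled = TRUE`, counts over multiple sites are summed
#' and tested once; otherwise each site gets its own p-value.
#'
#' @param k alternate-supporting read counts (vector allowed).
#' @param n total read counts; every site needs `n >= 10`.
#' @param p0 expected alternate fraction under the null (default 0.5).
#' @param pooled sum counts across sites before testing.
#' @return numeric p-value(s).
#' @export
allele_balance_test <- function(k, n, p0 = 0.5, pooled = FALSE) {
  stopifnot(length(k) == length(n), all(k >= 0), all(k <= n),
            p0 > 0, p0 < 1)
  if (pooled) { k <- sum(k); n <- sum(n) }
  if (any(n < 10))
    stop("allele balance test requires a minimum coverage depth of 10")
  vapply(seq_along(k), function(i) {
    d <- stats::dbinom(0:n[i], n[i], p0)
    min(1, sum(d[d <= d[k[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}
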