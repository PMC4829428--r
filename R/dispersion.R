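#' Per-feature moment estimates of mean and dispersion
#'
#' For every feature, computes the arithmetic mean of normalized counts per
#' condition, the pooled mean over all samples, and a method-of-moments
#' estimate of the negative-binomial dispersion from the pooled
#' within-condition variance:
#' `alpha_obs = max(0, (s^2 - mu) / mu^2)`,
#' where `s^2` is the within-condition sample variance pooled across
#' conditions and `mu` the pooled mean. Under the NB parameterization used
#' throughout (`variance = mu + alpha * mu^2`), `alpha_obs` is zero for
#' Poisson-like data. If a fitted [DispersionTrend-class] is supplied, the
#' effective dispersion applies it as a floor:
#' `alpha_eff = max(alpha_obs, a0 + a1 / mu)`.
#'
#' @param normalized Numeric matrix of normalized counts (features x
#'   samples).
#' @param condition Condition label per sample (length `ncol(normalized)`).
#' @param trend Optional [DispersionTrend-class] used as the dispersion
#'   floor.
#' @return A data.frame with one row per feature: per-condition means
#'   (`mean_<condition>`), `mu`, `alpha_obs` and (when a trend is given)
#'   `alpha_eff`.
#' @seealso [fitDispersionTrend()]
#' @export
estimateFeatures <- function(normalized, condition, trend = NULL) {
    normalized <- as.matrix(normalized)
    condition <- as.character(condition)
    if (length(condition) != ncol(normalized))
        stop("need one condition per sample")
    conds <- unique(condition)
    if (any(table(condition) < 1L))
        stop("every condition needs at least one sample")
    n <- ncol(normalized)
    mu <- rowMeans(normalized)
    condMeans <- vapply(conds, function(cc)
        rowMeans(normalized[, condition == cc, drop = FALSE]),
        numeric(nrow(normalized)))
    condMeans <- matrix(condMeans, nrow = nrow(normalized),
                        dimnames = list(rownames(normalized), conds))
    # pooled within-condition sum of squares, df = n - #conditions
    ss <- rowSums((normalized - condMeans[, condition, drop = FALSE])^2)
    df <- n - length(conds)
    s2 <- if (df > 0) ss / df else rep(NA_real_, nrow(normalized))
    alpha_obs <- ifelse(mu > 0 & is.finite(s2),
                        pmax(0, (s2 - mu) / mu^2), 0)
    out <- data.frame(feature_id = rownames(normalized), mu = mu,
                      alpha_obs = alpha_obs, row.names = NULL,
                      stringsAsFactors = FALSE)
    for (cc in conds) out[[paste0("mean_", cc)]] <- condMeans[, cc]
    if (!is.null(trend)) {
        floorDisp <- ifelse(mu > 0, trendDispersion(trend, pmax(mu, 1e-12)),
                            trend@a0)
        out$alpha_eff <- pmax(alpha_obs, floorDisp)
    }
    out
}

#' Fit the dispersion-mean trend
#'
#' Least-squares fit of `alpha_obs = a0 + a1 / mu` over features with
#' positive mean and positive observed dispersion, with both coefficients
#' constrained non-negative (the best boundary fit is used when the
#' unconstrained solution goes negative). The fitted trend serves as the
#' per-feature dispersion floor in the Monte-Carlo test.
#'
#' @param mu Numeric vector of pooled normalized means, or the data.frame
#'   returned by [estimateFeatures()].
#' @param alpha_obs Observed dispersions (ignored when `mu` is a
#'   data.frame).
#' @param minFeatures Minimum number of usable features (default 20).
#' @return A [DispersionTrend-class].
#' @export
fitDispersionTrend <- function(mu, alpha_obs = NULL, minFeatures = 20L) {
    if (is.data.frame(mu)) {
        alpha_obs <- mu$alpha_obs
        mu <- mu$mu
    }
    use <- is.finite(mu) & is.finite(alpha_obs) & mu > 0 & alpha_obs > 0
    if (sum(use) < minFeatures)
        stop("fewer than ", minFeatures, " features with positive mean and ",
             "dispersion; supply a constant dispersion via dispersionTrend()")
    a <- alpha_obs[use]
    x <- 1 / mu[use]
    sse <- function(a0, a1) sum((a - a0 - a1 * x)^2)
    fit <- stats::lm.fit(cbind(1, x), a)
    cand <- list(fit$coefficients)
    # boundary fits for the non-negativity constraint
    cand <- c(cand,
              list(c(0, max(0, sum(a * x) / sum(x^2))),
                   c(max(0, mean(a)), 0)))
    cand <- lapply(cand, function(cf) pmax(cf, 0))
    errs <- vapply(cand, function(cf) sse(cf[1L], cf[2L]), numeric(1))
    best <- cand[[which.min(errs)]]
    dispersionTrend(unname(best[1L]), unname(best[2L]))
}
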