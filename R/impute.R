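#' Estimate Normal parameters under left-censoring
#'
#' Quantile-regression estimate of the mean and standard deviation of a
#' Normal variable observed only above a detection limit.  The observed
#' values are sorted; the value of observed rank \eqn{r} (so overall rank
#' \eqn{r + m} among \eqn{n = n_{obs} + m} with \eqn{m} censored points)
#' is assigned plotting position \eqn{(r + m - 0.5)/n}, and the sorted
#' values are regressed on the corresponding standard-normal quantiles
#' over the upper part of the distribution (plotting positions above
#' \code{min_quantile}).  The slope estimates the standard deviation, the
#' intercept the mean.
#'
#' @param observed numeric vector of >= 5 observed (non-censored) values.
#' @param missing_count number of left-censored values.
#' @param min_quantile lower bound of the plotting positions used in the
#'   regression (default 0.25), for robustness against tail irregularity.
#' @return list(\code{mu}, \code{sigma}).
#' @examples
#' x <- qnorm(seq(0.21, 0.999, by = 0.002), 10, 2)  # lowest 20% censored
#' estimateTruncatedNormal(x, missing_count = 100)
#' @export
estimateTruncatedNormal <- function(observed, missing_count,
                                    min_quantile = 0.25) {
  observed <- observed[is.finite(observed)]
  if (length(observed) < 5L)
    stop("fewer than 5 observed values: drop this column instead")
  stopifnot(missing_count >= 0, min_quantile >= 0, min_quantile < 1)
  n_obs <- length(observed)
  n_tot <- n_obs + missing_count
  pp <- (seq_len(n_obs) + missing_count - 0.5) / n_tot
  y <- sort(observed)
  use <- pp > min_quantile
  if (sum(use) < 3L) use <- rep(TRUE, n_obs)
  q <- qnorm(pp[use])
  fit <- lm(y[use] ~ q)
  sigma <- unname(coef(fit)[2])
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate (near-constant) observed data: sigma estimate is not positive")
  list(mu = unname(coef(fit)[1]), sigma = sigma)
}

.qrilcColumn <- function(values, tune_sigma, min_quantile) {
  miss <- which(is.na(values))
  if (!length(miss)) return(list(values = values, n = 0L, draws = numeric(0)))
  obs <- values[-miss]
  if (!length(obs)) stop("column entirely missing: cannot impute")
  est <- estimateTruncatedNormal(obs, missing_count = length(miss),
                                 min_quantile = min_quantile)
  s <- est$sigma * tune_sigma
  hi <- min(obs)
  lo <- 0
  p_lo <- pnorm(lo, est$mu, s)
  p_hi <- pnorm(hi, est$mu, s)
  if (p_hi <= p_lo) p_lo <- 0   # upper bound below zero-floor: drop the floor
  u <- runif(length(miss), p_lo, p_hi)
  draws <- qnorm(u, est$mu, s)
  draws <- pmin(draws, hi * (1 - sign(hi) * 1e-12))  # strictly below min(obs)
  values[miss] <- draws
  list(values = values, n = length(miss), draws = draws,
       mu = est$mu, sigma = est$sigma, limit = hi)
}

#' QRILC imputation of left-censored missing values
#'
#' Quantile regression imputation of left-censored data: per lipid, the
#' underlying Normal mean and standard deviation are estimated from the
#' observed quantiles ([estimateTruncatedNormal()]) and each missing value
#' is drawn from that Normal truncated above at the lipid's minimum
#' observed value (and below at 0).  Observed entries are untouched;
#' lipids with no missing values pass through identically; the draw is
#' deterministic given \code{seed}.
#'
#' @param x a \linkS4class{LipidomicsExperiment} (the named assay,
#'   study samples only, is imputed) or a samples x lipids matrix whose
#'   columns are lipids.
#' @param seed integer seed for the truncated draws.
#' @param tune_sigma multiplier on the estimated standard deviation used
#'   for the draws (default 1).
#' @param min_quantile passed to [estimateTruncatedNormal()].
#' @param assay assay to impute for the experiment method
#'   (default \code{"concentrations"}).
#' @return For a matrix: list(\code{completed}, \code{log}) where
#'   \code{log} is a data.frame recording lipid, count, estimated
#'   parameters, detection limit and each draw.  For an experiment: the
#'   experiment with the assay completed on study samples and the log in
#'   \code{metadata(x)$imputation_log}.
#' @export
setGeneric("qrilcImpute",
           function(x, seed = 17L, tune_sigma = 1, min_quantile = 0.25,
                    assay = "concentrations")
             standardGeneric("qrilcImpute"))

#' @rdname qrilcImpute
setMethod("qrilcImpute", "matrix",
          function(x, seed = 17L, tune_sigma = 1, min_quantile = 0.25,
                   assay = "concentrations") {
  stopifnot(tune_sigma > 0)
  logs <- list()
  out <- x
  .withSeed(seed, {
    for (j in seq_len(ncol(x))) {
      if (!anyNA(x[, j])) next
      res <- .qrilcColumn(x[, j], tune_sigma, min_quantile)
      out[, j] <- res$values
      nm <- if (is.null(colnames(x))) as.character(j) else colnames(x)[j]
      logs[[length(logs) + 1L]] <-
        data.frame(lipid = nm, n_imputed = res$n, mu = res$mu,
                   sigma = res$sigma, limit = res$limit,
                   draw = res$draws, stringsAsFactors = FALSE)
    }
  })
  log <- if (length(logs)) do.call(rbind, logs)
         else data.frame(lipid = character(0), n_imputed = integer(0),
                         mu = numeric(0), sigma = numeric(0),
                         limit = numeric(0), draw = numeric(0))
  list(completed = out, log = log)
})

#' @rdname qrilcImpute
setMethod("qrilcImpute", "LipidomicsExperiment",
          function(x, seed = 17L, tune_sigma = 1, min_quantile = 0.25,
                   assay = "concentrations") {
  a <- SummarizedExperiment::assay(x, assay)
  st <- sampleRoles(x) == "study"
  res <- qrilcImpute(t(a[, st, drop = FALSE]), seed = seed,
                     tune_sigma = tune_sigma, min_quantile = min_quantile)
  a[, st] <- t(res$completed)
  SummarizedExperiment::assay(x, assay) <- a
  S4Vectors::metadata(x)$imputation_log <- res$log
  x
})
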