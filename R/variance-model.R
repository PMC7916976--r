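# ---- profiled REML machinery for the random-intercept model ----------------
#
# Model: y = X beta + Z b + e, b ~ N(0, sigma2_bs I_m), e ~ N(0, sigma2_ws I_n),
# Z the subject indicator matrix.  With lambda = sigma2_bs / sigma2_ws,
# V* = I + lambda Z Z' is block diagonal, so every quantity reduces to
# per-subject group sums:
#   V*_i^{-1} = I - (lambda / (1 + lambda n_i)) J.
# The restricted likelihood is profiled over beta (GLS) and sigma2_ws
# (closed form), leaving a smooth scalar criterion in lambda that is
# minimized over log(lambda) in [-12, 12] and polished by root-finding on
# its analytic derivative; the boundary lambda = 0 is evaluated explicitly.

.remlPieces <- function(y, X, gi, ni, lambda) {
  n <- length(y); p <- ncol(X)
  G1X <- rowsum(X, gi, reorder = TRUE)
  G1y <- rowsum(y, gi, reorder = TRUE)[, 1]
  w <- lambda / (1 + lambda * ni)
  M <- crossprod(X) - crossprod(G1X, w * G1X)
  v <- drop(crossprod(X, y)) - drop(crossprod(G1X, w * G1y))
  qyy <- sum(y^2) - sum(w * G1y^2)
  Mi <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Mi)) return(NULL)
  beta <- drop(Mi %*% v)
  rss <- qyy - sum(beta * v)
  rss <- max(rss, 0)
  list(beta = beta, rss = rss, M = M, Mi = Mi,
       logdetM = as.numeric(determinant(M)$modulus),
       logdetVstar = sum(log1p(lambda * ni)),
       G1X = G1X, G1y = G1y, n = n, p = p)
}

# profiled criterion to MINIMIZE: (n-p) log rss + log|V*| + log|X'V*^-1 X|
.remlCriterion <- function(y, X, gi, ni, lambda) {
  pc <- .remlPieces(y, X, gi, ni, lambda)
  if (is.null(pc) || pc$rss <= 0) return(Inf)
  (pc$n - pc$p) * log(pc$rss) + pc$logdetVstar + pc$logdetM
}

# analytic derivative of the criterion wrt lambda
.remlCriterionGrad <- function(y, X, gi, ni, lambda) {
  pc <- .remlPieces(y, X, gi, ni, lambda)
  if (is.null(pc) || pc$rss <= 0) return(NA_real_)
  d <- 1 + lambda * ni
  A <- t(pc$G1X / d)                       # p x m, columns a_i
  tvec <- (pc$G1y - drop(pc$G1X %*% pc$beta)) / d
  drss <- -sum(tvec^2)
  (pc$n - pc$p) * drss / pc$rss + sum(ni / d) - sum(A * (pc$Mi %*% A))
}

# restricted log-likelihood at explicit (sigma2_bs, sigma2_ws)
.remlLoglikTheta <- function(y, X, gi, ni, s2b, s2w) {
  lambda <- s2b / s2w
  pc <- .remlPieces(y, X, gi, ni, lambda)
  if (is.null(pc)) return(NA_real_)
  np <- pc$n - pc$p
  -0.5 * (np * log(2 * pi) + np * log(s2w) + pc$logdetVstar +
            pc$logdetM + pc$rss / s2w)
}

.designMatrix <- function(data, fixed) {
  mf <- stats::model.frame(fixed, data = data, na.action = stats::na.pass,
                           drop.unused.levels = TRUE)
  X <- stats::model.matrix(fixed, mf)
  # drop constant (degenerate) non-intercept columns, then rank-trim
  keep <- colnames(X) == "(Intercept)" | apply(X, 2, function(z) var(z) > 0)
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

#' Fit a random-intercept mixed model by profiled REML
#'
#' Estimates between-participant variance \eqn{\sigma^2_{BS}} (random
#' intercept), within-participant variance \eqn{\sigma^2_{WS}} (residual)
#' and fixed effects by restricted maximum likelihood.  For each candidate
#' variance ratio \eqn{\lambda = \sigma^2_{BS}/\sigma^2_{WS}} the fixed
#' effects are solved by generalized least squares and the residual
#' variance is profiled in closed form; the restricted criterion is
#' minimized over \eqn{\log\lambda \in [-12, 12]} and refined by
#' root-finding on its analytic derivative (the boundary
#' \eqn{\lambda = 0} is evaluated explicitly, and a negative
#' between-participant variance is truncated at the boundary).  The
#' standard error of \eqn{\sigma^2_{BS}} is obtained from the observed
#' information (numerical second derivatives of the restricted
#' log-likelihood in the two variances) at the optimum.
#'
#' @param data data.frame with columns \code{subject_id},
#'   \code{concentration} and any fixed-effect covariates (typically
#'   \code{timepoint} and \code{order}).
#' @param fixed one-sided formula for the fixed effects; terms whose
#'   covariates are absent or constant are dropped automatically.
#' @return A \linkS4class{VarianceComponentsFit}.
#' @examples
#' cfg <- studyConfig(n_subjects = 8, seed = 3)
#' sim <- simulateStudy(cfg)
#' d <- data.frame(SummarizedExperiment::colData(sim$experiment))
#' d$concentration <- sim$truth$concentrations["PC 34:1", d$sample_id]
#' fitRandomIntercept(d)
#' @export
fitRandomIntercept <- function(data, fixed = ~ timepoint + order) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "concentration") %in% colnames(data)))
  vars <- all.vars(fixed)
  vars <- vars[vars %in% colnames(data)]
  fixed <- if (length(vars))
    stats::reformulate(vars) else ~ 1
  data <- data[is.finite(data$concentration), , drop = FALSE]
  # reference levels: morning / morning-first when those labels are used
  preferred <- list(timepoint = c("morning", "evening"),
                    order = c("morning-first", "evening-first"))
  for (cn in intersect(names(preferred), colnames(data))) {
    if (!is.factor(data[[cn]]) &&
        all(unique(data[[cn]]) %in% preferred[[cn]]))
      data[[cn]] <- factor(data[[cn]], levels = preferred[[cn]])
  }
  g <- factor(data$subject_id)
  if (nlevels(g) < 2) stop("need >= 2 subjects with data")
  y <- data$concentration
  X <- .designMatrix(data, fixed)
  n <- length(y); p <- ncol(X)
  if (n - p < 2) stop("not enough observations for the design")
  gi <- as.integer(g)
  ni <- as.integer(table(gi))
  # classify non-intercept columns as within- or between-subject
  nonint <- setdiff(colnames(X), "(Intercept)")
  within <- vapply(nonint, function(cn) {
    any(tapply(X[, cn], gi, function(z) length(unique(z)) > 1L))
  }, logical(1))
  if (var(y) == 0) {
    return(methods::new("VarianceComponentsFit",
      sigma2_bs = 0, sigma2_ws = 0, se_sigma2_bs = NA_real_,
      beta = setNames(c(y[1], rep(0, p - 1L)), colnames(X)),
      se_beta = setNames(rep(NA_real_, p), colnames(X)),
      reml_loglik = NA_real_, n_obs = n, n_subjects = nlevels(g),
      terms = colnames(X), boundary = TRUE, degenerate = TRUE,
      convergence = list(message = "constant response", within = within)))
  }
  crit <- function(ll) .remlCriterion(y, X, gi, ni, exp(ll))
  opt <- optimize(crit, interval = c(-12, 12), tol = 1e-10)
  ll_hat <- opt$minimum
  # polish: root of the analytic derivative near the optimizer solution
  gfun <- function(ll) {
    gg <- .remlCriterionGrad(y, X, gi, ni, exp(ll)) * exp(ll)
    if (is.na(gg)) 0 else gg
  }
  lo <- ll_hat - 0.7; hi <- min(ll_hat + 0.7, 12)
  glo <- gfun(lo); ghi <- gfun(hi)
  if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0) {
    rt <- tryCatch(uniroot(gfun, c(lo, hi), tol = 1e-13),
                   error = function(e) NULL)
    if (!is.null(rt) && crit(rt$root) <= opt$objective + 1e-9)
      ll_hat <- rt$root
  }
  f_hat <- crit(ll_hat)
  f_zero <- .remlCriterion(y, X, gi, ni, 0)
  boundary <- is.finite(f_zero) && f_zero <= f_hat
  lambda <- if (boundary) 0 else exp(ll_hat)
  pc <- .remlPieces(y, X, gi, ni, lambda)
  if (is.null(pc) || pc$rss <= 0)
    stop("REML fit failed: singular generalized least squares system")
  s2w <- pc$rss / (n - p)
  s2b <- lambda * s2w
  loglik <- .remlLoglikTheta(y, X, gi, ni, s2b, s2w)
  # observed information in (sigma2_bs, sigma2_ws) by central differences
  se_s2b <- NA_real_
  info_ok <- FALSE
  if (!boundary) {
    h <- 1e-4 * c(max(s2b, 1e-3 * s2w), s2w)
    f2 <- function(th) .remlLoglikTheta(y, X, gi, ni, th[1], th[2])
    th0 <- c(s2b, s2w)
    H <- matrix(NA_real_, 2, 2)
    for (a in 1:2) for (b in 1:2) {
      if (b < a) { H[a, b] <- H[b, a]; next }
      ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
      if (a == b) {
        H[a, b] <- (f2(th0 + ea) - 2 * f2(th0) + f2(th0 - ea)) / h[a]^2
      } else {
        H[a, b] <- (f2(th0 + ea + eb) - f2(th0 + ea - eb) -
                      f2(th0 - ea + eb) + f2(th0 - ea - eb)) /
          (4 * h[a] * h[b])
      }
    }
    if (all(is.finite(H))) {
      cov <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(cov) && cov[1, 1] > 0) {
        se_s2b <- sqrt(cov[1, 1])
        info_ok <- TRUE
      }
    }
  }
  se_beta <- sqrt(pmax(diag(pc$Mi), 0) * s2w)
  methods::new("VarianceComponentsFit",
    sigma2_bs = s2b, sigma2_ws = s2w, se_sigma2_bs = se_s2b,
    beta = setNames(pc$beta, colnames(X)),
    se_beta = setNames(se_beta, colnames(X)),
    reml_loglik = loglik, n_obs = n, n_subjects = nlevels(g),
    terms = colnames(X), boundary = boundary, degenerate = FALSE,
    convergence = list(lambda = lambda, criterion = f_hat,
                       criterion_zero = f_zero, info_ok = info_ok,
                       within = within))
}

#' Intraclass correlation from a variance-components fit
#'
#' \eqn{ICC = \sigma^2_{BS} / (\sigma^2_{BS} + \sigma^2_{WS})}, the
#' proportion of total variance attributable to stable between-participant
#' differences, with the conventional benchmark labels on half-open
#' ranges: below 0.4 \emph{below-moderate}, \[0.4, 0.6) \emph{moderate},
#' \[0.6, 0.8) \emph{substantial}, \[0.8, 1\] \emph{almost perfect}.
#'
#' @param fit a \linkS4class{VarianceComponentsFit}.
#' @return list(\code{icc}, \code{label}, \code{z}, \code{p_z},
#'   \code{undefined}); \code{icc} is \code{NA} (flagged) when both
#'   variances are zero.
#' @export
iccFromFit <- function(fit) {
  stopifnot(methods::is(fit, "VarianceComponentsFit"))
  tot <- fit@sigma2_bs + fit@sigma2_ws
  if (tot <= 0)
    return(list(icc = NA_real_, label = NA_character_, z = NA_real_,
                p_z = NA_real_, undefined = TRUE))
  icc <- fit@sigma2_bs / tot
  label <- iccLabel(icc)
  wz <- waldZTest(fit)
  list(icc = icc, label = label, z = wz$z, p_z = wz$p, undefined = FALSE)
}

#' @describeIn iccFromFit benchmark label for an ICC value (vectorised).
#' @param icc numeric ICC value(s) in \[0, 1\].
#' @export
iccLabel <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("below-moderate", "moderate", "substantial",
                 "almost perfect")) |> as.character()
}

#' Wald Z-test of the between-participant variance
#'
#' \eqn{Z = \hat\sigma^2_{BS} / \mathrm{se}(\hat\sigma^2_{BS})} with a
#' one-sided p-value from the upper Normal tail (a variance component is
#' one-sided by nature).  When the fit sits on the \eqn{\sigma^2_{BS}=0}
#' boundary or the information matrix is singular, the standard error is
#' undefined and p is reported as 1 with a flag.
#'
#' @param fit a \linkS4class{VarianceComponentsFit}.
#' @return list(\code{z}, \code{p}, \code{se_undefined}).
#' @export
waldZTest <- function(fit) {
  stopifnot(methods::is(fit, "VarianceComponentsFit"))
  se <- fit@se_sigma2_bs
  if (!is.finite(se) || se <= 0)
    return(list(z = NA_real_, p = 1, se_undefined = TRUE))
  z <- fit@sigma2_bs / se
  list(z = z, p = pnorm(z, lower.tail = FALSE), se_undefined = FALSE)
}

#' F-test of a fixed effect
#'
#' Single-degree-of-freedom Wald F: \eqn{F = (\hat\beta / se)^2} with
#' numerator df 1 and denominator df by containment: for a
#' within-subject term (e.g. time of day),
#' \eqn{df = n_{obs} - n_{subjects} - (q_w + 1)} where \eqn{q_w} counts
#' within-subject fixed-effect columns; for a between-subject term (e.g.
#' collection order), \eqn{df = n_{subjects} - (q_b + 1)} with \eqn{q_b}
#' the between-subject columns.  Both give df 18 in the full 20-subject
#' two-timepoint design.  \code{df_method = "residual"} uses
#' \eqn{n_{obs} - p} instead.
#'
#' @param fit a \linkS4class{VarianceComponentsFit}.
#' @param term fixed-effect term name (a design-column prefix, e.g.
#'   \code{"timepoint"} or \code{"order"}).
#' @param df_method \code{"containment"} (default) or \code{"residual"}.
#' @return list(\code{term}, \code{f}, \code{df_num}, \code{df_den},
#'   \code{p}).
#' @export
fixedEffectFTest <- function(fit, term, df_method = c("containment",
                                                      "residual")) {
  stopifnot(methods::is(fit, "VarianceComponentsFit"))
  df_method <- match.arg(df_method)
  cols <- setdiff(fit@terms, "(Intercept)")
  hit <- cols[startsWith(cols, term)]
  if (length(hit) != 1L)
    stop("term '", term, "' not identifiable in the design (dropped for ",
         "rank deficiency or absent)")
  beta <- fit@beta[hit]; se <- fit@se_beta[hit]
  f <- (beta / se)^2
  within <- fit@convergence$within
  q_w <- sum(within); q_b <- sum(!within)
  df_den <- if (df_method == "residual") {
    fit@n_obs - length(fit@terms)
  } else if (isTRUE(within[hit])) {
    fit@n_obs - fit@n_subjects - (q_w + 1L)
  } else {
    fit@n_subjects - (q_b + 1L)
  }
  if (df_den < 1L) df_den <- 1L
  list(term = term, f = unname(f), df_num = 1L, df_den = df_den,
       p = unname(pf(f, 1, df_den, lower.tail = FALSE)))
}

#' Per-lipid (or per-class) variance-components panel fit
#'
#' Fits the random-intercept REML model to every lipid species, or to
#' class totals (member species summed per sample before fitting), and
#' tabulates variance components, ICC with benchmark label, the Wald Z
#' test of the between-participant variance and containment F-tests of
#' the fixed effects.
#'
#' @param x a \linkS4class{LipidomicsExperiment} with study samples, or a
#'   samples x lipids concentration matrix plus \code{metadata}.
#' @param metadata for the matrix method: data.frame with
#'   \code{sample_id}, \code{subject_id}, \code{timepoint}, \code{order}.
#' @param level \code{"species"} (each lipid separately) or
#'   \code{"class"} (totals per lipid class).
#' @param assay assay name for the experiment method.
#' @param fixed fixed-effect formula, see [fitRandomIntercept()].
#' @return data.frame, one row per unit: \code{lipid}, \code{level},
#'   \code{sigma2_bs}, \code{sigma2_ws}, \code{icc}, \code{icc_label},
#'   \code{z}, \code{p_z}, \code{f_time}, \code{p_time}, \code{f_order},
#'   \code{p_order}, \code{boundary}, \code{n_obs}.  Units with fewer
#'   than 4 usable records are skipped and listed in
#'   \code{attr(result, "skipped")}.
#' @export
setGeneric("fitVariancePanel",
           function(x, metadata = NULL, level = c("species", "class"),
                    assay = "concentrations", fixed = ~ timepoint + order)
             standardGeneric("fitVariancePanel"))

#' @rdname fitVariancePanel
setMethod("fitVariancePanel", "matrix",
          function(x, metadata = NULL, level = c("species", "class"),
                   assay = "concentrations", fixed = ~ timepoint + order) {
  level <- match.arg(level)
  stopifnot(!is.null(metadata),
            all(c("sample_id", "subject_id", "timepoint") %in%
                  colnames(metadata)))
  metadata <- as.data.frame(metadata)
  if (!all(rownames(x) %in% metadata$sample_id))
    stop("metadata does not cover all samples")
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  if (level == "class") {
    cls <- parseLipidNames(colnames(x))$lipid_class
    x <- sapply(split(seq_len(ncol(x)), cls), function(jj)
      rowSums(x[, jj, drop = FALSE]))
  }
  units <- colnames(x)
  skipped <- character(0)
  rows <- vector("list", length(units))
  for (j in seq_along(units)) {
    y <- x[, j]
    usable <- sum(is.finite(y))
    if (usable < 4L) {
      skipped <- c(skipped, units[j])
      next
    }
    d <- cbind(md, concentration = y)
    fit <- fitRandomIntercept(d, fixed = fixed)
    ic <- iccFromFit(fit)
    ftime <- tryCatch(fixedEffectFTest(fit, "timepoint"),
                      error = function(e) list(f = NA_real_, p = NA_real_))
    ford <- tryCatch(fixedEffectFTest(fit, "order"),
                     error = function(e) list(f = NA_real_, p = NA_real_))
    rows[[j]] <- data.frame(
      lipid = units[j], level = level,
      sigma2_bs = fit@sigma2_bs, sigma2_ws = fit@sigma2_ws,
      icc = ic$icc, icc_label = if (is.na(ic$icc)) NA_character_
                                else ic$label,
      z = ic$z, p_z = ic$p_z,
      f_time = ftime$f, p_time = ftime$p,
      f_order = ford$f, p_order = ford$p,
      boundary = fit@boundary, n_obs = fit@n_obs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
})

#' @rdname fitVariancePanel
setMethod("fitVariancePanel", "LipidomicsExperiment",
          function(x, metadata = NULL, level = c("species", "class"),
                   assay = "concentrations", fixed = ~ timepoint + order) {
  st <- studySamples(x)
  mat <- t(SummarizedExperiment::assay(st, assay))
  md <- data.frame(SummarizedExperiment::colData(st))
  fitVariancePanel(mat, metadata = md, level = level, fixed = fixed)
})
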