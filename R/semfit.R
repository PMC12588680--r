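# Maximum-likelihood observed-variable path models: covariance-structure
# fitting, fit indices (chi-square, RMSEA, AIC, SRMR, CFI), standardized
# coefficients and the correlated-endpoint Bonferroni adjustment.

#' Read a path model from a text file
#'
#' One directed edge per line, \code{from -> to}; blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param path model file.
#' @return A [PathModel-class].
#' @export
readPathModel <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  m <- regmatches(lines, regexec("^(\\S+)\\s*->\\s*(\\S+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("unparseable model line(s): ", paste(lines[bad], collapse = "; "))
  PathModel(data.frame(from = vapply(m, `[`, "", 2),
                       to = vapply(m, `[`, "", 3)))
}

# Model-implied covariance: Sigma = (I-A)^-1 Psi (I-A)^-T with A holding path
# coefficients [to, from], Psi the exogenous covariance block plus diagonal
# endogenous residual variances.
.impliedSigma <- function(theta, layout) {
  p <- length(layout$vars)
  A <- matrix(0, p, p, dimnames = list(layout$vars, layout$vars))
  for (k in seq_len(nrow(layout$edges)))
    A[layout$edges$to[k], layout$edges$from[k]] <- theta[layout$coefIdx[k]]
  Psi <- matrix(0, p, p, dimnames = list(layout$vars, layout$vars))
  for (k in seq_along(layout$endo))
    Psi[layout$endo[k], layout$endo[k]] <- exp(theta[layout$residIdx[k]])
  for (k in seq_along(layout$exog))
    Psi[layout$exog[k], layout$exog[k]] <- exp(theta[layout$exvarIdx[k]])
  if (length(layout$exog) > 1) {
    pairs <- layout$excovPairs
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      Psi[a, b] <- Psi[b, a] <- theta[layout$excovIdx[k]]
    }
  }
  IA <- diag(p) - A
  IAinv <- solve(IA)
  IAinv %*% Psi %*% t(IAinv)
}

.fml <- function(theta, layout, S, logDetS) {
  Sigma <- .impliedSigma(theta, layout)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logDet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logDet + tr - logDetS - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

# Start values from the sample covariance: equation-wise regression
# coefficients plus Schur-complement residual variances (exact ML for
# recursive models with independent errors).
.startValues <- function(layout, S) {
  theta <- numeric(layout$nFree)
  for (v in layout$endo) {
    pa <- layout$edges$from[layout$edges$to == v]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    theta[layout$coefIdx[layout$edges$to == v]] <- b
    rv <- S[v, v] - sum(b * S[pa, v])
    theta[layout$residIdx[match(v, layout$endo)]] <- log(max(rv, 1e-8))
  }
  for (k in seq_along(layout$exog))
    theta[layout$exvarIdx[k]] <- log(max(S[layout$exog[k], layout$exog[k]], 1e-8))
  if (length(layout$exog) > 1) {
    pairs <- layout$excovPairs
    for (k in seq_len(ncol(pairs)))
      theta[layout$excovIdx[k]] <- S[pairs[1, k], pairs[2, k]]
  }
  theta
}

.modelLayout <- function(model) {
  vars <- model@variables
  edges <- model@edges
  endo <- unique(edges$to)
  exog <- setdiff(vars, endo)
  nE <- nrow(edges)
  coefIdx <- seq_len(nE)
  residIdx <- nE + seq_along(endo)
  exvarIdx <- nE + length(endo) + seq_along(exog)
  excovPairs <- if (length(exog) > 1) utils::combn(exog, 2) else
    matrix(character(0), nrow = 2)
  excovIdx <- nE + length(endo) + length(exog) + seq_len(ncol(excovPairs))
  list(vars = vars, edges = edges, endo = endo, exog = exog,
       coefIdx = coefIdx, residIdx = residIdx, exvarIdx = exvarIdx,
       excovPairs = excovPairs, excovIdx = excovIdx,
       nFree = nE + length(endo) + length(exog) + ncol(excovPairs))
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \code{F = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p}
#' over the free parameters (one coefficient per edge, one residual variance
#' per endogenous variable, free variances/covariances among exogenous
#' variables). Fit indices: \code{chi2 = (n-1) F},
#' \code{RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1)))} (0 when df = 0),
#' \code{AIC = chi2 + 2 q}, plus SRMR and CFI. Standardized coefficients are
#' \code{S = b * SD(from) / SD(to)} on the model-implied scale. Standard
#' errors come from the inverse Hessian of the discrepancy,
#' \code{acov = 2/(n-1) H^-1}.
#'
#' @param model a [PathModel-class].
#' @param data data.frame containing every model variable; incomplete rows
#'   are dropped (listwise deletion).
#' @param maxIter optimizer iteration budget.
#' @return A [SEMFit-class].
#' @export
fitPathModel <- function(model, data, maxIter = 1000) {
  validObject(model)
  layout <- .modelLayout(model)
  miss <- setdiff(layout$vars, names(data))
  if (length(miss))
    stop("data lacks model variable(s): ", paste(miss, collapse = ", "))
  d <- data[layout$vars]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  q <- layout$nFree
  if (n <= q)
    stop(sprintf("n = %d complete cases cannot identify %d free parameters", n, q))
  S <- stats::cov(d)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12)
    stop("sample covariance matrix is not positive definite")
  logDetS <- determinant(S, logarithm = TRUE)$modulus

  theta0 <- .startValues(layout, S)
  opt <- stats::optim(theta0, .fml, layout = layout, S = S, logDetS = logDetS,
                      method = "BFGS",
                      control = list(maxit = maxIter, reltol = 1e-14))
  if (opt$convergence != 0) {
    gr <- tryCatch(max(abs(stats::optimHess(opt$par, .fml, layout = layout,
                                            S = S, logDetS = logDetS))),
                   error = function(e) NA_real_)
    stop(sprintf("ML fit did not converge within %d iterations (code %d, last curvature %.3g)",
                 maxIter, opt$convergence, gr))
  }
  theta <- opt$par
  Fmin <- max(opt$value, 0)
  p <- length(layout$vars)
  df <- p * (p + 1) / 2 - q
  chi2 <- (n - 1) * Fmin
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  aic <- chi2 + 2 * q

  Sigma <- .impliedSigma(theta, layout)
  dimnames(Sigma) <- dimnames(S)

  H <- tryCatch(stats::optimHess(theta, .fml, layout = layout, S = S,
                                 logDetS = logDetS), error = function(e) NULL)
  se <- rep(NA_real_, q)
  if (!is.null(H)) {
    acov <- tryCatch(solve(H) * 2 / (n - 1), error = function(e) NULL)
    if (!is.null(acov)) {
      dg <- diag(acov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }

  est <- theta[layout$coefIdx]
  sec <- se[layout$coefIdx]
  stdOf <- function(th) {
    Sg <- .impliedSigma(th, layout)
    sdv <- sqrt(diag(Sg))
    names(sdv) <- layout$vars
    th[layout$coefIdx] * sdv[layout$edges$from] / sdv[layout$edges$to]
  }
  std <- stdOf(theta)
  # delta-method SEs for the standardized coefficients
  seStd <- rep(NA_real_, length(est))
  if (!is.null(H)) {
    acov <- tryCatch(solve(H) * 2 / (n - 1), error = function(e) NULL)
    if (!is.null(acov)) {
      eps <- 1e-6
      G <- vapply(seq_along(theta), function(j) {
        tp <- theta; tp[j] <- tp[j] + eps
        tm <- theta; tm[j] <- tm[j] - eps
        (stdOf(tp) - stdOf(tm)) / (2 * eps)
      }, numeric(length(est)))
      G <- matrix(G, nrow = length(est))
      v <- diag(G %*% acov %*% t(G))
      seStd[v > 0] <- sqrt(v[v > 0])
    }
  }
  z <- est / sec
  estimates <- data.frame(
    from = layout$edges$from, to = layout$edges$to,
    est = est, se = sec, z = z,
    p = 2 * stats::pnorm(-abs(z)), std = std, se_std = seStd,
    row.names = NULL)

  Dhalf <- diag(1 / sqrt(diag(S)))
  R <- Dhalf %*% (S - Sigma) %*% Dhalf
  srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  SigB <- diag(diag(S))
  Fb <- determinant(SigB, logarithm = TRUE)$modulus +
    sum(diag(solve(SigB) %*% S)) - logDetS - p
  chi2b <- (n - 1) * as.numeric(Fb)
  dfb <- p * (p - 1) / 2
  cfi <- 1 - max(chi2 - df, 0) / max(chi2b - dfb, chi2 - df, .Machine$double.eps)

  new("SEMFit", estimates = estimates, chi2 = chi2, df = as.numeric(df),
      rmsea = rmsea, aic = aic, srmr = as.numeric(srmr), cfi = cfi,
      n = as.numeric(n), nFree = as.numeric(q), converged = TRUE,
      impliedCov = Sigma)
}

#' Correlated-endpoint Bonferroni adjustment
#'
#' Adjusted significance level
#' \code{alpha_adj = 1 - (1 - alpha)^(1 / m^(1 - rbar))} for m tests with
#' average absolute correlation \code{rbar} between the tested parameters.
#' At \code{rbar = 0} this is the Sidak/Bonferroni level; as \code{rbar}
#' rises to 1 the correction weakens until no adjustment remains.
#'
#' @param pValues vector of p-values (m tests).
#' @param meanAbsCorrelation average absolute correlation \code{rbar} in
#'   [0, 1].
#' @param alpha nominal level (default 0.05).
#' @return list: \code{alpha_adjusted}, \code{significant} (logical per
#'   p-value), \code{m}, \code{rbar}.
#' @export
#' @examples
#' adjustedBonferroni(c(0.001, 0.03), meanAbsCorrelation = 0.5)
adjustedBonferroni <- function(pValues, meanAbsCorrelation, alpha = 0.05) {
  if (!length(pValues)) stop("pValues must be nonempty")
  r <- meanAbsCorrelation
  if (!is.finite(r) || r < 0 || r > 1)
    stop("meanAbsCorrelation must lie in [0, 1]")
  m <- length(pValues)
  alphaAdj <- 1 - (1 - alpha)^(1 / m^(1 - r))
  list(alpha_adjusted = alphaAdj, significant = pValues < alphaAdj,
       m = m, rbar = r)
}

#' Export a fitted path model as JSON
#'
#' @param fit a [SEMFit-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSEMFitJSON <- function(fit, path) {
  jsonlite::write_json(list(
    estimates = estimates(fit),
    fit = as.list(fitIndices(fit))), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
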