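# Cumulative-sum feature transform, the weighted composite score for
# neurodegeneration prediction, and behaviour-versus-degeneration curves.

#' Mean-normalized cumulative-sum transform
#'
#' Within each group, every feature is divided by its group mean and then
#' cumulatively summed across the measurement weeks (chronological order) per
#' subject. Doubling a feature leaves the transform unchanged; a feature
#' constant at its group mean maps to 1, 2, 3, ... Subjects missing any
#' configured week are dropped (with a message).
#'
#' @param ft data.frame with columns \code{subject}, \code{group},
#'   \code{week} and the features.
#' @param features feature column names to transform (default: all numeric
#'   columns besides the keys).
#' @param weeks the required weeks (default: all weeks present).
#' @return data.frame of the same shape, features replaced by their
#'   cumulative series.
#' @export
cumulativeFeatures <- function(ft, features = NULL, weeks = NULL) {
  keys <- c("subject", "group", "week")
  if (!all(keys %in% names(ft)))
    stop("feature table needs subject, group, week columns")
  if (is.null(features))
    features <- setdiff(names(ft)[vapply(ft, is.numeric, logical(1))],
                        c("week"))
  if (is.null(weeks)) weeks <- sort(unique(ft$week))
  ok <- vapply(split(ft, ft$subject), function(d)
    all(weeks %in% d$week) && !anyNA(d[d$week %in% weeks, features]),
    logical(1))
  dropped <- names(ok)[!ok]
  if (length(dropped))
    message("dropping subject(s) with incomplete weeks: ",
            paste(dropped, collapse = ", "))
  ft <- ft[ft$subject %in% names(ok)[ok] & ft$week %in% weeks, , drop = FALSE]
  out <- ft[order(ft$group, ft$subject, ft$week), , drop = FALSE]
  for (g in unique(out$group)) {
    gi <- out$group == g
    for (f in features) {
      mu <- mean(out[gi, f])
      if (!is.finite(mu) || mu == 0)
        stop(sprintf("group '%s' mean of feature '%s' is zero; cannot normalize",
                     g, f))
      for (s in unique(out$subject[gi])) {
        si <- gi & out$subject == s
        out[si, f] <- cumsum(out[si, f] / mu)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Weighted composite score by forward selection
#'
#' Greedy forward selection over candidate features: at each step the feature
#' whose nonnegative-least-squares weight vector (renormalized to sum 1)
#' gives the lowest RMSE against the target is added; selection stops when
#' the relative RMSE improvement falls below \code{minImprovement}. Weights
#' are nonnegative and sum to 1 by construction.
#'
#' @param candidates data.frame or matrix of candidate features (columns).
#' @param target numeric target (e.g. a neurodegeneration score) per row.
#' @param groups optional group labels for per-group RMSE reporting.
#' @param minImprovement relative RMSE improvement needed to keep adding
#'   features (default 0.01).
#' @param maxFeatures cap on the number of selected features.
#' @return list: \code{selected} (ordered names), \code{weights} (named,
#'   nonnegative, sum 1), \code{rmse}, \code{baselineRMSE} (intercept-only),
#'   \code{perGroupRMSE}, \code{predicted}.
#' @export
compositeScore <- function(candidates, target, groups = NULL,
                           minImprovement = 0.01, maxFeatures = Inf) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y))
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all candidate features are constant")
  X <- X[, sds > 0, drop = FALSE]

  rmseOf <- function(cols) {
    Fm <- X[, cols, drop = FALSE]
    w <- tryCatch(pracma::lsqnonneg(Fm, y)$x, error = function(e) NULL)
    if (is.null(w) || sum(w) <= 0) return(list(rmse = Inf, w = NULL))
    w <- w / sum(w)
    list(rmse = sqrt(mean((y - Fm %*% w)^2)), w = w)
  }

  baseline <- sqrt(mean((y - mean(y))^2))
  selected <- character(0)
  best <- list(rmse = baseline, w = numeric(0))
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining) || length(selected) >= maxFeatures) break
    trials <- lapply(remaining, function(f) rmseOf(c(selected, f)))
    rmses <- vapply(trials, `[[`, numeric(1), "rmse")
    k <- which.min(rmses)
    if (!is.finite(rmses[k])) break
    improvement <- (best$rmse - rmses[k]) / max(best$rmse, .Machine$double.eps)
    if (length(selected) > 0 && improvement < minImprovement) break
    if (length(selected) == 0 && improvement < minImprovement) {
      # even the best single feature adds nothing over the intercept
      selected <- remaining[k]
      best <- trials[[k]]
      break
    }
    selected <- c(selected, remaining[k])
    best <- trials[[k]]
  }
  w <- setNames(as.numeric(best$w), selected)
  pred <- if (length(selected)) as.numeric(X[, selected, drop = FALSE] %*% w)
    else rep(mean(y), length(y))
  perGroup <- NULL
  if (!is.null(groups)) {
    perGroup <- vapply(split(seq_along(y), groups), function(idx)
      sqrt(mean((y[idx] - pred[idx])^2)), numeric(1))
  }
  list(selected = selected, weights = w, rmse = best$rmse,
       baselineRMSE = baseline, perGroupRMSE = perGroup, predicted = pred)
}

#' Behaviour-versus-neurodegeneration curves
#'
#' Behaviour deficit scores are z-normalized per group and decoded to three
#' ordinal classes (normal / moderate / severe) at the standard-normal
#' tercile cuts; "preserved motor function" means the normal class. Per
#' group, a logistic curve of P(preserved) against the neurodegeneration
#' percentage is fitted; the midpoint (degeneration at which preservation
#' probability crosses 1/2) and slope are returned.
#'
#' @param deficit behaviour deficit score (higher = worse), per observation.
#' @param degeneration neurodegeneration percentage per observation.
#' @param groups group labels (default: one group).
#' @return data.frame per group: \code{group}, \code{midpoint},
#'   \code{slope}, \code{nPreserved}, \code{n}; attribute \code{"classes"}
#'   holds the decoded ordinal classes.
#' @export
degenerationBehaviorCurve <- function(deficit, degeneration, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(deficit))
  stopifnot(length(deficit) == length(degeneration),
            length(groups) == length(deficit))
  cuts <- stats::qnorm(c(1 / 3, 2 / 3))
  classes <- rep(NA_character_, length(deficit))
  out <- list()
  for (g in unique(groups)) {
    gi <- which(groups == g)
    mu <- mean(deficit[gi]); sdev <- stats::sd(deficit[gi])
    if (!is.finite(sdev) || sdev == 0)
      stop(sprintf("group '%s' has a single behaviour class; curve unidentifiable", g))
    z <- (deficit[gi] - mu) / sdev
    cls <- cut(z, c(-Inf, cuts, Inf),
               labels = c("normal", "moderate", "severe"))
    if (length(unique(cls)) < 2)
      stop(sprintf("group '%s' has a single behaviour class; curve unidentifiable", g))
    classes[gi] <- as.character(cls)
    preserved <- as.integer(cls == "normal")
    fit <- suppressWarnings(stats::glm(preserved ~ degeneration[gi],
                                       family = stats::binomial()))
    b <- stats::coef(fit)
    out[[g]] <- data.frame(group = g, midpoint = -b[1] / b[2], slope = b[2],
                           nPreserved = sum(preserved), n = length(gi),
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "classes") <- classes
  res
}
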