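#' @include AllClasses.R gis.R
NULL

#' Selection thresholds for the LUR procedure
#'
#' @param corrThreshold candidates must have absolute Pearson correlation
#'   below this with every variable already in the model (default 0.7).
#' @param pRemove backward-pruning threshold: variables with p-value above
#'   it are removed one by one (default 0.2).
#' @param pKeep a final supplementary variable is kept only if its p-value
#'   is at or below this (default 0.2).
#' @return list of thresholds.
#' @export
lurConfig <- function(corrThreshold = 0.7, pRemove = 0.2, pKeep = 0.2) {
  stopifnot(corrThreshold > 0, pRemove > 0, pKeep > 0)
  list(corrThreshold = corrThreshold, pRemove = pRemove, pKeep = pKeep)
}

# Resolve a FeatureMatrix or plain matrix into a sites x variables matrix.
.featuresBySite <- function(features) {
  if (is(features, "FeatureMatrix"))
    t(SummarizedExperiment::assay(features, "features"))
  else as.matrix(features)
}

# Fast OLS with intercept. X: n x p (p >= 0), y: length n. Errors on rank
# deficiency naming the offending columns.
.ols <- function(X, y) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (n <= p + 1) stop("need more sites than coefficients (n > p + 1)")
  Xf <- cbind(`(Intercept)` = rep(1, n), X)
  qr0 <- qr(Xf)
  if (qr0$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qr0$pivot[seq.int(qr0$rank + 1L, ncol(Xf))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr0, y)
  fittedv <- drop(Xf %*% beta)
  res <- y - fittedv
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - p - 1
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qr0))
  unpivot <- order(qr0$pivot)
  XtXinv <- XtXinv[unpivot, unpivot, drop = FALSE]
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- beta / se
  pv <- 2 * stats::pt(-abs(tval), df)
  pv[is.na(pv)] <- 1  # zero coefficient with zero SE carries no evidence
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj <- 1 - (1 - r2) * (n - 1) / df
  names(se) <- names(pv) <- names(beta)
  new("RegressionFit", variables = colnames(X), coefficients = beta, se = se,
      pValues = pv, r2 = r2, adjR2 = adj, fitted = fittedv, residuals = res,
      n = as.integer(n))
}

# Intercept-only fit: R2 and adjusted R2 are 0 by convention.
.olsNull <- function(y) {
  n <- length(y)
  m <- mean(y)
  new("RegressionFit", variables = character(), coefficients = c(`(Intercept)` = m),
      se = c(`(Intercept)` = stats::sd(y) / sqrt(n)),
      pValues = c(`(Intercept)` = NA_real_), r2 = 0, adjR2 = 0,
      fitted = rep(m, n), residuals = y - m, n = as.integer(n))
}

#' Ordinary least squares fit of noise on selected predictors
#'
#' Least-squares fit with intercept; two-sided t-test p-values per
#' coefficient; adjusted R-squared computed as
#' \code{1 - (1 - R2) * (n - 1) / (n - p - 1)}.
#'
#' @param features a \linkS4class{FeatureMatrix} or a sites-by-variables
#'   numeric matrix.
#' @param response per-site noise levels in dB(A).
#' @param variables character vector of columns to use; NULL takes all.
#' @return A \linkS4class{RegressionFit}.
#' @export
fitOls <- function(features, response, variables = NULL) {
  X <- .featuresBySite(features)
  if (!is.null(variables)) {
    missing <- setdiff(variables, colnames(X))
    if (length(missing))
      stop("variables not present in the feature matrix: ",
           paste(missing, collapse = ", "))
    X <- X[, variables, drop = FALSE]
  }
  if (ncol(X) == 0L) return(.olsNull(response))
  if (any(apply(X, 2, stats::sd) == 0))
    stop("constant columns in design: ",
         paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "))
  .ols(X, response)
}

#' Univariate screen of every candidate predictor
#'
#' Fits one single-variable regression of the response per candidate and
#' records the slope, the R-squared and whether the slope sign matches the
#' variable's expected sign. Constant columns screen as R-squared 0 with
#' \code{sign_ok = FALSE} and can never be selected.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param response per-site noise levels in dB(A).
#' @return data.frame with one row per candidate: \code{name},
#'   \code{var_type}, \code{buffer_m}, \code{expected_sign},
#'   \code{coefficient}, \code{r2}, \code{sign_ok}.
#' @export
univariateScreen <- function(features, response) {
  X <- .featuresBySite(features)
  meta <- as.data.frame(SummarizedExperiment::rowData(features))
  y <- response
  sdx <- apply(X, 2, stats::sd)
  sdy <- stats::sd(y)
  r <- rep(0, ncol(X))
  ok <- sdx > 0 & sdy > 0
  if (any(ok)) r[ok] <- suppressWarnings(stats::cor(X[, ok, drop = FALSE], y))
  coefv <- ifelse(sdx > 0, r * sdy / sdx, NA_real_)
  data.frame(name = colnames(X), var_type = meta$var_type,
             buffer_m = meta$buffer_m, expected_sign = meta$expected_sign,
             coefficient = coefv, r2 = r^2,
             sign_ok = !is.na(coefv) & sign(coefv) == meta$expected_sign,
             stringsAsFactors = FALSE)
}

#' Choose the best buffer per variable type
#'
#' Within each variable type (e.g. medium-road length, household density),
#' keeps only the buffers whose univariate slope has the expected sign and
#' among those picks the highest univariate R-squared; exact ties go to the
#' smaller buffer, then to the lexicographically first name. Types with no
#' correctly-signed buffer are dropped.
#'
#' @param screen output of \code{\link{univariateScreen}}.
#' @return The selected subset of \code{screen}, ordered by decreasing
#'   R-squared (ties by name); one row per surviving type. Attribute
#'   \code{"dropped_types"} lists the types removed for sign violations.
#' @export
selectBestBuffer <- function(screen) {
  stopifnot(nrow(screen) > 0)
  keep <- list()
  droppedTypes <- character()
  for (tp in unique(screen$var_type)) {
    g <- screen[screen$var_type == tp & screen$sign_ok, , drop = FALSE]
    if (nrow(g) == 0L) {
      droppedTypes <- c(droppedTypes, tp)
      next
    }
    o <- order(-g$r2, g$buffer_m, g$name)
    keep[[tp]] <- g[o[1], , drop = FALSE]
  }
  out <- do.call(rbind, keep)
  if (is.null(out))
    out <- screen[0, , drop = FALSE]
  out <- out[order(-out$r2, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_types") <- droppedTypes
  out
}

.traceRow <- function(step, event, variable, detail, before, after) {
  data.frame(step = step, event = event, variable = variable,
             detail = detail, adj_r2_before = before, adj_r2_after = after,
             stringsAsFactors = FALSE)
}

.emptyTrace <- function() .traceRow(integer(), character(), character(),
                                    character(), numeric(), numeric())

# Trial fit that treats an exactly collinear design as inadmissible
# (composite candidates can be exact linear combinations of included
# variables without any pairwise correlation reaching the gate).
.olsTry <- function(X, y) {
  tryCatch(.ols(X, y), error = function(e) {
    if (grepl("rank-deficient", conditionMessage(e))) NULL else stop(e)
  })
}

# Absolute Pearson correlations of one column against a set of columns.
.absCor <- function(X, candidate, against) {
  if (length(against) == 0L) return(numeric())
  abs(drop(suppressWarnings(stats::cor(X[, candidate],
                                       X[, against, drop = FALSE]))))
}

#' Correlation-gated forward selection
#'
#' Iterates the screened candidates in decreasing order of univariate
#' R-squared (ties by name). A candidate enters the model iff its absolute
#' Pearson correlation with every variable already included is below the
#' threshold and refitting with it strictly increases the adjusted
#' R-squared. Every decision is logged.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param candidates data.frame from \code{\link{selectBestBuffer}} (or any
#'   frame with \code{name} and \code{r2} columns).
#' @param response per-site noise levels in dB(A).
#' @param config thresholds from \code{\link{lurConfig}}.
#' @return list with \code{fit} (\linkS4class{RegressionFit}),
#'   \code{included} (character) and \code{trace} (data.frame).
#' @export
forwardSelection <- function(features, candidates, response,
                             config = lurConfig()) {
  X <- .featuresBySite(features)
  ord <- order(-candidates$r2, candidates$name)
  queue <- candidates$name[ord]
  included <- character()
  fit <- .olsNull(response)
  trace <- list()
  step <- 0L
  for (cand in queue) {
    step <- step + 1L
    before <- fit@adjR2
    if (length(included) + 2L >= length(response)) {
      trace[[step]] <- .traceRow(step, "rejected_no_gain", cand,
                                 "insufficient residual degrees of freedom",
                                 before, before)
      next
    }
    if (any(.absCor(X, cand, included) >= config$corrThreshold)) {
      trace[[step]] <- .traceRow(step, "rejected_correlation", cand,
                                 paste(included, collapse = ","),
                                 before, before)
      next
    }
    trial <- .olsTry(X[, c(included, cand), drop = FALSE], response)
    if (is.null(trial)) {
      trace[[step]] <- .traceRow(step, "rejected_correlation", cand,
                                 "exactly collinear with included variables",
                                 before, before)
      next
    }
    if (trial@adjR2 > before) {
      included <- c(included, cand)
      fit <- trial
      trace[[step]] <- .traceRow(step, "added", cand, "", before, fit@adjR2)
    } else {
      trace[[step]] <- .traceRow(step, "rejected_no_gain", cand, "",
                                 before, before)
    }
  }
  list(fit = fit, included = included,
       trace = if (length(trace)) do.call(rbind, trace) else .emptyTrace())
}

#' Backward pruning on p-values
#'
#' While any included variable has a p-value above the threshold, removes
#' the one with the largest p-value and refits. At exit every remaining
#' variable has p at or below the threshold.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param included character vector of variables currently in the model.
#' @param response per-site noise levels in dB(A).
#' @param config thresholds from \code{\link{lurConfig}}.
#' @return list with \code{fit}, \code{included} and \code{trace}.
#' @export
backwardPrune <- function(features, included, response, config = lurConfig()) {
  X <- .featuresBySite(features)
  fit <- if (length(included)) .ols(X[, included, drop = FALSE], response)
         else .olsNull(response)
  trace <- list()
  step <- 0L
  while (length(included) > 0L) {
    pv <- fit@pValues[included]
    if (max(pv) <= config$pRemove) break
    worstP <- max(pv)
    worst <- sort(names(pv)[pv == worstP])[1]
    step <- step + 1L
    before <- fit@adjR2
    included <- setdiff(included, worst)
    fit <- if (length(included)) .ols(X[, included, drop = FALSE], response)
           else .olsNull(response)
    trace[[step]] <- .traceRow(step, "removed_pvalue", worst,
                               sprintf("p=%.4g", worstP), before, fit@adjR2)
  }
  list(fit = fit, included = included,
       trace = if (length(trace)) do.call(rbind, trace) else .emptyTrace())
}

# Deterministic ordering of competing challengers/additions: higher
# adjusted R2, then smaller buffer, then name.
.pickBest <- function(df) {
  buf <- df$buffer_m
  buf[is.na(buf)] <- Inf
  df[order(-df$adjR2, buf, df$name)[1], , drop = FALSE]
}

#' Challenge each model variable against the full candidate grid
#'
#' For each variable in the model (in model order), tries replacing it with
#' every candidate of any type and buffer not already included. A
#' replacement is accepted iff it strictly increases the adjusted
#' R-squared, keeps all pairwise absolute correlations below the threshold,
#' and its refitted coefficient has the expected sign. Among admissible
#' challengers the one with the highest adjusted R-squared wins (ties to
#' the smaller buffer, then name). One full pass.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param included character vector of variables currently in the model.
#' @param response per-site noise levels in dB(A).
#' @param allCandidates character vector naming the full challenge pool
#'   (defaults to every variable in \code{features}).
#' @param config thresholds from \code{\link{lurConfig}}.
#' @return list with \code{fit}, \code{included} and \code{trace}.
#' @export
challengeVariables <- function(features, included, response,
                               allCandidates = NULL, config = lurConfig()) {
  X <- .featuresBySite(features)
  meta <- as.data.frame(SummarizedExperiment::rowData(features))
  rownames(meta) <- meta$name
  if (is.null(allCandidates)) allCandidates <- colnames(X)
  fit <- if (length(included)) .ols(X[, included, drop = FALSE], response)
         else .olsNull(response)
  trace <- list()
  step <- 0L
  for (pos in seq_along(included)) {
    current <- included[pos]
    others <- included[-pos]
    pool <- setdiff(allCandidates, included)
    rows <- list()
    for (cand in pool) {
      if (stats::sd(X[, cand]) == 0) next
      if (any(.absCor(X, cand, others) >= config$corrThreshold)) next
      trial <- .olsTry(X[, c(others, cand), drop = FALSE], response)
      if (is.null(trial)) next
      expSign <- meta[cand, "expected_sign"]
      if (!is.na(expSign) &&
          sign(trial@coefficients[cand]) != expSign) next
      if (trial@adjR2 <= fit@adjR2) next
      rows[[length(rows) + 1L]] <- data.frame(
        name = cand, adjR2 = trial@adjR2,
        buffer_m = meta[cand, "buffer_m"], stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      best <- .pickBest(do.call(rbind, rows))
      step <- step + 1L
      before <- fit@adjR2
      included[pos] <- best$name
      fit <- .ols(X[, included, drop = FALSE], response)
      trace[[step]] <- .traceRow(step, "challenged_swap", current,
                                 best$name, before, fit@adjR2)
    }
  }
  list(fit = fit, included = included,
       trace = if (length(trace)) do.call(rbind, trace) else .emptyTrace())
}

#' Final augmentation with at most one supplementary variable
#'
#' Evaluates adding each remaining candidate to the model; the single best
#' addition is kept iff it strictly increases the adjusted R-squared,
#' passes the correlation gate against every included variable, and its
#' p-value is at or below the threshold.
#'
#' @inheritParams challengeVariables
#' @return list with \code{fit}, \code{included} and \code{trace}.
#' @export
finalAugment <- function(features, included, response, allCandidates = NULL,
                         config = lurConfig()) {
  X <- .featuresBySite(features)
  meta <- as.data.frame(SummarizedExperiment::rowData(features))
  rownames(meta) <- meta$name
  if (is.null(allCandidates)) allCandidates <- colnames(X)
  fit <- if (length(included)) .ols(X[, included, drop = FALSE], response)
         else .olsNull(response)
  pool <- setdiff(allCandidates, included)
  rows <- list()
  for (cand in pool) {
    if (stats::sd(X[, cand]) == 0) next
    if (length(included) + 2L >= length(response)) break
    if (any(.absCor(X, cand, included) >= config$corrThreshold)) next
    trial <- .olsTry(X[, c(included, cand), drop = FALSE], response)
    if (is.null(trial)) next
    if (trial@adjR2 <= fit@adjR2) next
    if (trial@pValues[cand] > config$pKeep) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = cand, adjR2 = trial@adjR2, buffer_m = meta[cand, "buffer_m"],
      stringsAsFactors = FALSE)
  }
  trace <- .emptyTrace()
  if (length(rows)) {
    best <- .pickBest(do.call(rbind, rows))
    before <- fit@adjR2
    included <- c(included, best$name)
    fit <- .ols(X[, included, drop = FALSE], response)
    trace <- .traceRow(1L, "augmented", best$name, "", before, fit@adjR2)
  }
  list(fit = fit, included = included, trace = trace)
}

#' Build a land use regression model by supervised selection
#'
#' Runs the complete selection procedure: a univariate screen of every
#' candidate, sign-constrained best-buffer choice per variable type,
#' correlation-gated forward selection in decreasing univariate R-squared
#' order, backward pruning of variables with p above the threshold, a
#' challenge pass replacing model variables with better-explaining
#' candidates of any type and buffer, and a final augmentation admitting at
#' most one supplementary variable. The procedure is fully deterministic:
#' all ties are broken by higher adjusted R-squared, then smaller buffer,
#' then variable name.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param response per-site Lden (or other target level) in dB(A), aligned
#'   with the columns of \code{features}.
#' @param config thresholds from \code{\link{lurConfig}}.
#' @return A \linkS4class{LURModel} carrying the final fit, the full
#'   selection trace and the thresholds used.
#' @export
buildLUR <- function(features, response, config = lurConfig()) {
  stopifnot(is(features, "FeatureMatrix"))
  X <- .featuresBySite(features)
  if (nrow(X) != length(response))
    stop("response length must match the number of sites")
  screen <- univariateScreen(features, response)
  chosen <- selectBestBuffer(screen)

  trace <- list()
  add <- function(ev) trace[[length(trace) + 1L]] <<- ev
  scr <- .traceRow(seq_len(nrow(screen)), "screened", screen$name,
                   sprintf("r2=%.4f sign_ok=%s", screen$r2, screen$sign_ok),
                   NA_real_, NA_real_)
  add(scr)
  if (nrow(chosen))
    add(.traceRow(seq_len(nrow(chosen)), "buffer_chosen", chosen$name,
                  chosen$var_type, NA_real_, chosen$r2))
  for (tp in attr(chosen, "dropped_types"))
    add(.traceRow(1L, "type_dropped_sign", tp, "", NA_real_, NA_real_))

  fw <- forwardSelection(features, chosen, response, config)
  add(fw$trace)
  bp <- backwardPrune(features, fw$included, response, config)
  add(bp$trace)
  ch <- challengeVariables(features, bp$included, response,
                           allCandidates = colnames(X), config = config)
  add(ch$trace)
  au <- finalAugment(features, ch$included, response,
                     allCandidates = colnames(X), config = config)
  add(au$trace)

  tr <- do.call(rbind, trace)
  tr$step <- seq_len(nrow(tr))
  rownames(tr) <- NULL
  meta <- SummarizedExperiment::rowData(features)
  new("LURModel", fit = au$fit, trace = tr, config = config,
      variableData = meta[au$included, , drop = FALSE])
}
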