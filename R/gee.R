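# Logistic generalized estimating equations with cluster-robust (sandwich)
# inference for repeated prescriber-month measurements.

#' Logistic regression by generalized estimating equations
#'
#' Fits a marginal logistic mean model to clustered binary data by iteratively
#' reweighted estimating equations with a working correlation structure, and
#' reports sandwich-robust standard errors clustered on \code{id}. The robust
#' covariance is consistent even when the working correlation is
#' misspecified, which is what licenses the automatic fallback chain used by
#' \code{\link{fit_panel_model}} (unstructured, then exchangeable, then
#' independence) when a richer structure cannot be estimated stably on
#' unbalanced cluster lengths.
#'
#' Working correlations: \code{"independence"}; \code{"exchangeable"} (a
#' single within-cluster correlation estimated by moments from Pearson
#' residuals); \code{"unstructured"} (one correlation per occasion pair,
#' estimated from clusters observing both occasions; requires \code{waves},
#' integer occasion indices unique within cluster). The binomial scale
#' parameter is fixed at 1.
#'
#' @param formula model formula with a binary (0/1) response.
#' @param data data.frame holding the model variables, \code{id} and
#'   \code{waves}.
#' @param id cluster identifier: a column name (string) or a vector.
#' @param waves occasion index: column name or integer vector; required for
#'   the unstructured structure.
#' @param corstr working correlation structure.
#' @param maxit,tol iteration control for the estimating equations.
#' @return object of class \code{"gee_logit"} with coefficients, robust,
#'   Mancl-DeRouen bias-corrected (\code{vcov(fit, "bc")}; preferable when
#'   events or clusters are sparse) and model-based ("naive") covariance
#'   matrices, the estimated working correlation,
#'   convergence metadata, and enough state for methods
#'   (\code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{confint}, \code{fitted}, \code{residuals}, \code{predict}).
#' @export
#' @examples
#' d <- data.frame(y = rbinom(60, 1, 0.4), x = rnorm(60),
#'                 id = rep(1:20, each = 3), t = rep(1:3, 20))
#' f <- gee_logit(y ~ x, d, id = "id", waves = "t", corstr = "exchangeable")
#' summary(f)
gee_logit <- function(formula, data, id, waves = NULL,
                      corstr = c("independence", "exchangeable",
                                 "unstructured"),
                      maxit = 50L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  X <- stats::model.matrix(formula, mf)
  idv <- if (is.character(id) && length(id) == 1L) data[[id]] else id
  if (is.null(idv) || length(idv) != nrow(X))
    stop("id must name a column of data or match its rows", call. = FALSE)
  wv <- if (is.null(waves)) NULL
  else if (is.character(waves) && length(waves) == 1L) data[[waves]] else waves
  if (corstr == "unstructured" && is.null(wv))
    stop("unstructured working correlation requires waves", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("outcome is all-zero or all-one; model is not estimable", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending term(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }

  ord <- order(match(idv, unique(idv)), if (is.null(wv)) seq_along(idv) else wv)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; idv <- idv[ord]
  wv <- if (is.null(wv)) stats::ave(seq_along(idv), idv, FUN = seq_along) else wv[ord]
  cluster_rows <- split(seq_along(idv), factor(idv, levels = unique(idv)))
  if (corstr == "unstructured") {
    dup <- vapply(cluster_rows, function(r) anyDuplicated(wv[r]) > 0L, logical(1L))
    if (any(dup)) stop("waves must be unique within cluster", call. = FALSE)
  }
  p <- ncol(X)
  n_clust <- length(cluster_rows)
  T_max <- max(wv)

  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  alpha <- NULL
  R_full <- NULL
  converged <- FALSE
  singular <- FALSE

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
    v <- mu * (1 - mu)
    r <- (y - mu) / sqrt(v)

    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (rows in cluster_rows) {
        ni <- length(rows)
        if (ni < 2L) next
        ri <- r[rows]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1L) / 2
      }
      alpha <- if (den > p) num / (den - p) else 0
      alpha <- max(min(alpha, 0.95), -1 / (max(lengths(cluster_rows)) - 1) + 1e-6)
    } else if (corstr == "unstructured") {
      S <- matrix(0, T_max, T_max); Nj <- matrix(0, T_max, T_max)
      for (rows in cluster_rows) {
        wi <- wv[rows]; ri <- r[rows]
        S[wi, wi] <- S[wi, wi] + outer(ri, ri)
        Nj[wi, wi] <- Nj[wi, wi] + 1
      }
      R_full <- S / pmax(Nj - p, 1)
      R_full[Nj < 2] <- 0
      R_full[R_full > 0.95] <- 0.95
      R_full[R_full < -0.95] <- -0.95
      diag(R_full) <- 1
      ok <- !inherits(try(chol(R_full), silent = TRUE), "try-error")
      if (!ok) { singular <- TRUE; break }
    }

    B <- matrix(0, p, p)
    U <- numeric(p)
    for (rows in cluster_rows) {
      Xi <- X[rows, , drop = FALSE]
      si <- sqrt(v[rows])
      Ri <- switch(corstr,
                   independence = diag(length(rows)),
                   exchangeable = {
                     ni <- length(rows)
                     m <- matrix(alpha, ni, ni); diag(m) <- 1; m
                   },
                   unstructured = R_full[wv[rows], wv[rows], drop = FALSE])
      Rinv <- tryCatch(solve(Ri), error = function(e) NULL)
      if (is.null(Rinv)) { singular <- TRUE; break }
      M <- t(Xi * si) %*% Rinv         # p x ni
      B <- B + M %*% (Xi * si)
      U <- U + drop(M %*% ((y[rows] - mu[rows]) / si))
    }
    if (singular) break
    step <- tryCatch(solve(B, U), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 30) break  # coefficients drifting to +/- infinity
  }
  sep_terms <- colnames(X)[abs(beta) > 10 & !converged]
  if (length(sep_terms) > 0L)
    stop(errorCondition(
      paste0("apparent separation (coefficient diverging); offending term(s): ",
             paste(sep_terms, collapse = ", ")),
      class = c("pssnet_separation", "error", "condition")))
  if (singular)
    stop("working correlation or estimating equations singular for corstr = '",
         corstr, "'", call. = FALSE)

  # sandwich covariance B^{-1} (sum_i u_i u_i') B^{-1}, plus the
  # Mancl-DeRouen bias-corrected variant with leverage-adjusted residuals
  # (I - H_i)^{-1} (y_i - mu_i), which restores near-nominal CI coverage
  # when events are sparse
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  v <- mu * (1 - mu)
  B <- matrix(0, p, p)
  Ci_l <- Di_l <- ri_l <- vector("list", n_clust)
  k <- 0L
  for (rows in cluster_rows) {
    k <- k + 1L
    Xi <- X[rows, , drop = FALSE]
    si <- sqrt(v[rows])
    Ri <- switch(corstr,
                 independence = diag(length(rows)),
                 exchangeable = {
                   ni <- length(rows)
                   m <- matrix(alpha, ni, ni); diag(m) <- 1; m
                 },
                 unstructured = R_full[wv[rows], wv[rows], drop = FALSE])
    M <- t(Xi * si) %*% solve(Ri)
    B <- B + M %*% (Xi * si)
    Ci_l[[k]] <- sweep(M, 2L, si, "/")   # D_i' V_i^{-1}  (p x n_i)
    Di_l[[k]] <- Xi * v[rows]
    ri_l[[k]] <- y[rows] - mu[rows]
  }
  Binv <- solve(B)
  meat <- matrix(0, p, p)
  meat_bc <- matrix(0, p, p)
  for (k in seq_len(n_clust)) {
    ui <- drop(Ci_l[[k]] %*% ri_l[[k]])
    meat <- meat + tcrossprod(ui)
    ni <- length(ri_l[[k]])
    Hi <- Di_l[[k]] %*% Binv %*% Ci_l[[k]]
    adj <- tryCatch(solve(diag(ni) - Hi, ri_l[[k]]),
                    error = function(e) ri_l[[k]])
    ubc <- drop(Ci_l[[k]] %*% adj)
    meat_bc <- meat_bc + tcrossprod(ubc)
  }
  vr <- Binv %*% meat %*% Binv
  dimnames(vr) <- list(colnames(X), colnames(X))
  vbc <- Binv %*% meat_bc %*% Binv
  dimnames(vbc) <- dimnames(vr)
  naive <- Binv
  dimnames(naive) <- dimnames(vr)

  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov_robust = vr, vcov_bc = vbc, vcov_naive = naive,
    alpha = alpha, working_correlation = R_full, corstr = corstr,
    converged = converged, n = length(y), n_clusters = n_clust,
    fitted_values = mu, linear_predictors = eta, y = y,
    formula = formula, call = cl, xlevels = stats::.getXlevels(
      stats::terms(mf), mf), terms = stats::terms(mf)
  ), class = "gee_logit")
}

#' @export
coef.gee_logit <- function(object, ...) object$coefficients

#' @export
vcov.gee_logit <- function(object, type = c("robust", "bc", "naive"), ...) {
  type <- match.arg(type)
  switch(type, robust = object$vcov_robust, bc = object$vcov_bc,
         naive = object$vcov_naive)
}

#' @export
fitted.gee_logit <- function(object, ...) object$fitted_values

#' @export
residuals.gee_logit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted_values
  if (type == "pearson")
    r <- r / sqrt(object$fitted_values * (1 - object$fitted_values))
  r
}

#' @export
confint.gee_logit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov_robust))
  est <- object$coefficients
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.gee_logit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$linear_predictors
  else {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                             xlev = object$xlevels)
    drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.gee_logit <- function(x, ...) {
  cat("Logistic GEE (", x$corstr, " working correlation), ",
      x$n, " observations in ", x$n_clusters, " clusters\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.gee_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_robust))
  est <- object$coefficients
  z <- est / se
  tab <- data.frame(
    estimate = est, robust_se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    aor = exp(est), ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se))
  out <- list(coefficients = tab, corstr = object$corstr,
              alpha = object$alpha, n = object$n,
              n_clusters = object$n_clusters, converged = object$converged)
  class(out) <- "summary.gee_logit"
  out
}

#' @export
print.summary.gee_logit <- function(x, ...) {
  cat("Logistic GEE, ", x$corstr, " working correlation",
      if (!is.null(x$alpha)) sprintf(" (alpha = %.3f)", x$alpha), "\n",
      sep = "")
  cat(sprintf("%d observations in %d clusters; converged: %s\n", x$n,
              x$n_clusters, x$converged))
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "robust_se", "z", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Fit a panel model with adjusted odds ratios and a fallback chain
#'
#' High-level wrapper around \code{\link{gee_logit}} for the assembled
#' adoption / discontinuation panels. Categorical terms enter with the
#' published reference levels (exposure \code{none}, region Interior,
#' specialty general practice, lowest experience and caseload quartiles); the
#' requested working correlation is tried first and, if it cannot be
#' estimated (non-convergence or singularity on unbalanced cluster lengths),
#' the chain falls back unstructured -> exchangeable -> independence, always
#' recording what was used. Confidence intervals use the normal 1.96
#' multiplier, matching two-sided 95\% intervals.
#'
#' @param panel a panel from \code{\link{assemble_panel}}.
#' @param terms character vector of regressor columns; the default is the
#'   full published covariate set.
#' @param corstr working correlation requested first.
#' @param fallback allow the fallback chain (default TRUE).
#' @return data.frame (class \code{"pss_model_result"}) with one row per
#'   coefficient: \code{term}, \code{estimate}, \code{robust_se}, \code{aor},
#'   \code{ci_lo}, \code{ci_hi}; metadata in attributes \code{n},
#'   \code{n_clusters}, \code{corstr_used}, \code{fallback_from},
#'   \code{converged}, and the fitted object in \code{fit}.
#' @export
fit_panel_model <- function(panel,
                            terms = c("study_month", "exposure_cat",
                                      "clustering", "adjusted_strength",
                                      "region", "specialty", "oat_history",
                                      "experience_cat", "caseload_cat",
                                      "covid_client", "pct_age40",
                                      "pct_cci_gt1", "pct_benzo",
                                      "pct_social_assistance",
                                      "pct_overdose_12m"),
                            corstr = "unstructured", fallback = TRUE) {
  miss <- setdiff(terms, names(panel))
  if (length(miss) > 0L)
    stop("panel lacks term(s): ", paste(miss, collapse = ", "), call. = FALSE)
  f <- stats::as.formula(paste("outcome ~", paste(terms, collapse = " + ")))
  chain <- c("unstructured", "exchangeable", "independence")
  chain <- chain[match(corstr, chain):length(chain)]
  if (!fallback) chain <- chain[1L]
  fit <- NULL
  used <- NULL
  tried <- character(0)
  for (cs in chain) {
    fit <- tryCatch(
      gee_logit(f, panel, id = "prescriber_id", waves = "study_month",
                corstr = cs),
      error = function(e) e)
    # separation and rank deficiency do not depend on the working
    # correlation; surface them instead of walking the chain
    if (inherits(fit, "pssnet_separation")) stop(fit)
    if (inherits(fit, "error") &&
        grepl("rank deficient|all-zero|all-one", conditionMessage(fit)))
      stop(fit)
    if (inherits(fit, "gee_logit") && fit$converged) { used <- cs; break }
    tried <- c(tried, cs)
    fit <- NULL
  }
  if (is.null(fit))
    stop("no working correlation in the chain could be fitted (tried: ",
         paste(tried, collapse = ", "), ")", call. = FALSE)
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), estimate = s$estimate,
                    robust_se = s$robust_se, aor = s$aor, ci_lo = s$ci_lo,
                    ci_hi = s$ci_hi, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- fit$n
  attr(out, "n_clusters") <- fit$n_clusters
  attr(out, "corstr_used") <- used
  attr(out, "fallback_from") <- tried
  attr(out, "converged") <- fit$converged
  attr(out, "fit") <- fit
  class(out) <- c("pss_model_result", "data.frame")
  out
}

#' Random-intercept variance diagnostic
#'
#' Fits the random-intercept logistic counterpart of a panel model and
#' reports the intercept variance -- the diagnostic that motivates using a
#' marginal GEE when the cluster variance estimate collapses to zero.
#' Advisory only. With single-observation clusters the variance is not
#' identifiable and is reported as NA.
#'
#' @inheritParams fit_panel_model
#' @return list with \code{variance}, \code{identifiable}, \code{message}.
#' @export
glmm_variance_check <- function(panel, terms = c("exposure_cat",
                                                 "caseload_cat")) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("lme4 is required for the GLMM variance diagnostic", call. = FALSE)
  sizes <- table(panel$prescriber_id)
  if (all(sizes <= 1L))
    return(list(variance = NA_real_, identifiable = FALSE,
                message = "all clusters have a single observation"))
  f <- stats::as.formula(paste("outcome ~", paste(terms, collapse = " + "),
                               "+ (1 | prescriber_id)"))
  fit <- lme4::glmer(f, data = panel, family = stats::binomial(), nAGQ = 0L)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(variance = vc$vcov[1L], identifiable = TRUE,
       message = sprintf("random-intercept variance %.4g", vc$vcov[1L]))
}
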