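#' Latent-scale intraclass correlation for a logistic multilevel model
#'
#' Uses the latent-threshold convention for binary outcomes: the level-1
#' residual variance of the underlying logistic variable is
#' \eqn{\pi^2/3}, so
#' \deqn{\mathrm{ICC} = \frac{\sigma^2_u}{\sigma^2_u + \pi^2/3}.}
#'
#' @param sigma2_u Random-intercept variance (>= 0).
#' @return ICC in \eqn{[0, 1)}.
#' @export
icc_from_variance <- function(sigma2_u) {
  if (any(sigma2_u < 0)) {
    stop("sigma2_u must be non-negative", call. = FALSE)
  }
  sigma2_u / (sigma2_u + pi^2 / 3)
}

#' @rdname icc_from_variance
#' @param icc Intraclass correlation in \eqn{[0, 1)}; the inverse map
#'   returns the random-intercept variance that produces it.
#' @export
variance_from_icc <- function(icc) {
  if (any(icc < 0 | icc >= 1)) {
    stop("icc must lie in [0, 1)", call. = FALSE)
  }
  icc / (1 - icc) * pi^2 / 3
}

#' Fit a random-intercept binary logistic regression
#'
#' Cluster-level random-intercept logistic regression estimated by maximum
#' likelihood with the random effect integrated out by adaptive
#' Gauss-Hermite quadrature (\code{lme4::glmer}, \code{bobyqa} optimiser).
#' Standard errors come from the observed information. The latent-scale
#' intraclass correlation is derived from the estimated variance via
#' \code{\link{icc_from_variance}}.
#'
#' With \code{engine = "glm"} the random-intercept variance is constrained
#' to zero and an ordinary logistic regression is fitted instead — the
#' fast path used inside bootstrap loops and the reference model of the
#' cluster-effect likelihood-ratio test.
#'
#' @param formula Fixed-effects formula, e.g. \code{good_enc ~ mei_category
#'   + sanc}. Do not include the random term; it is added from
#'   \code{cluster}.
#' @param data Data.frame with the model variables.
#' @param cluster Name of the cluster id column.
#' @param nAGQ Number of adaptive quadrature points (default 7; 1 gives
#'   the Laplace approximation).
#' @param engine \code{"glmer"} (default) or \code{"glm"}.
#' @param weights Optional sampling weights for a weighted
#'   pseudo-likelihood; default \code{NULL} fits the unweighted
#'   likelihood.
#' @return An object of class \code{relogit_fit}: a list with
#'   \code{coefficients} (data.frame: term, estimate, se, z, p_value, or),
#'   \code{sigma2_u}, \code{icc}, \code{loglik}, \code{converged},
#'   \code{boundary} (TRUE when the variance estimate is at 0),
#'   \code{n_obs}, \code{n_clusters}, \code{nAGQ}, \code{engine},
#'   \code{formula}, \code{cluster} and the underlying \code{model}.
#' @export
fit_relogit <- function(formula, data, cluster, nAGQ = 7L,
                        engine = c("glmer", "glm"), weights = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  if (!cluster %in% names(data)) {
    stop("cluster column '", cluster, "' not found in data", call. = FALSE)
  }
  outcome_name <- all.vars(formula)[1]
  y <- data[[outcome_name]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome '", outcome_name, "' must be binary 0/1", call. = FALSE)
  }
  n_cl <- length(unique(data[[cluster]]))
  if (engine == "glmer" && n_cl < 2L) {
    stop("need at least 2 clusters for a random-intercept fit",
         call. = FALSE)
  }
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effects design matrix is rank deficient", call. = FALSE)
  }

  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(data), all(weights > 0))
    data[[".pseudo_weight"]] <- weights
  }

  if (engine == "glm") {
    fit <- if (is.null(weights)) {
      stats::glm(formula, data = data, family = stats::binomial())
    } else {
      stats::glm(formula, data = data, family = stats::binomial(),
                 weights = .pseudo_weight)
    }
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ll <- as.numeric(stats::logLik(fit))
    sigma2_u <- 0
    converged <- isTRUE(fit$converged)
    model <- fit
  } else {
    rhs <- paste(deparse(formula[[3]]), collapse = " ")
    full_formula <- stats::as.formula(
      paste(outcome_name, "~", rhs, "+ (1 |", cluster, ")"))
    ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                               calc.derivs = TRUE)
    model <- if (is.null(weights)) {
      lme4::glmer(full_formula, data = data, family = stats::binomial(),
                  nAGQ = nAGQ, control = ctrl)
    } else {
      lme4::glmer(full_formula, data = data, family = stats::binomial(),
                  nAGQ = nAGQ, weights = .pseudo_weight, control = ctrl)
    }
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    ll <- as.numeric(stats::logLik(model))
    vc <- as.data.frame(lme4::VarCorr(model))
    sigma2_u <- vc$vcov[vc$grp == cluster][1]
    converged <- length(model@optinfo$conv$lme4$messages) == 0L &&
      model@optinfo$conv$opt == 0L
  }

  if (any(abs(est) > 12) || any(se > 25)) {
    warning("extreme coefficient or SE: possible separation in '",
            outcome_name, "' equation", call. = FALSE)
  }
  coefs <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    z = unname(est / se),
    p_value = 2 * stats::pnorm(-abs(unname(est / se))),
    or = exp(unname(est)), row.names = NULL)

  structure(list(
    coefficients = coefs,
    sigma2_u = sigma2_u,
    icc = icc_from_variance(sigma2_u),
    loglik = ll,
    converged = converged,
    boundary = sigma2_u < 1e-8,
    n_obs = nrow(data),
    n_clusters = n_cl,
    nAGQ = if (engine == "glmer") nAGQ else NA_integer_,
    engine = engine,
    formula = formula,
    cluster = cluster,
    model = model
  ), class = "relogit_fit")
}

#' @export
print.relogit_fit <- function(x, digits = 3, ...) {
  cat("Random-intercept logistic fit (", x$engine, ")\n", sep = "")
  cat("  ", x$n_obs, "observations in", x$n_clusters, "clusters;",
      "logLik", format(x$loglik, digits = 7), "\n")
  cat(sprintf("  sigma2_u = %.4f  ICC = %.4f%s\n", x$sigma2_u, x$icc,
              if (x$boundary) "  (variance at boundary)" else ""))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  stats::printCoefmat(
    `rownames<-`(as.matrix(x$coefficients[c("estimate", "se", "z",
                                            "p_value")]),
                 x$coefficients$term),
    digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Boundary-corrected likelihood-ratio test for the cluster effect
#'
#' Compares the random-intercept fit with the ordinary logistic fit with
#' the same fixed effects. Because the null value \eqn{\sigma^2_u = 0}
#' lies on the boundary of the parameter space, the statistic's reference
#' distribution is the 50:50 mixture of a point mass at zero and
#' \eqn{\chi^2_1}; the p-value is half the \eqn{\chi^2_1} tail
#' probability (0.5 at a statistic of exactly 0).
#'
#' @param fit A \code{\link{fit_relogit}} result with
#'   \code{engine = "glmer"}.
#' @param null_fit Optional ordinary logistic fit (a \code{relogit_fit}
#'   with \code{engine = "glm"} or a \code{glm} object) with identical
#'   fixed effects; fitted automatically from the model frame when
#'   omitted.
#' @return A list with \code{statistic}, \code{df} (the mixture,
#'   reported as 0.5), \code{p_value}, \code{loglik_full},
#'   \code{loglik_null}.
#' @export
cluster_effect_lrt <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "relogit_fit"))
  if (fit$engine != "glmer") {
    stop("fit must be a random-intercept (glmer) fit", call. = FALSE)
  }
  if (is.null(null_fit)) {
    frame <- fit$model@frame
    null_ll <- as.numeric(stats::logLik(
      stats::glm(fit$formula, data = frame, family = stats::binomial())))
  } else {
    if (inherits(null_fit, "relogit_fit")) {
      if (null_fit$engine != "glm") {
        stop("null_fit must be an ordinary logistic fit", call. = FALSE)
      }
      same <- identical(sort(null_fit$coefficients$term),
                        sort(fit$coefficients$term))
      if (!same) {
        stop("null_fit fixed effects do not match the full fit",
             call. = FALSE)
      }
      null_ll <- null_fit$loglik
    } else if (inherits(null_fit, "glm")) {
      null_ll <- as.numeric(stats::logLik(null_fit))
    } else {
      stop("null_fit must be a relogit_fit or glm object", call. = FALSE)
    }
  }
  lrt_boundary(fit$loglik, null_ll)
}

#' @rdname cluster_effect_lrt
#' @param loglik_full,loglik_null Log-likelihoods of the nested fits; the
#'   statistic is \code{2 * (loglik_full - loglik_null)}, floored at 0.
#' @export
lrt_boundary <- function(loglik_full, loglik_null) {
  stat <- max(0, 2 * (loglik_full - loglik_null))
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 0.5, p_value = p,
       loglik_full = loglik_full, loglik_null = loglik_null)
}
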