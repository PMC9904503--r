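#' Product-of-coefficients effect arithmetic
#'
#' The indirect (mediated) effect of an exposure level is the product of
#' the exposure-to-mediator path \code{a} and the mediator-to-outcome
#' path \code{b}, both on the log-odds scale. The total effect is
#' \code{a*b + c} when the indirect effect is judged significant, and the
#' direct effect \code{c} alone otherwise. The proportion mediated is
#' \code{100 * me / te}, defined only when the indirect effect is
#' significant and the total effect non-zero.
#'
#' @param a Exposure-to-mediator log-odds coefficient.
#' @param b Mediator-to-outcome log-odds coefficient.
#' @return \code{indirect_effect}: the product \code{a * b}.
#' @export
indirect_effect <- function(a, b) {
  a * b
}

#' @rdname indirect_effect
#' @param me Indirect effect.
#' @param c_direct Direct (exposure-to-outcome) log-odds coefficient.
#' @param me_significant Logical: is the indirect effect significant?
#' @return \code{total_effect}: \code{me + c_direct} when
#'   \code{me_significant}, else \code{c_direct}.
#' @export
total_effect <- function(me, c_direct, me_significant = TRUE) {
  n <- max(length(me), length(c_direct), length(me_significant))
  me <- rep_len(me, n)
  c_direct <- rep_len(c_direct, n)
  sig <- rep_len(me_significant, n)
  ifelse(sig, me + c_direct, c_direct)
}

#' @rdname indirect_effect
#' @param te Total effect.
#' @return \code{proportion_mediated}: percentage \code{100 * me / te},
#'   or \code{NA} when undefined.
#' @export
proportion_mediated <- function(me, te, me_significant = TRUE) {
  n <- max(length(me), length(te), length(me_significant))
  me <- rep_len(me, n)
  te <- rep_len(te, n)
  sig <- rep_len(me_significant, n)
  ifelse(sig & te != 0, 100 * me / te, NA_real_)
}

#' Screen candidate covariates by unadjusted association
#'
#' Retains a covariate when the chi-square test of its unadjusted
#' association with the outcome has p-value below the threshold (0.30 by
#' default), the screening rule used to choose adjustment covariates for
#' the structural equations.
#'
#' @param data Data.frame with the candidate covariates and outcome.
#' @param candidates Character vector of covariate column names.
#' @param outcome Name of the binary outcome column.
#' @param threshold Retain when p < threshold (default 0.30).
#' @return Data.frame with columns \code{covariate}, \code{p_value},
#'   \code{retained}; attribute \code{retained} carries the retained
#'   names as a character vector.
#' @export
screen_covariates <- function(data, candidates, outcome,
                              threshold = 0.30) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    stop("candidate column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  p <- vapply(candidates, function(v) {
    tab <- table(data[[v]], data[[outcome]])
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  res <- data.frame(covariate = candidates, p_value = unname(p),
                    retained = unname(p) < threshold, row.names = NULL)
  attr(res, "retained") <- res$covariate[res$retained]
  res
}

#' Fit the two-equation mediation structural model
#'
#' Fits the two random-intercept logistic equations of the mediation
#' model: the mediator equation \code{mediator ~ exposure + covariates}
#' yields the a-paths (one per non-reference exposure level); the outcome
#' equation \code{outcome ~ exposure + mediator + covariates} yields the
#' b-path (mediator coefficient) and the c-paths (direct exposure
#' coefficients). Both equations share the cluster random intercept
#' structure.
#'
#' @param data Data.frame with all model columns.
#' @param exposure Name of the exposure factor (3-level MEI category by
#'   default usage; any factor with a reference first level works).
#' @param mediator,outcome Names of the binary mediator and outcome
#'   columns.
#' @param covariates Character vector of adjustment covariate names
#'   (possibly empty).
#' @param cluster Name of the cluster id column.
#' @param engine,nAGQ Passed to \code{\link{fit_relogit}}.
#' @return An object of class \code{mediation_paths}: list with
#'   \code{a}, \code{c} (named vectors over non-reference exposure
#'   levels), \code{b} (scalar), \code{me} (point indirect effects
#'   \code{a*b}), the two fits \code{fit_mediator} and
#'   \code{fit_outcome}, and the model specification.
#' @export
fit_mediation_sem <- function(data, exposure = "mei_category",
                              mediator = "sanc", outcome = "good_enc",
                              covariates = character(),
                              cluster = "cluster_id",
                              engine = c("glmer", "glm"), nAGQ = 7L) {
  engine <- match.arg(engine)
  stopifnot(is.data.frame(data))
  for (v in c(exposure, mediator, outcome, cluster)) {
    if (!v %in% names(data)) {
      stop("column '", v, "' not found in data", call. = FALSE)
    }
  }
  if (!is.factor(data[[exposure]])) {
    stop("exposure '", exposure, "' must be a factor with its reference ",
         "level first", call. = FALSE)
  }
  exp_levels <- levels(data[[exposure]])
  if (length(exp_levels) < 2L) {
    stop("exposure needs at least two levels", call. = FALSE)
  }

  rhs_m <- paste(c(exposure, covariates), collapse = " + ")
  rhs_y <- paste(c(exposure, mediator, covariates), collapse = " + ")
  f_m <- stats::as.formula(paste(mediator, "~", rhs_m))
  f_y <- stats::as.formula(paste(outcome, "~", rhs_y))

  fit_m <- fit_relogit(f_m, data, cluster, nAGQ = nAGQ, engine = engine)
  fit_y <- fit_relogit(f_y, data, cluster, nAGQ = nAGQ, engine = engine)

  non_ref <- exp_levels[-1]
  terms_exp <- paste0(exposure, non_ref)
  get_coef <- function(fit, term) {
    i <- match(term, fit$coefficients$term)
    if (is.na(i)) {
      stop("coefficient '", term, "' absent from fit", call. = FALSE)
    }
    fit$coefficients$estimate[i]
  }
  a <- stats::setNames(vapply(terms_exp, get_coef, numeric(1),
                              fit = fit_m), non_ref)
  c_direct <- stats::setNames(vapply(terms_exp, get_coef, numeric(1),
                                     fit = fit_y), non_ref)
  b <- get_coef(fit_y, mediator)

  structure(list(
    a = a, b = b, c = c_direct,
    me = indirect_effect(a, b),
    fit_mediator = fit_m, fit_outcome = fit_y,
    exposure = exposure, mediator = mediator, outcome = outcome,
    covariates = covariates, cluster = cluster,
    levels = exp_levels, engine = engine, nAGQ = nAGQ
  ), class = "mediation_paths")
}

#' @export
print.mediation_paths <- function(x, digits = 3, ...) {
  cat("Mediation path coefficients (reference:", x$levels[1], ")\n")
  for (lvl in names(x$a)) {
    cat(sprintf("  %-8s a = %+.*f  c = %+.*f  a*b = %+.*f\n", lvl,
                digits, x$a[[lvl]], digits, x$c[[lvl]],
                digits, x$me[[lvl]]))
  }
  cat(sprintf("  mediator->outcome b = %+.*f\n", digits, x$b))
  invisible(x)
}

# bias-corrected percentile interval (BC, no acceleration)
bc_interval <- function(boot, t0, conf = 0.95) {
  boot <- boot[!is.na(boot)]
  B <- length(boot)
  if (B == 0L) return(c(NA_real_, NA_real_))
  if (stats::sd(boot) == 0) return(c(t0, t0))
  prop <- (sum(boot < t0) + 0.5 * sum(boot == t0)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  alpha <- (1 - conf) / 2
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
  unname(stats::quantile(boot, probs, type = 7))
}

#' Cluster-bootstrap inference for the mediation effects
#'
#' Resamples the data \code{B} times (by default whole clusters, sampled
#' with replacement to the original cluster count, respecting the survey
#' design; optionally individual women), refits both structural equations
#' on each resample and recomputes the indirect, direct and total effects
#' per exposure level. Reported are the bootstrap standard error (resample
#' standard deviation) and the bias-corrected (BC) percentile interval —
#' the percentile interval shifted by \eqn{z_0} estimated from the
#' fraction of resample statistics below the point estimate, with no
#' acceleration term. An effect is flagged significant when its 95% BC
#' interval excludes 0. Following the product-of-coefficients rule, the
#' total effect is \code{a*b + c} when the indirect effect is significant
#' and \code{c} otherwise, and the proportion mediated is reported only
#' for significant indirect effects.
#'
#' Resample refits default to the ordinary-logistic fast path
#' (\code{boot_engine = "glm"}): cluster resampling already accounts for
#' within-cluster dependence in the resulting intervals, and refitting
#' the quadrature likelihood thousands of times is rarely worth its cost.
#' Set \code{boot_engine = "glmer"} (with \code{boot_nAGQ}, default 1 =
#' Laplace) to integrate the random intercept in every resample. Failed
#' resample fits (non-convergence, separation, lost factor levels) are
#' dropped and counted; more than 10% failures adds a warning flag to the
#' result, and all resamples failing is an error.
#'
#' @inheritParams fit_mediation_sem
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; \code{(seed, B, unit)} fully determine the
#'   resample index sequences, drawn before any fitting.
#' @param unit Resampling unit: \code{"cluster"} (default) or
#'   \code{"woman"}.
#' @param boot_engine Engine for resample refits (see Details).
#' @param boot_nAGQ Quadrature points for \code{boot_engine = "glmer"}.
#' @param conf Confidence level of the BC intervals (default 0.95).
#' @param paths Optionally a precomputed \code{\link{fit_mediation_sem}}
#'   result to use as the point fit (its specification overrides the
#'   other model arguments).
#' @return An object of class \code{mediation_result}: list with
#'   \code{effects} (data.frame: level, effect in direct/indirect/total,
#'   estimate, boot_se, ci_low, ci_high, or, or_ci_low, or_ci_high,
#'   significant), \code{b} (the same summary row for the
#'   mediator-to-outcome path), \code{pme} (per level; \code{NA} when
#'   undefined), \code{paths} (the point fit), \code{B},
#'   \code{n_failed}, \code{high_failure_rate}, \code{seed},
#'   \code{unit}, \code{conf}.
#' @export
bootstrap_mediation <- function(data, exposure = "mei_category",
                                mediator = "sanc", outcome = "good_enc",
                                covariates = character(),
                                cluster = "cluster_id",
                                B = 1000L, seed = 1L,
                                unit = c("cluster", "woman"),
                                engine = c("glmer", "glm"), nAGQ = 7L,
                                boot_engine = c("glm", "glmer"),
                                boot_nAGQ = 1L, conf = 0.95,
                                paths = NULL) {
  unit <- match.arg(unit)
  boot_engine <- match.arg(boot_engine)
  engine <- match.arg(engine)
  B <- as.integer(B)
  if (is.na(B) || B < 2L) stop("B must be >= 2", call. = FALSE)

  if (is.null(paths)) {
    paths <- fit_mediation_sem(data, exposure, mediator, outcome,
                               covariates, cluster, engine = engine,
                               nAGQ = nAGQ)
  } else {
    stopifnot(inherits(paths, "mediation_paths"))
    exposure <- paths$exposure; mediator <- paths$mediator
    outcome <- paths$outcome; covariates <- paths$covariates
    cluster <- paths$cluster
  }
  non_ref <- names(paths$a)

  # all resample index sequences are drawn up front: (seed, B, unit)
  # fully determine them
  set.seed(as.integer(seed))
  n <- nrow(data)
  if (unit == "cluster") {
    rows_by_cluster <- split(seq_len(n), as.character(data[[cluster]]))
    n_cl <- length(rows_by_cluster)
    plans <- lapply(seq_len(B), function(r) {
      sample.int(n_cl, n_cl, replace = TRUE)
    })
  } else {
    plans <- lapply(seq_len(B), function(r) {
      sample.int(n, n, replace = TRUE)
    })
  }

  rhs_m <- paste(c(exposure, covariates), collapse = " + ")
  rhs_y <- paste(c(exposure, mediator, covariates), collapse = " + ")
  f_m <- stats::as.formula(paste(mediator, "~", rhs_m))
  f_y <- stats::as.formula(paste(outcome, "~", rhs_y))
  terms_exp <- paste0(exposure, non_ref)

  boot_one <- if (boot_engine == "glm") {
    # model matrices built once; resamples index rows
    X_m <- stats::model.matrix(f_m, data)
    X_y <- stats::model.matrix(f_y, data)
    y_m <- data[[mediator]]
    y_y <- data[[outcome]]
    function(idx) {
      cf_m <- glm_fit_coefs(X_m[idx, , drop = FALSE], y_m[idx])
      if (is.null(cf_m)) return(NULL)
      cf_y <- glm_fit_coefs(X_y[idx, , drop = FALSE], y_y[idx])
      if (is.null(cf_y)) return(NULL)
      c(a = unname(cf_m[terms_exp]), b = unname(cf_y[[mediator]]),
        c = unname(cf_y[terms_exp]))
    }
  } else {
    function(idx) {
      d <- data[idx$rows, , drop = FALSE]
      d[[cluster]] <- idx$new_cluster
      fit <- tryCatch(suppressWarnings(
        fit_mediation_sem(d, exposure, mediator, outcome, covariates,
                          cluster, engine = "glmer", nAGQ = boot_nAGQ)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      if (any(abs(c(fit$a, fit$b, fit$c)) > 15)) return(NULL)
      c(a = unname(fit$a), b = fit$b, c = unname(fit$c))
    }
  }

  k <- length(non_ref)
  draws <- matrix(NA_real_, B, 2 * k + 1,
                  dimnames = list(NULL, c(paste0("a.", non_ref), "b",
                                          paste0("c.", non_ref))))
  for (r in seq_len(B)) {
    if (unit == "cluster") {
      chosen <- plans[[r]]
      idx_rows <- unlist(rows_by_cluster[chosen], use.names = FALSE)
      if (boot_engine == "glm") {
        est <- boot_one(idx_rows)
      } else {
        new_cl <- rep.int(seq_along(chosen),
                          lengths(rows_by_cluster[chosen]))
        est <- boot_one(list(rows = idx_rows, new_cluster = new_cl))
      }
    } else {
      idx_rows <- plans[[r]]
      est <- if (boot_engine == "glm") {
        boot_one(idx_rows)
      } else {
        boot_one(list(rows = idx_rows,
                      new_cluster = data[[cluster]][idx_rows]))
      }
    }
    if (!is.null(est)) draws[r, ] <- est
  }

  ok <- stats::complete.cases(draws)
  n_failed <- B - sum(ok)
  if (!any(ok)) {
    stop("all ", B, " bootstrap resamples failed to fit", call. = FALSE)
  }
  high_failure <- n_failed > 0.1 * B
  if (high_failure) {
    warning(sprintf("%d of %d bootstrap resamples failed", n_failed, B),
            call. = FALSE)
  }
  draws <- draws[ok, , drop = FALSE]

  summarise_effect <- function(boot, t0) {
    ci <- bc_interval(boot, t0, conf)
    data.frame(estimate = t0, boot_se = stats::sd(boot),
               ci_low = ci[1], ci_high = ci[2],
               or = exp(t0), or_ci_low = exp(ci[1]),
               or_ci_high = exp(ci[2]),
               significant = ci[1] > 0 | ci[2] < 0)
  }

  eff <- NULL
  pme <- data.frame(level = non_ref, pme = NA_real_,
                    pme_ci_low = NA_real_, pme_ci_high = NA_real_,
                    row.names = NULL)
  for (lvl in non_ref) {
    a0 <- paths$a[[lvl]]; c0 <- paths$c[[lvl]]; b0 <- paths$b
    a_r <- draws[, paste0("a.", lvl)]
    c_r <- draws[, paste0("c.", lvl)]
    b_r <- draws[, "b"]
    me_r <- indirect_effect(a_r, b_r)
    me0 <- indirect_effect(a0, b0)
    row_me <- summarise_effect(me_r, me0)
    me_sig <- row_me$significant
    te0 <- total_effect(me0, c0, me_sig)
    te_r <- total_effect(me_r, c_r, me_sig)
    row_dir <- summarise_effect(c_r, c0)
    row_te <- summarise_effect(te_r, te0)
    eff <- rbind(eff, cbind(level = lvl,
                            effect = c("direct", "indirect", "total"),
                            rbind(row_dir, row_me, row_te)))
    if (me_sig && te0 != 0) {
      pme_r <- proportion_mediated(me_r, te_r)
      pme_ci <- bc_interval(pme_r, proportion_mediated(me0, te0), conf)
      pme[pme$level == lvl, c("pme", "pme_ci_low", "pme_ci_high")] <-
        c(proportion_mediated(me0, te0), pme_ci)
    }
  }
  rownames(eff) <- NULL
  b_row <- cbind(effect = "mediator", summarise_effect(draws[, "b"],
                                                       paths$b))

  structure(list(
    effects = eff, b = b_row, pme = pme, paths = paths,
    B = B, n_failed = n_failed, high_failure_rate = high_failure,
    seed = as.integer(seed), unit = unit, conf = conf,
    boot_engine = boot_engine
  ), class = "mediation_result")
}

glm_fit_coefs <- function(X, y) {
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  cf <- fit$coefficients
  if (anyNA(cf) || any(abs(cf) > 15)) return(NULL)
  cf
}

#' @export
print.mediation_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Mediation result: %d bootstrap resamples (%s unit, seed %d%s)\n",
    x$B, x$unit, x$seed,
    if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  cat("Reference exposure level:", x$paths$levels[1], "\n\n")
  fmt <- function(r) {
    sprintf("  %-8s %-9s %+.*f (%.2f)  OR %.2f [%.2f-%.2f]%s",
            r$level, r$effect, digits, r$estimate, r$boot_se, r$or,
            r$or_ci_low, r$or_ci_high,
            if (isTRUE(r$significant)) " *" else "")
  }
  for (i in seq_len(nrow(x$effects))) {
    cat(fmt(x$effects[i, ]), "\n")
  }
  b <- x$b
  cat(sprintf("  mediator->outcome b = %+.*f (%.2f)  OR %.2f [%.2f-%.2f]%s\n",
              digits, b$estimate, b$boot_se, b$or, b$or_ci_low,
              b$or_ci_high, if (isTRUE(b$significant)) " *" else ""))
  for (i in seq_len(nrow(x$pme))) {
    p <- x$pme[i, ]
    cat(sprintf("  PME %-8s %s\n", p$level,
                if (is.na(p$pme)) "-" else sprintf("%.2f%%", p$pme)))
  }
  invisible(x)
}
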