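#' Configuration for the clustered synthetic survey generator
#'
#' Builds a validated configuration for \code{\link{generate_population}}.
#' Defaults emulate the structure of a two-stage cluster survey of home
#' births: 672 clusters (enumeration areas) of 4 eligible women each
#' (roughly the analysed home-birth subsample an EA of ~30 households
#' yields), indicator prevalences matching the observed dimension means,
#' exposure-to-mediator and exposure/mediator-to-outcome path coefficients
#' equal to the published multilevel estimates, and random-intercept
#' variances solving the published latent-scale intraclass correlations
#' (0.26 for the mediator equation, 0.13 for the outcome equation).
#'
#' @param n_clusters Number of clusters (>= 2).
#' @param women_per_cluster Women per cluster: the fixed size, or the mean
#'   of a Poisson size distribution when \code{cluster_size = "poisson"}.
#' @param cluster_size \code{"fixed"} or \code{"poisson"}.
#' @param schema Indicator schema (\code{\link{mei_schema}}).
#' @param indicator_prevalences Named probability in (0,1) per indicator;
#'   a per-dimension named vector is expanded to the dimension's
#'   indicators.
#' @param latent_loading Loading \eqn{\lambda \in [0, 1)} of a shared
#'   woman-level Gaussian factor inducing positive dependence between
#'   indicators through a Gaussian copula (marginals preserved); 0 means
#'   independent draws.
#' @param true_paths Named log-odds path coefficients:
#'   \code{a_avg}, \code{a_high} (exposure to mediator), \code{b}
#'   (mediator to outcome), \code{c_avg}, \code{c_high} (exposure to
#'   outcome, direct).
#' @param covariate_effects List with named numeric vectors
#'   \code{mediator} and \code{outcome}; allowed names are
#'   \code{age_20_30}, \code{age_30plus}, \code{bo_second_third},
#'   \code{bo_fourth_plus}, \code{res_urban}, \code{reg_central},
#'   \code{reg_western}. Defaults to all zero.
#' @param intercepts Named log-odds intercepts \code{mediator},
#'   \code{outcome} (conditional on the random intercept). The defaults
#'   were calibrated by Gauss-Hermite integration over the random
#'   intercepts so that, under the default paths and ICCs, the marginal
#'   SANC prevalence is 5.28% and the marginal good-ENC prevalence 7.6%.
#' @param sigma2_u Named random-intercept variances \code{mediator},
#'   \code{outcome} (>= 0).
#' @param enc_base_probs Named base probabilities for the five ENC
#'   components (see \code{\link{enc_components}}, without the
#'   \code{enc_} prefix here).
#' @param covariate_probs List of category probabilities for
#'   \code{age_group}, \code{birth_order}, \code{residence},
#'   \code{region}.
#' @param sanc_visit_lambda Poisson rate for visit counts: non-SANC women
#'   draw counts from 0-7 with Poisson(\code{sanc_visit_lambda}) weights,
#'   SANC women draw 8 + Poisson(\code{sanc_visit_lambda}).
#' @param seed Integer root seed; per-cluster substreams are derived from
#'   it so earlier clusters are unchanged when \code{n_clusters} grows.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_clusters = 672L,
                             women_per_cluster = 4L,
                             cluster_size = c("fixed", "poisson"),
                             schema = default_mei_schema(),
                             indicator_prevalences = NULL,
                             latent_loading = 0,
                             true_paths = c(a_avg = 0.73, a_high = 1.52,
                                            b = 0.72, c_avg = -0.01,
                                            c_high = 0.53),
                             covariate_effects = NULL,
                             intercepts = c(mediator = -4.19,
                                            outcome = -2.86),
                             sigma2_u = c(
                               mediator = variance_from_icc(0.26),
                               outcome = variance_from_icc(0.13)),
                             enc_base_probs = c(
                               cord_clean_cut = 0.863,
                               nothing_applied = 0.471,
                               dried_quickly = 0.628,
                               bath_delayed = 0.472,
                               early_breastfeeding = 0.690),
                             covariate_probs = list(
                               age_group = c(`15-20` = 0.1727,
                                             `20-30` = 0.6058,
                                             `30+` = 0.2215),
                               birth_order = c(first = 0.2944,
                                               second_third = 0.5263,
                                               fourth_plus = 0.1793),
                               residence = c(rural = 0.8071,
                                             urban = 0.1929),
                               region = c(eastern = 0.3210,
                                          central = 0.3881,
                                          western = 0.2909)),
                             sanc_visit_lambda = 2,
                             seed = 2017L) {
  cluster_size <- match.arg(cluster_size)
  stopifnot(inherits(schema, "mei_schema"))
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 2L) {
    stop("n_clusters must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(women_per_cluster) || women_per_cluster < 1) {
    stop("women_per_cluster must be >= 1", call. = FALSE)
  }

  # dimension-level means of the survey's achieved indicators
  default_dim_prev <- c(decision = 0.686, ipv_attitude = 0.927,
                        health_access = 0.600, social_independence = 0.423,
                        assets = 0.400)
  prev <- expand_indicator_prevalences(indicator_prevalences, schema,
                                       default_dim_prev)
  if (any(prev <= 0 | prev >= 1)) {
    stop("indicator prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  if (latent_loading < 0 || latent_loading >= 1) {
    stop("latent_loading must lie in [0, 1)", call. = FALSE)
  }

  path_names <- c("a_avg", "a_high", "b", "c_avg", "c_high")
  tp <- c(a_avg = 0, a_high = 0, b = 0, c_avg = 0, c_high = 0)
  if (!is.null(true_paths)) {
    if (is.null(names(true_paths)) ||
        !all(names(true_paths) %in% path_names)) {
      stop("true_paths names must be among: ",
           paste(path_names, collapse = ", "), call. = FALSE)
    }
    tp[names(true_paths)] <- true_paths
  }

  ce_names <- c("age_20_30", "age_30plus", "bo_second_third",
                "bo_fourth_plus", "res_urban", "reg_central", "reg_western")
  zero_ce <- stats::setNames(rep(0, length(ce_names)), ce_names)
  ce <- list(mediator = zero_ce, outcome = zero_ce)
  if (!is.null(covariate_effects)) {
    for (eq in names(covariate_effects)) {
      if (!eq %in% c("mediator", "outcome")) {
        stop("covariate_effects entries must be 'mediator'/'outcome'",
             call. = FALSE)
      }
      v <- covariate_effects[[eq]]
      if (is.null(names(v)) || !all(names(v) %in% ce_names)) {
        stop("covariate effect names must be among: ",
             paste(ce_names, collapse = ", "), call. = FALSE)
      }
      ce[[eq]][names(v)] <- v
    }
  }

  stopifnot(all(c("mediator", "outcome") %in% names(intercepts)),
            all(c("mediator", "outcome") %in% names(sigma2_u)))
  if (any(sigma2_u < 0)) stop("sigma2_u must be >= 0", call. = FALSE)
  if (any(enc_base_probs <= 0 | enc_base_probs >= 1)) {
    stop("ENC base probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  for (v in covariate_probs) {
    if (any(v <= 0) || abs(sum(v) - 1) > 1e-6) {
      stop("covariate probabilities must be positive and sum to 1",
           call. = FALSE)
    }
  }

  structure(list(
    n_clusters = n_clusters, women_per_cluster = women_per_cluster,
    cluster_size = cluster_size, schema = schema,
    indicator_prevalences = prev, latent_loading = latent_loading,
    true_paths = tp, covariate_effects = ce,
    intercepts = intercepts[c("mediator", "outcome")],
    sigma2_u = sigma2_u[c("mediator", "outcome")],
    enc_base_probs = enc_base_probs, covariate_probs = covariate_probs,
    sanc_visit_lambda = sanc_visit_lambda, seed = as.integer(seed)
  ), class = "synthetic_config")
}

expand_indicator_prevalences <- function(prev, schema, default_dim_prev) {
  full <- stats::setNames(numeric(length(schema$indicators)),
                          schema$indicators)
  for (d in schema$dimensions) {
    p <- if (d$name %in% names(default_dim_prev)) {
      default_dim_prev[[d$name]]
    } else {
      0.5
    }
    full[d$indicators] <- p
  }
  if (!is.null(prev)) {
    if (is.null(names(prev))) {
      stop("indicator_prevalences must be named", call. = FALSE)
    }
    dim_names <- names(schema$dimensions)
    for (nm in names(prev)) {
      if (nm %in% dim_names) {
        full[schema$dimensions[[nm]]$indicators] <- prev[[nm]]
      } else if (nm %in% schema$indicators) {
        full[nm] <- prev[[nm]]
      } else {
        stop("unknown indicator or dimension in prevalences: ", nm,
             call. = FALSE)
      }
    }
  }
  full
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic survey config:", x$n_clusters, "clusters x",
      x$women_per_cluster, paste0("women (", x$cluster_size, ")"),
      "| seed", x$seed, "\n")
  cat("  paths:", paste(names(x$true_paths), round(x$true_paths, 3),
                        sep = "=", collapse = ", "), "\n")
  cat(sprintf("  sigma2_u: mediator %.3f (ICC %.3f), outcome %.3f (ICC %.3f)\n",
              x$sigma2_u[["mediator"]], icc_from_variance(x$sigma2_u[["mediator"]]),
              x$sigma2_u[["outcome"]], icc_from_variance(x$sigma2_u[["outcome"]])))
  invisible(x)
}

#' Read a generator configuration from a YAML file
#'
#' Fields mirror the arguments of \code{\link{synthetic_config}}; an
#' optional \code{schema} field may name a schema YAML file (resolved
#' relative to the config file).
#'
#' @param path Path to a YAML configuration file.
#' @return A \code{\link{synthetic_config}}.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$schema) && is.character(raw$schema)) {
    schema_path <- raw$schema
    if (!file.exists(schema_path)) {
      schema_path <- file.path(dirname(path), raw$schema)
    }
    raw$schema <- read_mei_schema(schema_path)
  }
  for (nm in c("indicator_prevalences", "true_paths", "intercepts",
               "sigma2_u", "enc_base_probs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$covariate_probs)) {
    raw$covariate_probs <- lapply(raw$covariate_probs, unlist)
  }
  if (!is.null(raw$covariate_effects)) {
    raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  }
  do.call(synthetic_config, raw)
}

#' Generate a clustered synthetic population of woman-level records
#'
#' Simulates one woman-level table under the two-equation multilevel
#' logistic model the package fits. Per cluster, random intercepts
#' \eqn{u^{med} \sim N(0, \sigma^2_{u,med})} and
#' \eqn{u^{out} \sim N(0, \sigma^2_{u,out})} are drawn; per woman,
#' covariates and binary empowerment indicators are drawn (independently,
#' or positively dependent through a shared Gaussian factor), the MEI
#' category is computed from the drawn indicators, the mediator
#' (SANC, 8+ skilled antenatal visits) is drawn from
#' \eqn{\mathrm{logit}^{-1}(\alpha_m + a\,\mathrm{MEI} + x'\gamma_m + u^{med})}
#' and the good-ENC outcome from
#' \eqn{\mathrm{logit}^{-1}(\alpha_y + c\,\mathrm{MEI} + b\,\mathrm{SANC}
#' + x'\gamma_y + u^{out})}. The five ENC components are then drawn
#' consistently with the outcome: all five are 1 when good ENC = 1;
#' otherwise components are drawn at their base probabilities and, if all
#' five came up 1, one uniformly chosen component is forced to 0.
#'
#' Reproducibility contract: the root seed determines a per-cluster
#' substream seed, so the same config and seed give a byte-identical
#' table, and increasing \code{n_clusters} leaves earlier clusters
#' unchanged.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A data.frame with one row per woman: \code{woman_id},
#'   \code{cluster_id}, the indicator columns of the schema, the five
#'   \code{enc_*} component columns, \code{sanc_visits}, \code{age_group},
#'   \code{birth_order}, \code{residence}, \code{region} and
#'   \code{weight} (all 1). Attributes \code{seed} and \code{true_params}
#'   echo the generating configuration.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cluster_seeds <- sample.int(.Machine$integer.max - 1L, config$n_clusters,
                              replace = TRUE)
  pieces <- vector("list", config$n_clusters)
  for (i in seq_len(config$n_clusters)) {
    pieces[[i]] <- generate_cluster(config, i, cluster_seeds[i])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$woman_id <- seq_len(nrow(out))
  out <- out[c("woman_id", setdiff(names(out), "woman_id"))]
  attr(out, "seed") <- config$seed
  attr(out, "true_params") <- true_params(config)
  out
}

generate_cluster <- function(config, i, cluster_seed) {
  set.seed(cluster_seed)
  u_med <- stats::rnorm(1, 0, sqrt(config$sigma2_u[["mediator"]]))
  u_out <- stats::rnorm(1, 0, sqrt(config$sigma2_u[["outcome"]]))
  n <- if (config$cluster_size == "poisson") {
    stats::rpois(1, config$women_per_cluster)
  } else {
    as.integer(config$women_per_cluster)
  }
  if (n == 0L) return(NULL)

  cp <- config$covariate_probs
  age_group <- sample(factor(names(cp$age_group),
                             levels = names(cp$age_group)),
                      n, TRUE, prob = cp$age_group)
  birth_order <- sample(factor(names(cp$birth_order),
                               levels = names(cp$birth_order)),
                        n, TRUE, prob = cp$birth_order)
  residence <- sample(factor(names(cp$residence),
                             levels = names(cp$residence)),
                      n, TRUE, prob = cp$residence)
  region <- sample(factor(names(cp$region), levels = names(cp$region)),
                   n, TRUE, prob = cp$region)

  # indicators: Gaussian-copula threshold model preserves each marginal
  prev <- config$indicator_prevalences
  k <- length(prev)
  lam <- config$latent_loading
  f <- if (lam > 0) stats::rnorm(n) else numeric(n)
  eps <- matrix(stats::rnorm(n * k), n, k)
  z <- lam * f + sqrt(1 - lam^2) * eps
  y <- matrix(as.integer(t(t(z) < stats::qnorm(prev))), n, k,
              dimnames = list(NULL, names(prev)))
  ind <- as.data.frame(y)

  scores <- compute_mei(ind, schema = config$schema)
  is_avg <- scores$mei_category == "average"
  is_high <- scores$mei_category == "high"

  ce_m <- config$covariate_effects$mediator
  ce_y <- config$covariate_effects$outcome
  cov_lp <- function(ce) {
    ce[["age_20_30"]] * (age_group == "20-30") +
      ce[["age_30plus"]] * (age_group == "30+") +
      ce[["bo_second_third"]] * (birth_order == "second_third") +
      ce[["bo_fourth_plus"]] * (birth_order == "fourth_plus") +
      ce[["res_urban"]] * (residence == "urban") +
      ce[["reg_central"]] * (region == "central") +
      ce[["reg_western"]] * (region == "western")
  }
  tp <- config$true_paths
  lp_med <- config$intercepts[["mediator"]] + tp[["a_avg"]] * is_avg +
    tp[["a_high"]] * is_high + cov_lp(ce_m) + u_med
  sanc <- stats::rbinom(n, 1, stats::plogis(lp_med))

  lam_v <- config$sanc_visit_lambda
  low_w <- stats::dpois(0:7, lam_v)
  visits <- integer(n)
  n0 <- sum(sanc == 0)
  if (n0 > 0) visits[sanc == 0] <- sample(0:7, n0, TRUE, prob = low_w)
  if (n0 < n) visits[sanc == 1] <- 8L + stats::rpois(n - n0, lam_v)

  lp_out <- config$intercepts[["outcome"]] + tp[["c_avg"]] * is_avg +
    tp[["c_high"]] * is_high + tp[["b"]] * sanc + cov_lp(ce_y) + u_out
  good <- stats::rbinom(n, 1, stats::plogis(lp_out))

  bp <- config$enc_base_probs
  comp <- matrix(stats::rbinom(n * 5L, 1, rep(bp, each = n)), n, 5L,
                 dimnames = list(NULL, enc_components()))
  comp[good == 1, ] <- 1L
  clash <- good == 0 & rowSums(comp) == 5L
  if (any(clash)) {
    drop_col <- sample.int(5L, sum(clash), replace = TRUE)
    comp[cbind(which(clash), drop_col)] <- 0L
  }

  cbind(
    data.frame(cluster_id = sprintf("EA%04d", i)),
    ind,
    as.data.frame(comp),
    data.frame(sanc_visits = visits, age_group = age_group,
               birth_order = birth_order, residence = residence,
               region = region, weight = 1)
  )
}

#' Ground-truth parameter report for a generator configuration
#'
#' Returns the exact generating values so recovery experiments can compare
#' estimates with truth.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A list with elements \code{paths} (a_avg, a_high, b, c_avg,
#'   c_high), \code{intercepts}, \code{sigma2_u}, \code{icc} (latent-scale
#'   intraclass correlations implied by \code{sigma2_u}),
#'   \code{covariate_effects}, \code{indicator_prevalences},
#'   \code{enc_base_probs} and \code{seed}.
#' @export
true_params <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  list(
    paths = config$true_paths,
    intercepts = config$intercepts,
    sigma2_u = config$sigma2_u,
    icc = c(mediator = icc_from_variance(config$sigma2_u[["mediator"]]),
            outcome = icc_from_variance(config$sigma2_u[["outcome"]])),
    covariate_effects = config$covariate_effects,
    indicator_prevalences = config$indicator_prevalences,
    enc_base_probs = config$enc_base_probs,
    seed = config$seed
  )
}
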