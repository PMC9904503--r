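#' Pearson chi-square test of association for a contingency table
#'
#' Thin validated wrapper around the Pearson chi-square test (no
#' continuity correction), used for the unadjusted association tables.
#'
#' @param tab A matrix or table of non-negative counts with at least two
#'   rows and two columns and no zero row/column margins.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chisq_association <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Prevalence with 95% confidence interval
#'
#' Point prevalence with a normal-approximation (Wald) interval, clipped
#' to \eqn{[0, 1]}. When per-observation values and cluster ids are
#' supplied, a cluster-bootstrap percentile interval is computed instead,
#' acknowledging within-cluster correlation.
#'
#' @param x Either the number of successes (with \code{n} supplied) or a
#'   0/1 vector of observations.
#' @param n Number of trials when \code{x} is a count.
#' @param cluster Optional cluster ids (same length as \code{x}) enabling
#'   the cluster-bootstrap interval; only valid when \code{x} is a
#'   vector.
#' @param conf Confidence level (default 0.95).
#' @param B Bootstrap resamples for the cluster interval.
#' @param seed Seed for the cluster bootstrap.
#' @return List with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{n}, \code{method}.
#' @export
prevalence_ci <- function(x, n = NULL, cluster = NULL, conf = 0.95,
                          B = 1000L, seed = 1L) {
  if (length(x) == 1L && !is.null(n)) {
    if (n <= 0) stop("n must be positive", call. = FALSE)
    if (x < 0 || x > n) stop("need 0 <= successes <= n", call. = FALSE)
    successes <- x
    obs <- NULL
  } else {
    if (length(x) == 0L) stop("no observations supplied", call. = FALSE)
    if (!all(x %in% c(0, 1))) stop("x must be 0/1", call. = FALSE)
    obs <- x
    successes <- sum(x)
    n <- length(x)
  }
  p <- successes / n
  if (!is.null(cluster) && !is.null(obs)) {
    stopifnot(length(cluster) == length(obs))
    set.seed(as.integer(seed))
    rows <- split(seq_along(obs), as.character(cluster))
    n_cl <- length(rows)
    boot <- vapply(seq_len(B), function(r) {
      idx <- unlist(rows[sample.int(n_cl, n_cl, replace = TRUE)],
                    use.names = FALSE)
      mean(obs[idx])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
    method <- "cluster bootstrap percentile"
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
    method <- "Wald"
  }
  list(estimate = p, ci_low = ci[1], ci_high = ci[2], n = n,
       method = method)
}

#' Descriptive association table for the outcome
#'
#' For each listed variable: level counts and percentages, outcome
#' prevalence per level (as a percentage, with Wald 95% CI) and the
#' Pearson chi-square p-value of the unadjusted association with the
#' outcome.
#'
#' @param data Data.frame with the variables and binary outcome.
#' @param variables Character vector of variable names to tabulate.
#' @param outcome Name of the binary outcome column.
#' @return Data.frame with columns \code{variable}, \code{level},
#'   \code{n}, \code{pct}, \code{prev_pct}, \code{ci_low}, \code{ci_high},
#'   \code{p_value} (repeated within variable).
#' @export
association_table <- function(data, variables, outcome) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  out <- NULL
  for (v in variables) {
    if (!v %in% names(data)) {
      stop("variable '", v, "' not found in data", call. = FALSE)
    }
    x <- data[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(x))
    tab <- table(factor(x, levels = lv), data[[outcome]])
    p <- chisq_association(tab)$p_value
    for (l in lv) {
      sel <- x == l
      n_l <- sum(sel)
      ci <- prevalence_ci(sum(data[[outcome]][sel]), n_l)
      out <- rbind(out, data.frame(
        variable = v, level = as.character(l), n = n_l,
        pct = 100 * n_l / nrow(data),
        prev_pct = 100 * ci$estimate,
        ci_low = 100 * ci$ci_low, ci_high = 100 * ci$ci_high,
        p_value = p, row.names = NULL))
    }
  }
  out
}

record_required_columns <- function(schema) {
  c("cluster_id", schema$indicators, enc_components(), "sanc_visits",
    "age_group", "birth_order", "residence", "region")
}

#' Read and validate a woman-level record table
#'
#' Reads a delimited text table of woman-level records (the format
#' written by \code{\link{write_records}}) and validates it against the
#' record dictionary: a \code{cluster_id}, every schema indicator, the
#' five ENC component columns, \code{sanc_visits} and the four
#' covariates. Missing columns are an error listing the names; binary
#' columns must be strictly 0/1.
#'
#' @param path Path to a tab-separated table with a header.
#' @param schema The \code{\link{mei_schema}} whose indicators the table
#'   must supply.
#' @return A validated data.frame with covariates as factors.
#' @export
read_records <- function(path, schema = default_mei_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, comment.char = "#")
  validate_records(data, schema)
}

#' @rdname read_records
#' @param data A record data.frame to validate (and coerce covariates to
#'   factors).
#' @export
validate_records <- function(data, schema = default_mei_schema()) {
  req <- record_required_columns(schema)
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("record table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(as.character(data$cluster_id))) ||
      anyNA(data$cluster_id)) {
    stop("cluster_id must be non-empty", call. = FALSE)
  }
  bin_cols <- c(schema$indicators, enc_components())
  for (v in bin_cols) {
    if (anyNA(data[[v]]) || !all(data[[v]] %in% c(0, 1))) {
      stop("column '", v, "' must be binary 0/1 with no missing values",
           call. = FALSE)
    }
  }
  if (anyNA(data$sanc_visits) || any(data$sanc_visits < 0)) {
    stop("sanc_visits must be non-negative", call. = FALSE)
  }
  if (!"weight" %in% names(data)) data$weight <- 1
  if (any(data$weight <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  lv <- list(age_group = c("15-20", "20-30", "30+"),
             birth_order = c("first", "second_third", "fourth_plus"),
             residence = c("rural", "urban"),
             region = c("eastern", "central", "western"))
  for (v in names(lv)) {
    vals <- as.character(data[[v]])
    bad <- setdiff(unique(vals), lv[[v]])
    if (length(bad)) {
      stop("column '", v, "' has unknown level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    data[[v]] <- factor(vals, levels = lv[[v]])
  }
  data
}

#' Write a record table as delimited text
#'
#' @param data Record data.frame.
#' @param path Output path (tab-separated, with header).
#' @return Invisibly, \code{path}.
#' @export
write_records <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

hash_config <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one of \code{input} (path to a record table) or
#' \code{synthetic} (a \code{\link{synthetic_config}}) must be supplied.
#'
#' @param input Path to a woman-level record table (see
#'   \code{\link{read_records}}), or \code{NULL}.
#' @param synthetic A \code{\link{synthetic_config}}, or \code{NULL}.
#' @param schema Indicator schema used for scoring and validation.
#' @param cuts MEI category cut points (see \code{\link{categorize_mei}}).
#' @param covariates Candidate adjustment covariates to screen.
#' @param screen_threshold Retain covariates with unadjusted chi-square
#'   p below this value (default 0.30).
#' @param B,seed,unit Bootstrap settings (see
#'   \code{\link{bootstrap_mediation}}); \code{seed} drives the bootstrap
#'   only — the generator uses the seed inside \code{synthetic}.
#' @param engine,nAGQ Point-fit engine settings.
#' @param boot_engine,boot_nAGQ Resample refit engine settings.
#' @param sanc_threshold Visit count defining the mediator (default 8).
#' @param verbose Log stage-level progress and record counts.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            schema = default_mei_schema(),
                            cuts = c(low = 0.50, high = 0.75),
                            covariates = c("age_group", "birth_order",
                                           "residence", "region"),
                            screen_threshold = 0.30,
                            B = 1000L, seed = 1L,
                            unit = c("cluster", "woman"),
                            engine = c("glmer", "glm"), nAGQ = 7L,
                            boot_engine = c("glm", "glmer"),
                            boot_nAGQ = 1L,
                            sanc_threshold = 8L,
                            verbose = TRUE) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of `input` and `synthetic` must be set",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(
    input = input, synthetic = synthetic, schema = schema, cuts = cuts,
    covariates = covariates, screen_threshold = screen_threshold,
    B = as.integer(B), seed = as.integer(seed),
    unit = match.arg(unit), engine = match.arg(engine),
    nAGQ = as.integer(nAGQ), boot_engine = match.arg(boot_engine),
    boot_nAGQ = as.integer(boot_nAGQ),
    sanc_threshold = as.integer(sanc_threshold),
    verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: load or simulate records, validate them,
#' compute MEI scores and categories, derive the good-ENC outcome and the
#' SANC mediator, produce the descriptive tables (ENC component
#' distribution, dimension summary, unadjusted association table), screen
#' covariates, fit the two multilevel structural equations (with ICC and
#' cluster-effect LRT per equation) and run the cluster bootstrap for
#' the mediation effects.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{pipeline_result}: list with
#'   \code{records} (scored, derived), \code{enc_distribution},
#'   \code{dimension_summary}, \code{association}, \code{screening},
#'   \code{mediation} (a \code{\link{bootstrap_mediation}} result),
#'   \code{icc} and \code{lrt} (per equation), and \code{metadata}
#'   (seed(s), config hash, package version, record counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message("[pipeline] ", ...)

  if (!is.null(config$input)) {
    log_msg("reading records from ", config$input)
    records <- read_records(config$input, config$schema)
    gen_seed <- NA_integer_
  } else {
    log_msg("generating synthetic population (seed ",
            config$synthetic$seed, ")")
    records <- generate_population(config$synthetic)
    records <- validate_records(records, config$schema)
    gen_seed <- config$synthetic$seed
  }
  log_msg(nrow(records), " women in ",
          length(unique(records$cluster_id)), " clusters")

  scores <- compute_mei(records, config$schema, cuts = config$cuts)
  records <- cbind(records, scores)
  records <- cbind(records, derive_good_enc(records))
  records$sanc <- derive_sanc(records$sanc_visits,
                              threshold = config$sanc_threshold)
  log_msg(sprintf("good ENC %.2f%%, SANC %.2f%%",
                  100 * mean(records$good_enc), 100 * mean(records$sanc)))

  enc_dist <- enc_distribution(records)
  dim_sum <- dimension_summary(scores, weights = records$weight)
  assoc <- association_table(records,
                             c("mei_category", "sanc", config$covariates),
                             "good_enc")

  screening <- screen_covariates(records, config$covariates, "good_enc",
                                 threshold = config$screen_threshold)
  retained <- attr(screening, "retained")
  log_msg("covariates retained by p < ", config$screen_threshold, ": ",
          paste(retained, collapse = ", "))

  log_msg("fitting structural equations (", config$engine, ")")
  paths <- fit_mediation_sem(records, "mei_category", "sanc", "good_enc",
                             retained, "cluster_id",
                             engine = config$engine, nAGQ = config$nAGQ)
  icc <- c(mediator = paths$fit_mediator$icc,
           outcome = paths$fit_outcome$icc)
  lrt <- if (config$engine == "glmer") {
    list(mediator = cluster_effect_lrt(paths$fit_mediator),
         outcome = cluster_effect_lrt(paths$fit_outcome))
  } else {
    NULL
  }

  log_msg("bootstrapping mediation effects (B = ", config$B, ", ",
          config$unit, " unit)")
  med <- bootstrap_mediation(records, paths = paths, B = config$B,
                             seed = config$seed, unit = config$unit,
                             boot_engine = config$boot_engine,
                             boot_nAGQ = config$boot_nAGQ)

  structure(list(
    records = records,
    enc_distribution = enc_dist,
    dimension_summary = dim_sum,
    association = assoc,
    screening = screening,
    mediation = med,
    icc = icc,
    lrt = lrt,
    metadata = list(
      generator_seed = gen_seed,
      bootstrap_seed = config$seed,
      config_hash = hash_config(config),
      package_version = as.character(utils::packageVersion("encmediate")),
      n_women = nrow(records),
      n_clusters = length(unique(records$cluster_id)),
      covariates_retained = retained
    )
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  md <- x$metadata
  cat("ENC mediation pipeline result\n")
  cat("  ", md$n_women, "women in", md$n_clusters, "clusters; config",
      substr(md$config_hash, 1, 8), "\n")
  cat(sprintf("  good ENC %.2f%%, SANC %.2f%%\n",
              100 * mean(x$records$good_enc), 100 * mean(x$records$sanc)))
  cat(sprintf("  ICC: mediator %.3f, outcome %.3f\n",
              x$icc[["mediator"]], x$icc[["outcome"]]))
  print(x$mediation)
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Writes the record table, descriptive tables, model coefficient tables
#' and the mediation effect table as tab-separated text, plus a
#' machine-readable \code{summary.json} with the headline quantities and
#' run metadata. Every table opens with a \code{#} comment line stamping
#' the run seeds and the configuration hash; outputs carry no timestamps,
#' so two runs with equal configuration are byte-identical.
#'
#' @param result A \code{\link{run_pipeline}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- result$metadata
  stamp <- sprintf("# generator_seed=%s bootstrap_seed=%s config=%s",
                   md$generator_seed, md$bootstrap_seed, md$config_hash)
  tsv <- function(d, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(
      utils::write.table(d, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    path
  }
  files <- c(
    tsv(result$records, "records.tsv"),
    tsv(result$enc_distribution$by_count, "enc_by_count.tsv"),
    tsv(result$enc_distribution$by_component, "enc_by_component.tsv"),
    tsv(result$dimension_summary, "dimension_summary.tsv"),
    tsv(result$association, "association.tsv"),
    tsv(result$screening, "screening.tsv"),
    tsv(result$mediation$effects, "mediation_effects.tsv"),
    tsv(result$mediation$pme, "proportion_mediated.tsv"),
    tsv(result$mediation$paths$fit_mediator$coefficients,
        "coefficients_mediator.tsv"),
    tsv(result$mediation$paths$fit_outcome$coefficients,
        "coefficients_outcome.tsv")
  )
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    metadata = result$metadata,
    icc = as.list(result$icc),
    lrt = lapply(result$lrt, function(l) l[c("statistic", "p_value")]),
    good_enc_prevalence_pct = 100 * mean(result$records$good_enc),
    sanc_prevalence_pct = 100 * mean(result$records$sanc),
    mediation = result$mediation$effects,
    proportion_mediated = result$mediation$pme,
    bootstrap = list(B = result$mediation$B,
                     n_failed = result$mediation$n_failed,
                     unit = result$mediation$unit,
                     seed = result$mediation$seed)
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, summary_path))
}
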