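#' Construct an empowerment index schema
#'
#' A schema describes the dimensions and binary indicators from which the
#' multidimensional empowerment index (MEI) is computed. Each dimension
#' carries an equal share \code{1/m} of the total weight and splits that
#' share equally across its indicators, following the Alkire-Foster nested
#' equal-weighting convention.
#'
#' @param dimensions A named list. Each element is itself a list with
#'   components \code{indicators} (character vector of indicator column
#'   names), optional \code{cutoffs} (character vector describing when a
#'   woman counts as empowered on each indicator), and optional
#'   \code{weight} (dimension weight; defaults to \code{1/m}). Indicator
#'   weights default to \code{weight / p_j} where \code{p_j} is the number
#'   of indicators in the dimension; they can be overridden with an
#'   \code{indicator_weights} numeric vector (used by
#'   \code{\link{validate_mei_schema}} to flag inconsistent schemas).
#' @return An object of class \code{mei_schema}: a list with elements
#'   \code{dimensions}, \code{m} (number of dimensions) and
#'   \code{indicators} (all indicator names in schema order).
#' @seealso \code{\link{default_mei_schema}}, \code{\link{compute_mei}},
#'   \code{\link{validate_mei_schema}}
#' @export
mei_schema <- function(dimensions) {
  if (!is.list(dimensions) || length(dimensions) == 0L ||
      is.null(names(dimensions)) || any(!nzchar(names(dimensions)))) {
    stop("`dimensions` must be a non-empty named list", call. = FALSE)
  }
  m <- length(dimensions)
  dims <- lapply(names(dimensions), function(nm) {
    d <- dimensions[[nm]]
    ind <- d$indicators
    if (is.null(ind) || length(ind) == 0L || !is.character(ind)) {
      stop("dimension '", nm, "' must list at least one indicator name",
           call. = FALSE)
    }
    w_dim <- if (is.null(d$weight)) 1 / m else as.numeric(d$weight)
    w_ind <- if (is.null(d$indicator_weights)) {
      rep(w_dim / length(ind), length(ind))
    } else {
      as.numeric(d$indicator_weights)
    }
    if (length(w_ind) != length(ind)) {
      stop("dimension '", nm, "': indicator_weights length must match ",
           "the number of indicators", call. = FALSE)
    }
    names(w_ind) <- ind
    cutoffs <- d$cutoffs
    if (!is.null(cutoffs)) {
      cutoffs <- rep_len(as.character(cutoffs), length(ind))
      names(cutoffs) <- ind
    }
    list(name = nm, weight = w_dim, indicators = ind,
         indicator_weights = w_ind, cutoffs = cutoffs)
  })
  names(dims) <- names(dimensions)
  all_ind <- unlist(lapply(dims, `[[`, "indicators"), use.names = FALSE)
  if (anyDuplicated(all_ind)) {
    stop("indicator names must be unique across dimensions; duplicated: ",
         paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(dimensions = dims, m = m, indicators = all_ind),
            class = "mei_schema")
}

#' Default five-dimension empowerment schema
#'
#' The default schema has five equally weighted dimensions (weight 0.20
#' each): household decision-making autonomy (4 indicators, 0.050 each),
#' attitude towards intimate partner violence (5 indicators, 0.040 each),
#' health access barriers (4 indicators, 0.050 each), social independence
#' (8 indicators, 0.025 each) and asset ownership (1 indicator, 0.200).
#' Indicators are already dichotomised: 1 means the woman meets the
#' empowerment cut-off on that indicator.
#'
#' @return A \code{\link{mei_schema}} with 22 indicators and total weight 1.
#' @export
default_mei_schema <- function() {
  mei_schema(list(
    decision = list(
      indicators = c("decision_own_healthcare", "decision_large_purchases",
                     "decision_family_visits", "decision_husband_earnings"),
      cutoffs = c("decides alone or jointly with husband",
                  "decides alone or jointly with husband",
                  "decides alone or jointly with husband",
                  "decides alone or jointly with husband")),
    ipv_attitude = list(
      indicators = c("ipv_going_out", "ipv_neglect_children", "ipv_argue",
                     "ipv_refuse_sex", "ipv_burn_food"),
      cutoffs = rep("does not agree wife beating is justified", 5)),
    health_access = list(
      indicators = c("access_permission", "access_money",
                     "access_distance", "access_companion"),
      cutoffs = c("gets permission to seek medical care",
                  "has money for treatment",
                  "distance to facility not a problem",
                  "going alone not a problem")),
    social_independence = list(
      indicators = c("social_education", "social_newspaper",
                     "social_television", "social_bank_account",
                     "social_employment", "social_age_first_birth",
                     "social_age_at_marriage", "social_spousal_education"),
      cutoffs = c("completed secondary or higher education",
                  "reads newspaper/magazine at least weekly",
                  "watches television at least weekly",
                  "has a bank account",
                  "has earnings from own work",
                  "first birth at age 19 or later",
                  "married at age 18 or later",
                  "education equal to or higher than husband's")),
    assets = list(
      indicators = "assets_household",
      cutoffs = "owns two or more major household assets")
  ))
}

#' Validate an empowerment schema
#'
#' Checks the nested equal-weighting invariants: every dimension weight
#' equals \code{1/m} and the weights sum to 1; within each dimension the
#' indicator weights are equal and sum to the dimension weight.
#'
#' @param schema A \code{\link{mei_schema}}.
#' @param tol Numeric tolerance on the weight identities.
#' @return A list with elements \code{ok} (logical), \code{messages}
#'   (character vector of diagnostics, empty when valid) and
#'   \code{total_weight} (sum of all indicator weights).
#' @export
validate_mei_schema <- function(schema, tol = 1e-8) {
  stopifnot(inherits(schema, "mei_schema"))
  msgs <- character()
  m <- schema$m
  dim_w <- vapply(schema$dimensions, `[[`, numeric(1), "weight")
  if (any(abs(dim_w - 1 / m) > tol)) {
    bad <- names(dim_w)[abs(dim_w - 1 / m) > tol]
    msgs <- c(msgs, paste0("dimension weight != 1/m for: ",
                           paste(bad, collapse = ", ")))
  }
  if (abs(sum(dim_w) - 1) > tol) {
    msgs <- c(msgs, sprintf("dimension weights sum to %.6f, not 1",
                            sum(dim_w)))
  }
  total <- 0
  for (d in schema$dimensions) {
    w <- d$indicator_weights
    total <- total + sum(w)
    if (abs(sum(w) - d$weight) > tol) {
      msgs <- c(msgs, sprintf(
        "dimension '%s': indicator weights sum to %.6f, not %.6f",
        d$name, sum(w), d$weight))
    }
    if (diff(range(w)) > tol) {
      msgs <- c(msgs, sprintf(
        "dimension '%s': indicator weights are not equal", d$name))
    }
  }
  list(ok = length(msgs) == 0L, messages = msgs, total_weight = total)
}

#' @export
print.mei_schema <- function(x, ...) {
  cat("Empowerment index schema:", x$m, "dimensions,",
      length(x$indicators), "indicators\n")
  for (d in x$dimensions) {
    cat(sprintf("  %-20s weight %.3f  (%d x %.3f)\n", d$name, d$weight,
                length(d$indicators), d$indicator_weights[[1]]))
  }
  invisible(x)
}

#' Read or write a schema as structured text
#'
#' Schemas are stored as YAML so alternative dimension/indicator sets can
#' be supplied as data rather than code.
#'
#' @param path File path.
#' @return \code{read_mei_schema} returns a \code{\link{mei_schema}};
#'   \code{write_mei_schema} invisibly returns \code{path}.
#' @export
read_mei_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$dimensions)) {
    stop("schema file must contain a top-level 'dimensions' map", call. = FALSE)
  }
  mei_schema(raw$dimensions)
}

#' @rdname read_mei_schema
#' @param schema A \code{\link{mei_schema}} to serialise.
#' @export
write_mei_schema <- function(schema, path) {
  stopifnot(inherits(schema, "mei_schema"))
  dims <- lapply(schema$dimensions, function(d) {
    out <- list(indicators = as.list(d$indicators),
                weight = d$weight,
                indicator_weights = as.list(unname(d$indicator_weights)))
    if (!is.null(d$cutoffs)) out$cutoffs <- as.list(unname(d$cutoffs))
    out
  })
  yaml::write_yaml(list(dimensions = dims), path)
  invisible(path)
}
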