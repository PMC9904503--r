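#' Compute multidimensional empowerment index scores
#'
#' For each woman the score is the equally weighted mean of dimension
#' achievement fractions,
#' \deqn{Z_i = \frac{1}{m} \sum_{j=1}^{m} \frac{1}{p_j}
#'       \sum_{k=1}^{p_j} y_{ijk},}
#' where \eqn{m} is the number of dimensions, \eqn{p_j} the number of
#' indicators in dimension \eqn{j} and \eqn{y_{ijk}} the 0/1 indicator
#' values. \eqn{Z_i} lies in \eqn{[0, 1]}: 0 means empowered on no
#' indicator, 1 fully empowered on all.
#'
#' Missing indicator columns or NA indicator values are errors, never
#' silently imputed: zero-filling would bias scores downward.
#'
#' @param data A data.frame with one row per woman containing a 0/1 column
#'   for every indicator in \code{schema}.
#' @param schema A \code{\link{mei_schema}}; defaults to
#'   \code{\link{default_mei_schema}()}.
#' @param cuts Category cut points passed to \code{\link{categorize_mei}}.
#' @return A data.frame with one row per input row: column \code{Z}, one
#'   \code{dim_<name>} column per dimension (achievement fraction in
#'   \eqn{[0,1]}) and \code{mei_category} (factor low/average/high).
#' @examples
#' d <- as.data.frame(as.list(setNames(
#'   rep(1, 22), default_mei_schema()$indicators)))
#' compute_mei(d)$Z  # fully empowered -> 1
#' @export
compute_mei <- function(data, schema = default_mei_schema(),
                        cuts = c(low = 0.50, high = 0.75)) {
  stopifnot(is.data.frame(data), inherits(schema, "mei_schema"))
  missing_cols <- setdiff(schema$indicators, names(data))
  if (length(missing_cols)) {
    stop("missing indicator column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dim_scores <- matrix(NA_real_, nrow(data), schema$m,
                       dimnames = list(NULL, names(schema$dimensions)))
  for (d in schema$dimensions) {
    y <- as.matrix(data[d$indicators])
    if (anyNA(y)) {
      bad <- d$indicators[colSums(is.na(data[d$indicators])) > 0]
      stop("NA values in indicator(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!all(y %in% c(0, 1))) {
      bad <- d$indicators[apply(y, 2, function(v) !all(v %in% c(0, 1)))]
      stop("non-binary values in indicator(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    dim_scores[, d$name] <- rowSums(y) / length(d$indicators)
  }
  Z <- rowMeans(dim_scores)
  out <- data.frame(Z = Z)
  colnames(dim_scores) <- paste0("dim_", colnames(dim_scores))
  out <- cbind(out, as.data.frame(dim_scores))
  out$mei_category <- categorize_mei(Z, cuts = cuts)
  out
}

#' Categorise an empowerment score
#'
#' Three-level categorisation of the score: \code{low} below the lower cut,
#' \code{average} from the lower cut up to (excluding) the upper cut, and
#' \code{high} at or above the upper cut. Defaults are 0.50 and 0.75, with
#' both boundaries inclusive on the upper side (a score of exactly 0.50 is
#' average, exactly 0.75 is high).
#'
#' @param z Numeric vector of scores in \eqn{[0, 1]}.
#' @param cuts Numeric vector \code{c(low = , high = )} of cut points with
#'   \code{0 < low < high <= 1}.
#' @return Factor with levels \code{low}, \code{average}, \code{high}.
#' @export
categorize_mei <- function(z, cuts = c(low = 0.50, high = 0.75)) {
  if (anyNA(z)) stop("scores contain NA", call. = FALSE)
  if (any(z < 0 | z > 1)) {
    stop("scores must lie in [0, 1]; offending values: ",
         paste(utils::head(z[z < 0 | z > 1], 3), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(cuts) == 2L, cuts[1] > 0, cuts[1] < cuts[2], cuts[2] <= 1)
  factor(ifelse(z >= cuts[2], "high", ifelse(z >= cuts[1], "average", "low")),
         levels = c("low", "average", "high"))
}

#' Summarise dimension achievement across women
#'
#' Mean achievement per dimension, and the mean overall score, expressed
#' as percentages. Sampling weights are supported as an optional weight
#' vector.
#'
#' @param scores Output of \code{\link{compute_mei}} (needs \code{Z} and
#'   the \code{dim_*} columns).
#' @param weights Optional positive weights, one per row.
#' @return A data.frame with columns \code{dimension} (including the row
#'   \code{"overall"}) and \code{mean_pct}.
#' @export
dimension_summary <- function(scores, weights = NULL) {
  stopifnot(is.data.frame(scores), "Z" %in% names(scores))
  if (nrow(scores) == 0L) stop("no scores supplied", call. = FALSE)
  dim_cols <- grep("^dim_", names(scores), value = TRUE)
  if (is.null(weights)) weights <- rep(1, nrow(scores))
  stopifnot(length(weights) == nrow(scores), all(weights > 0))
  wmean <- function(v) sum(v * weights) / sum(weights)
  data.frame(
    dimension = c(sub("^dim_", "", dim_cols), "overall"),
    mean_pct = 100 * c(vapply(scores[dim_cols], wmean, numeric(1)),
                       wmean(scores$Z)),
    row.names = NULL
  )
}
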