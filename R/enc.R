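#' Names of the five essential newborn care components
#'
#' The WHO-recommended immediate newborn practices: cord cut with a clean
#' instrument, nothing (or only chlorhexidine) applied to the cord, baby
#' dried within 5 minutes, bathing delayed at least 72 hours, and
#' breastfeeding initiated within 1 hour of birth.
#'
#' @return Character vector of the five component column names (prefix
#'   \code{enc_}).
#' @export
enc_components <- function() {
  c("enc_cord_clean_cut", "enc_nothing_applied", "enc_dried_quickly",
    "enc_bath_delayed", "enc_early_breastfeeding")
}

#' Derive the binary good-ENC outcome
#'
#' A newborn received good essential newborn care when all five components
#' were practiced; missing any component makes the practice poor.
#'
#' @param components A data.frame containing the five 0/1 columns named by
#'   \code{\link{enc_components}} (extra columns are ignored).
#' @return A data.frame with columns \code{n_practiced} (0-5) and
#'   \code{good_enc} (1 iff all five practiced).
#' @export
derive_good_enc <- function(components) {
  stopifnot(is.data.frame(components))
  missing_cols <- setdiff(enc_components(), names(components))
  if (length(missing_cols)) {
    stop("missing ENC component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(components[enc_components()])
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("ENC components must be 0/1 with no missing values", call. = FALSE)
  }
  n <- rowSums(x)
  data.frame(n_practiced = as.integer(n), good_enc = as.integer(n == 5L))
}

#' Derive the skilled antenatal care mediator
#'
#' Skilled antenatal care (SANC) follows the WHO 2016 guideline: a woman is
#' classified as having received SANC when she had eight or more antenatal
#' check-ups from skilled health personnel. Counts are dichotomised at the
#' threshold; already-binary input (all values 0/1 with
#' \code{binary = TRUE}) is passed through after validation.
#'
#' @param visits Non-negative integer vector of visit counts, or 0/1
#'   values when \code{binary = TRUE}.
#' @param threshold Visit count at and above which SANC = 1 (default 8).
#' @param binary Set \code{TRUE} when \code{visits} is already the 0/1
#'   mediator.
#' @return Integer 0/1 vector.
#' @export
derive_sanc <- function(visits, threshold = 8L, binary = FALSE) {
  if (anyNA(visits)) stop("visit counts contain NA", call. = FALSE)
  if (any(visits < 0)) stop("visit counts must be non-negative", call. = FALSE)
  if (binary) {
    if (!all(visits %in% c(0, 1))) {
      stop("binary = TRUE but values are not all 0/1", call. = FALSE)
    }
    return(as.integer(visits))
  }
  as.integer(visits >= threshold)
}

#' Distribution of ENC practice components
#'
#' Tabulates how many of the five components were practiced (0-5, with
#' counts and percentages summing to the sample) and the prevalence of
#' each individual component.
#'
#' @param components A data.frame with the five component columns (see
#'   \code{\link{enc_components}}).
#' @return A list with data.frames \code{by_count} (columns
#'   \code{n_practiced}, \code{count}, \code{pct}) and \code{by_component}
#'   (columns \code{component}, \code{count}, \code{pct}).
#' @export
enc_distribution <- function(components) {
  if (!is.data.frame(components) || nrow(components) == 0L) {
    stop("no ENC profiles supplied", call. = FALSE)
  }
  prof <- derive_good_enc(components)
  n <- nrow(prof)
  counts <- vapply(0:5, function(k) sum(prof$n_practiced == k), integer(1))
  by_count <- data.frame(n_practiced = 0:5, count = counts,
                         pct = 100 * counts / n)
  comp_counts <- vapply(components[enc_components()], sum, numeric(1))
  by_component <- data.frame(component = enc_components(),
                             count = as.integer(comp_counts),
                             pct = 100 * comp_counts / n,
                             row.names = NULL)
  list(by_count = by_count, by_component = by_component)
}
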