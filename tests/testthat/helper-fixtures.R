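# shared fixtures, all built in code

# reduced 3-dimension / 6-indicator schema for exhaustive checks
reduced_schema <- function() {
  mei_schema(list(
    alpha = list(indicators = c("a1", "a2")),
    beta = list(indicators = c("b1", "b2", "b3")),
    gamma = list(indicators = "g1")
  ))
}

# a record data.frame with all default-schema indicators set to `fill`
indicator_frame <- function(n = 1L, fill = 1,
                            schema = default_mei_schema()) {
  as.data.frame(matrix(fill, nrow = n, ncol = length(schema$indicators),
                       dimnames = list(NULL, schema$indicators)))
}

# generated population with scored/derived analysis columns attached
scored_population <- function(config) {
  d <- generate_population(config)
  d <- cbind(d, compute_mei(d, config$schema))
  d <- cbind(d, derive_good_enc(d))
  d$sanc <- derive_sanc(d$sanc_visits)
  d
}

# small hand-built mediation dataset: `reps` identical copies of a
# balanced within-cluster block, one copy per cluster, so every cluster
# is byte-identical (used for degeneracy and invariance checks)
identical_cluster_data <- function(reps = 6L) {
  block <- expand.grid(
    mei_category = factor(c("low", "average", "high"),
                          levels = c("low", "average", "high")),
    sanc = 0:1, good_enc = 0:1, dup = 1:2)
  block$dup <- NULL
  # break the symmetry so coefficients are non-trivial
  block <- rbind(block, block[block$sanc == 1 & block$good_enc == 1, ])
  out <- do.call(rbind, lapply(seq_len(reps), function(i) {
    b <- block
    b$cluster_id <- sprintf("C%02d", i)
    b
  }))
  rownames(out) <- NULL
  out
}
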