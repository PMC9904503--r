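test_that("configuration validation rejects impossible settings", {
  expect_error(synthetic_config(n_clusters = 1), "n_clusters")
  expect_error(synthetic_config(indicator_prevalences = c(assets = 1.2)),
               "\\(0, 1\\)")
  expect_error(synthetic_config(sigma2_u = c(mediator = -1, outcome = 0)),
               "sigma2_u")
  expect_error(synthetic_config(latent_loading = 1), "latent_loading")
  expect_error(synthetic_config(true_paths = c(bogus = 1)), "true_paths")
})

test_that("generation is deterministic and extends without perturbation", {
  cfg <- synthetic_config(n_clusters = 20, women_per_cluster = 10,
                          seed = 9)
  d1 <- generate_population(cfg)
  d2 <- generate_population(cfg)
  expect_identical(d1, d2)

  # adding clusters leaves earlier clusters' rows unchanged
  cfg30 <- synthetic_config(n_clusters = 30, women_per_cluster = 10,
                            seed = 9)
  d3 <- generate_population(cfg30)
  first <- d3[d3$cluster_id %in% unique(d1$cluster_id), ]
  rownames(first) <- NULL
  expect_identical(first, d1)
})

test_that("generated rows satisfy the structural invariants", {
  cfg <- synthetic_config(n_clusters = 30, women_per_cluster = 15,
                          cluster_size = "poisson", seed = 4)
  d <- generate_population(cfg)
  ind <- as.matrix(d[cfg$schema$indicators])
  expect_true(all(ind %in% c(0, 1)))
  comp <- as.matrix(d[enc_components()])
  expect_true(all(comp %in% c(0, 1)))
  expect_true(all(nzchar(d$cluster_id)))
  expect_true(all(d$sanc_visits >= 0))
  expect_true(all(d$weight == 1))

  # good ENC = 1 exactly when all five components are 1, on every row;
  # the outcome that generated the components is recoverable
  prof <- derive_good_enc(d)
  expect_identical(prof$good_enc == 1L, rowSums(comp) == 5)
})

test_that("null model produces one-half prevalences", {
  cfg <- synthetic_config(n_clusters = 40, women_per_cluster = 50,
                          true_paths = NULL,
                          covariate_effects = NULL,
                          intercepts = c(mediator = 0, outcome = 0),
                          sigma2_u = c(mediator = 0, outcome = 0),
                          seed = 12)
  d <- generate_population(cfg)
  expect_lt(abs(mean(derive_sanc(d$sanc_visits)) - 0.5), 0.03)
  expect_lt(abs(mean(derive_good_enc(d)$good_enc) - 0.5), 0.03)
})

test_that("intercept-only mediator prevalence matches its logistic inverse", {
  # intercept -2.89, no slopes, no cluster variance, 50,000 women
  cfg <- synthetic_config(n_clusters = 100, women_per_cluster = 500,
                          true_paths = NULL,
                          intercepts = c(mediator = -2.89, outcome = -2.89),
                          sigma2_u = c(mediator = 0, outcome = 0),
                          seed = 8)
  d <- generate_population(cfg)
  expect_equal(nrow(d), 50000)
  p_hat <- mean(derive_sanc(d$sanc_visits))
  expect_lt(abs(p_hat - plogis(-2.89)), 0.004)  # ~4 sd Monte-Carlo slack
})

test_that("true_params echoes the generating values", {
  cfg <- synthetic_config(seed = 1)
  tp <- true_params(cfg)
  expect_equal(tp$paths[["a_high"]], 1.52)
  expect_equal(tp$paths[["b"]], 0.72)
  expect_equal(tp$icc[["mediator"]], 0.26, tolerance = 1e-12)
  expect_equal(tp$icc[["outcome"]], 0.13, tolerance = 1e-12)

  zero <- synthetic_config(true_paths = NULL, seed = 1)
  expect_true(all(true_params(zero)$paths == 0))
})

test_that("within-cluster mediator correlation increases with sigma2_u", {
  between_var <- function(s2) {
    cfg <- synthetic_config(n_clusters = 150, women_per_cluster = 40,
                            true_paths = NULL,
                            intercepts = c(mediator = -1, outcome = -1),
                            sigma2_u = c(mediator = s2, outcome = 0),
                            seed = 77)
    d <- generate_population(cfg)
    d$sanc <- derive_sanc(d$sanc_visits)
    stats::var(tapply(d$sanc, d$cluster_id, mean))
  }
  v <- vapply(c(0, 0.5, 1.5, 3), between_var, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("zero-path populations show null MEI/outcome association at nominal rate", {
  rejections <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(n_clusters = 80, women_per_cluster = 12,
                            true_paths = NULL,
                            intercepts = c(mediator = -2, outcome = -1),
                            sigma2_u = c(mediator = 0, outcome = 0),
                            seed = 4000 + r)
    d <- scored_population(cfg)
    tab <- table(d$mei_category, d$good_enc)
    p <- chisq_association(tab)$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  # binomial(60, 0.05): ~3 expected; 9+ would be far in the tail
  expect_lte(rejections / n_rep, 0.15)
})

test_that("latent loading induces positive indicator dependence, same marginals", {
  base <- synthetic_config(n_clusters = 50, women_per_cluster = 60,
                           seed = 21)
  dep <- synthetic_config(n_clusters = 50, women_per_cluster = 60,
                          latent_loading = 0.6, seed = 21)
  d0 <- generate_population(base)
  d1 <- generate_population(dep)
  i1 <- "decision_own_healthcare"; i2 <- "social_bank_account"
  expect_lt(abs(mean(d1[[i1]]) - mean(d0[[i1]])), 0.03)
  r0 <- cor(d0[[i1]], d0[[i2]])
  r1 <- cor(d1[[i1]], d1[[i2]])
  expect_lt(abs(r0), 0.05)
  expect_gt(r1, 0.1)
  # spread of the score widens under dependence
  expect_gt(sd(compute_mei(d1)$Z), sd(compute_mei(d0)$Z))
})

test_that("config round-trips through its YAML representation", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_clusters = 12, women_per_cluster = 5, seed = 3,
    true_paths = list(a_high = 1.0, b = 0.5),
    sigma2_u = list(mediator = 0.4, outcome = 0.2),
    intercepts = list(mediator = -2, outcome = -2)
  ), tf)
  cfg <- read_synthetic_config(tf)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$true_paths[["a_high"]], 1.0)
  expect_equal(cfg$true_paths[["a_avg"]], 0)
  expect_identical(generate_population(cfg), generate_population(cfg))
})
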