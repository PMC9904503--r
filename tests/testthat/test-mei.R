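test_that("score formula matches hand-evaluated cases", {
  schema <- default_mei_schema()
  d <- indicator_frame(fill = 1)
  expect_equal(compute_mei(d, schema)$Z, 1.0)
  expect_equal(compute_mei(indicator_frame(fill = 0), schema)$Z, 0.0)

  # all four decision indicators on, everything else off: (1/5) * (4/4)
  d0 <- indicator_frame(fill = 0)
  d0[schema$dimensions$decision$indicators] <- 1
  sc <- compute_mei(d0, schema)
  expect_equal(sc$Z, 0.2)
  expect_equal(sc$dim_decision, 1.0)
  expect_equal(sc$dim_assets, 0.0)
})

test_that("Z equals the equally weighted mean of dimension sub-scores", {
  schema <- default_mei_schema()
  set.seed(11)
  d <- indicator_frame(n = 200, fill = 0)
  d[] <- matrix(rbinom(200 * ncol(d), 1, 0.5), 200)
  sc <- compute_mei(d, schema)
  dim_cols <- grep("^dim_", names(sc), value = TRUE)
  expect_equal(sc$Z, rowMeans(sc[dim_cols]), tolerance = 1e-12)
  expect_true(all(sc$Z >= 0 & sc$Z <= 1))
})

test_that("formula agrees with the weighted-sum oracle on all 64 assignments", {
  schema <- reduced_schema()
  w <- setNames(
    unlist(lapply(schema$dimensions, `[[`, "indicator_weights"),
           use.names = FALSE),
    unlist(lapply(schema$dimensions, `[[`, "indicators"),
           use.names = FALSE))
  grid <- expand.grid(rep(list(0:1), 6))
  names(grid) <- schema$indicators
  z <- compute_mei(grid, schema)$Z
  oracle <- as.matrix(grid) %*% unname(w[schema$indicators])
  expect_equal(z, drop(oracle), tolerance = 1e-12)
})

test_that("flipping any indicator 0 to 1 raises Z by exactly its weight", {
  schema <- default_mei_schema()
  w <- setNames(
    unlist(lapply(schema$dimensions, `[[`, "indicator_weights"),
           use.names = FALSE),
    unlist(lapply(schema$dimensions, `[[`, "indicators"),
           use.names = FALSE))
  set.seed(5)
  for (r in 1:10) {
    d <- indicator_frame(fill = 0)
    d[] <- rbinom(ncol(d), 1, 0.5)
    z0 <- compute_mei(d, schema)$Z
    off <- schema$indicators[unlist(d[1, schema$indicators]) == 0]
    for (ind in off) {
      d1 <- d
      d1[[ind]] <- 1
      expect_equal(compute_mei(d1, schema)$Z - z0, unname(w[ind]),
                   tolerance = 1e-12)
    }
  }
})

test_that("missing or invalid indicators are errors, not imputed", {
  schema <- default_mei_schema()
  d <- indicator_frame(fill = 1)
  d$assets_household <- NULL
  expect_error(compute_mei(d, schema), "assets_household")
  d2 <- indicator_frame(fill = 1)
  d2$ipv_argue <- NA
  expect_error(compute_mei(d2, schema), "ipv_argue")
  d3 <- indicator_frame(fill = 1)
  d3$access_money <- 2
  expect_error(compute_mei(d3, schema), "access_money")
})

test_that("categorisation applies the documented boundary rules", {
  expect_equal(as.character(categorize_mei(c(0, 0.49, 0.5, 0.74, 0.75, 1))),
               c("low", "low", "average", "average", "high", "high"))
  expect_error(categorize_mei(1.2), "\\[0, 1\\]")
  expect_error(categorize_mei(-0.1), "\\[0, 1\\]")
  # cut points are configurable
  expect_equal(as.character(categorize_mei(0.45, cuts = c(0.4, 0.6))),
               "average")
})

test_that("schema validation enforces the nested equal-weight invariants", {
  v <- validate_mei_schema(default_mei_schema())
  expect_true(v$ok)
  expect_equal(v$total_weight, 1, tolerance = 1e-12)

  bad <- mei_schema(list(
    alpha = list(indicators = c("a1", "a2"),
                 indicator_weights = c(0.06, 0.44)),
    beta = list(indicators = "b1")
  ))
  vb <- validate_mei_schema(bad)
  expect_false(vb$ok)
  expect_true(any(grepl("not equal", vb$messages)))

  # single-indicator dimension carrying the whole dimension weight passes
  single <- mei_schema(list(
    alpha = list(indicators = "a1"),
    beta = list(indicators = "b1")
  ))
  expect_true(validate_mei_schema(single)$ok)
})

test_that("schema round-trips through its YAML representation", {
  schema <- default_mei_schema()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_mei_schema(schema, tf)
  back <- read_mei_schema(tf)
  expect_equal(back$indicators, schema$indicators)
  expect_equal(
    unlist(lapply(back$dimensions, `[[`, "indicator_weights")),
    unlist(lapply(schema$dimensions, `[[`, "indicator_weights")))
  set.seed(2)
  d <- indicator_frame(n = 50)
  d[] <- matrix(rbinom(50 * ncol(d), 1, 0.6), 50)
  expect_equal(compute_mei(d, back)$Z, compute_mei(d, schema)$Z)
})

test_that("dimension summary averages correctly, with and without weights", {
  sc <- data.frame(Z = c(0.4, 0.8), dim_alpha = c(0.2, 1.0))
  s <- dimension_summary(sc)
  expect_equal(s$mean_pct[s$dimension == "overall"], 60.0)
  expect_equal(s$mean_pct[s$dimension == "alpha"], 60.0)
  sw <- dimension_summary(sc, weights = c(3, 1))
  expect_equal(sw$mean_pct[sw$dimension == "overall"], 100 * 0.5)
  expect_error(dimension_summary(sc[0, ]), "no scores")

  # fully empowered population: every dimension at 100%
  d <- indicator_frame(n = 5, fill = 1)
  s2 <- dimension_summary(compute_mei(d))
  expect_true(all(s2$mean_pct == 100))
})

test_that("dimension means of a synthetic population match generator prevalences", {
  cfg <- synthetic_config(n_clusters = 40, women_per_cluster = 100,
                          seed = 31)
  d <- generate_population(cfg)
  s <- dimension_summary(compute_mei(d, cfg$schema))
  # expected sub-score mean = indicator prevalence (equal within dimension)
  expected <- c(decision = 68.6, ipv_attitude = 92.7, health_access = 60.0,
                social_independence = 42.3, assets = 40.0)
  for (nm in names(expected)) {
    got <- s$mean_pct[s$dimension == nm]
    expect_lt(abs(got - expected[[nm]]), 1.5)  # ~4 sd Monte-Carlo slack
  }
})
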