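test_that("product-of-coefficients arithmetic matches hand calculation", {
  expect_equal(indirect_effect(1.52, 0.72), 1.0944)
  expect_equal(indirect_effect(0, 0.72), 0)
  expect_equal(indirect_effect(0.73, 0.72), 0.5256)

  expect_equal(total_effect(1.09, 0.53, TRUE), 1.62)
  expect_equal(total_effect(0.53, -0.01, FALSE), -0.01)
  expect_equal(total_effect(0, 0.4, TRUE), 0.4)

  expect_equal(proportion_mediated(1.09, 1.62), 100 * 1.09 / 1.62)
  expect_equal(proportion_mediated(0.7, 0.7), 100)
  expect_equal(proportion_mediated(0, 0.5), 0)
  expect_true(is.na(proportion_mediated(0.5, 0)))
  expect_true(is.na(proportion_mediated(0.5, 0.8, me_significant = FALSE)))
  # invariant to common positive rescaling
  expect_equal(proportion_mediated(3 * 1.09, 3 * 1.62),
               proportion_mediated(1.09, 1.62))
})

test_that("covariate screening applies the p < 0.30 rule", {
  set.seed(8)
  n <- 4000
  d <- data.frame(y = rbinom(n, 1, 0.3))
  d$same <- d$y                      # p ~ 0: retained
  d$noise <- rbinom(n, 1, 0.5)       # independent at huge n: dropped
  d$weak <- ifelse(rbinom(n, 1, 0.985), d$noise, d$y)
  res <- screen_covariates(d, c("same", "noise", "weak"), "y")
  expect_true(res$retained[res$covariate == "same"])
  expect_false(res$retained[res$covariate == "noise"])
  expect_equal(attr(res, "retained"),
               res$covariate[res$retained])
  # threshold is honoured
  res_all <- screen_covariates(d, c("same", "noise"), "y", threshold = 1.01)
  expect_true(all(res_all$retained))
  expect_error(screen_covariates(d, "absent", "y"), "absent")
})

test_that("path extraction maps equation coefficients to a, b, c", {
  cfg <- synthetic_config(n_clusters = 60, women_per_cluster = 30,
                          sigma2_u = c(mediator = 0, outcome = 0),
                          seed = 19)
  d <- scored_population(cfg)
  p <- fit_mediation_sem(d, engine = "glm")
  cm <- p$fit_mediator$coefficients
  cy <- p$fit_outcome$coefficients
  expect_equal(unname(p$a["high"]),
               cm$estimate[cm$term == "mei_categoryhigh"])
  expect_equal(unname(p$c["average"]),
               cy$estimate[cy$term == "mei_categoryaverage"])
  expect_equal(p$b, cy$estimate[cy$term == "sanc"])
  expect_equal(p$me, p$a * p$b)
  expect_error(fit_mediation_sem(d, exposure = "Z"), "factor")
})

test_that("estimates are invariant to joint row/cluster relabelling", {
  cfg <- synthetic_config(n_clusters = 40, women_per_cluster = 20,
                          seed = 33)
  d <- scored_population(cfg)
  p1 <- fit_mediation_sem(d, engine = "glm")
  set.seed(1)
  perm <- sample.int(nrow(d))
  d2 <- d[perm, ]
  d2$cluster_id <- paste0("relabel_", d2$cluster_id)
  p2 <- fit_mediation_sem(d2, engine = "glm")
  expect_equal(p1$a, p2$a, tolerance = 1e-8)
  expect_equal(p1$b, p2$b, tolerance = 1e-8)
  expect_equal(p1$c, p2$c, tolerance = 1e-8)
})

test_that("bootstrap is reproducible and reports OR = exp(effect)", {
  cfg <- synthetic_config(n_clusters = 50, women_per_cluster = 25,
                          seed = 41)
  d <- scored_population(cfg)
  m1 <- bootstrap_mediation(d, engine = "glm", B = 120, seed = 5)
  m2 <- bootstrap_mediation(d, engine = "glm", B = 120, seed = 5)
  expect_identical(m1$effects, m2$effects)
  expect_identical(m1$pme, m2$pme)
  m3 <- bootstrap_mediation(d, engine = "glm", B = 120, seed = 6)
  expect_false(identical(m1$effects$boot_se, m3$effects$boot_se))

  # scale consistency on every row
  expect_equal(m1$effects$or, exp(m1$effects$estimate), tolerance = 1e-12)
  expect_equal(m1$effects$or_ci_low, exp(m1$effects$ci_low),
               tolerance = 1e-12)
  expect_equal(m1$b$or, exp(m1$b$estimate), tolerance = 1e-12)
})

test_that("total effect composition follows the significance rule", {
  cfg <- synthetic_config(n_clusters = 60, women_per_cluster = 25,
                          seed = 43)
  d <- scored_population(cfg)
  m <- bootstrap_mediation(d, engine = "glm", B = 200, seed = 2)
  eff <- m$effects
  for (lvl in unique(eff$level)) {
    ind <- eff[eff$level == lvl & eff$effect == "indirect", ]
    dir <- eff[eff$level == lvl & eff$effect == "direct", ]
    tot <- eff[eff$level == lvl & eff$effect == "total", ]
    if (ind$significant) {
      expect_equal(tot$estimate, ind$estimate + dir$estimate,
                   tolerance = 1e-12)
      pme_row <- m$pme[m$pme$level == lvl, ]
      if (tot$estimate != 0) {
        expect_equal(pme_row$pme,
                     100 * ind$estimate / tot$estimate,
                     tolerance = 1e-12)
      }
    } else {
      expect_equal(tot$estimate, dir$estimate, tolerance = 1e-12)
      expect_true(is.na(m$pme$pme[m$pme$level == lvl]))
    }
  }
})

test_that("identical clusters collapse the bootstrap to the point estimate", {
  d <- identical_cluster_data(reps = 8L)
  m <- bootstrap_mediation(d, covariates = character(), B = 60, seed = 9,
                           engine = "glm")
  expect_equal(m$effects$boot_se, rep(0, nrow(m$effects)),
               tolerance = 1e-10)
  expect_equal(m$effects$ci_low, m$effects$estimate, tolerance = 1e-10)
  expect_equal(m$effects$ci_high, m$effects$estimate, tolerance = 1e-10)
})

test_that("woman and cluster resampling agree when clustering is absent", {
  cfg <- synthetic_config(n_clusters = 80, women_per_cluster = 25,
                          sigma2_u = c(mediator = 0, outcome = 0),
                          seed = 47)
  d <- scored_population(cfg)
  mc <- bootstrap_mediation(d, engine = "glm", B = 300, seed = 11,
                            unit = "cluster")
  mw <- bootstrap_mediation(d, engine = "glm", B = 300, seed = 11,
                            unit = "woman")
  se_c <- mc$effects$boot_se[mc$effects$effect == "indirect"]
  se_w <- mw$effects$boot_se[mw$effects$effect == "indirect"]
  expect_true(all(se_c / se_w > 0.7 & se_c / se_w < 1.4))
})

test_that("glmer resample engine runs and agrees broadly with the fast path", {
  cfg <- synthetic_config(n_clusters = 40, women_per_cluster = 25,
                          sigma2_u = c(mediator = 0, outcome = 0),
                          seed = 51)
  d <- scored_population(cfg)
  p <- fit_mediation_sem(d, engine = "glm")
  mg <- bootstrap_mediation(d, paths = p, B = 30, seed = 13,
                            boot_engine = "glmer", boot_nAGQ = 1)
  mf <- bootstrap_mediation(d, paths = p, B = 200, seed = 13,
                            boot_engine = "glm")
  expect_lt(mg$n_failed, 30)
  ratio <- mg$b$boot_se / mf$b$boot_se
  expect_true(ratio > 0.4 && ratio < 2.5)
})

test_that("degenerate bootstrap inputs raise errors", {
  d <- identical_cluster_data(reps = 4L)
  expect_error(bootstrap_mediation(d, covariates = character(), B = 1,
                                   engine = "glm"), "B must be")
})
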