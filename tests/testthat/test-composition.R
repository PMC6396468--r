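test_that("sigmoid and logit are mutually inverse on the open interval", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(logit(0.5), 0)
  expect_equal(logit(sigmoid(1.7)), 1.7, tolerance = 1e-12)
  for (p in c(1e-4, 0.3, 0.97)) {
    expect_equal(sigmoid(logit(p)), p, tolerance = 1e-12)
  }
  expect_error(logit(0), "strictly inside")
  expect_error(logit(1), "strictly inside")
  expect_equal(logit_clipped(1), logit(1 - 1e-5))
  expect_equal(logit_clipped(0), logit(1e-5))
})

test_that("delta scores vanish for a no-op variant and indicators follow windows", {
  fx <- fixture_genome()
  mods <- tiny_modules()
  ex <- fx$annotation$exons
  e <- ex[ex$strand == "+", ][1, ]
  mid <- floor((e$start + e$end) / 2)
  p <- apply_variant(fx$genome, e, make_snv(fx$genome, e$contig, mid))
  noop <- p
  noop$alt_region <- noop$ref_region
  sc0 <- module_delta_scores(noop, mods)
  expect_equal(as.numeric(sc0[1, 1:5]), rep(0, 5))
  # mid-exon SNV, > 5 nt from both splice sites: all indicators 0
  sc <- module_delta_scores(p, mods)
  expect_equal(as.numeric(sc[, c("ind_exon_ss", "ind_intron5p_donor",
                                 "ind_intron3p_acceptor")]), c(0, 0, 0))
  # intronic SNV 4 nt past the donor: 5' intron / donor overlap
  p2 <- apply_variant(fx$genome, e, make_snv(fx$genome, e$contig, e$end + 3L))
  sc2 <- module_delta_scores(p2, mods)
  expect_equal(sc2$ind_intron5p_donor, 1L)
  expect_equal(sc2$ind_exon_ss, 0L)
  # last exonic base: exon / splice-site overlap
  p3 <- apply_variant(fx$genome, e, make_snv(fx$genome, e$contig, e$end - 1L))
  expect_equal(module_delta_scores(p3, mods)$ind_exon_ss, 1L)
  # intronic SNV 30 nt before the acceptor: 3' intron / acceptor overlap
  p4 <- apply_variant(fx$genome, e, make_snv(fx$genome, e$contig, e$start - 30L))
  expect_equal(module_delta_scores(p4, mods)$ind_intron3p_acceptor, 1L)
  # untrained modules are refused
  untrained <- build_module_set(list(donor = list(hidden = c(4, 4)),
                                     acceptor = list(filters = 2),
                                     exon = list(filters = 2),
                                     intron = list(filters = 2)), seed = 1)
  expect_error(module_delta_scores(p, untrained), "trained")
})

test_that("the linear composition model exposes nine named coefficients", {
  rows <- make_effect_rows(60, seed = 21)
  m <- fit_effect_model(rows)
  expect_s3_class(m, "ss_effect_model")
  expect_length(m$coef, 9L)
  expect_named(m$coef, c("intercept", "dS_intron3p", "dS_acceptor", "dS_exon",
                         "dS_donor", "dS_intron5p", "ind_exon_ss.dS_exon",
                         "ind_intron5p_donor.dS_intron5p",
                         "ind_intron3p_acceptor.dS_intron3p"))
  expect_error(fit_effect_model(rows[1:5, ]), "at least 9 rows")
  degenerate <- rows
  degenerate$dS_donor <- 0
  expect_warning(fit_effect_model(degenerate), "zero-variance")
})

test_that("noise-free responses are recovered exactly; Huber resists outliers", {
  beta <- default_true_beta()
  rows <- make_effect_rows(400, beta, noise_sd = 0, seed = 22)
  m <- fit_effect_model(rows)
  expect_lt(max(abs(m$coef - beta)), 1e-6)
  # gaussian noise + 5% gross outliers
  set.seed(23)
  rows2 <- make_effect_rows(2000, beta, noise_sd = 0.1, seed = 23)
  out <- sample.int(2000, 100)
  rows2$response[out] <- rows2$response[out] + rnorm(100, 0, 8)
  mh <- fit_effect_model(rows2, huber_delta = 1.0)
  expect_lt(max(abs(mh$coef - beta)), 0.05)
  X <- spliceshift:::effect_design_matrix(rows2)
  ols <- coef(stats::lm.fit(X, rows2$response))
  expect_gt(max(abs(ols - beta)), max(abs(mh$coef - beta)))
  # independent robust-regression cross-check: MASS::rlm with Huber psi
  # lands near the same coefficients
  rl <- MASS::rlm(X, rows2$response, psi = MASS::psi.huber, maxit = 50)
  expect_lt(max(abs(coef(rl) - mh$coef)), 0.05)
})

test_that("delta-logit transforms to delta-PSI per the logistic identities", {
  # log(4) shifts psi_ref 0.5 to 0.8
  r <- predict_delta_psi(1.3862944, 0.5)
  expect_equal(r$psi_alt, 0.8, tolerance = 1e-6)
  expect_equal(r$delta_psi, 0.3, tolerance = 1e-6)
  expect_equal(predict_delta_psi(0, 0.3)$delta_psi, 0)
  # round trip: dlogit built from two clipped PSI values recovers their
  # difference exactly
  set.seed(31)
  p_ref <- runif(50, 1e-4, 1 - 1e-4)
  p_alt <- runif(50, 1e-4, 1 - 1e-4)
  rt <- predict_delta_psi(logit(p_alt) - logit(p_ref), p_ref)
  expect_equal(rt$delta_psi, p_alt - p_ref, tolerance = 1e-12)
  # boundary references stay finite through clipping
  rb <- predict_delta_psi(c(2, -2), c(1, 0))
  expect_true(all(is.finite(unlist(rb))))
  expect_error(predict_delta_psi(1), "psi_ref")
  # monotonicity in dlogit at fixed psi_ref
  d <- seq(-3, 3, length.out = 25)
  expect_true(all(diff(predict_delta_psi(d, rep(0.4, 25))$delta_psi) > 0))
})

test_that("splice-site competition halves under heterozygosity", {
  # dlogit difference log(0.6/0.4) - log(0.2/0.8) moves psi5_ref 0.2 to 0.6
  d1 <- logit(0.6)
  d2 <- logit(0.2)
  expect_equal(predict_competition(d1, d2, 0.2, "hom_alt"), 0.4, tolerance = 1e-6)
  expect_equal(predict_competition(d1, d2, 0.2, "het"), 0.2, tolerance = 1e-6)
  expect_equal(predict_competition(1.3, 1.3, 0.7, "hom_alt"), 0)
  expect_equal(predict_competition(1.3, 1.3, 0.7, "het"), 0)
  set.seed(32)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1); p <- runif(1)
    expect_equal(predict_competition(a, b, p, "het"),
                 predict_competition(a, b, p, "hom_alt") / 2)
  }
  # increasing the first exon's dlogit increases delta-PSI5, the second
  # decreases it
  expect_true(all(diff(predict_competition(seq(-2, 2, 0.5), 0, 0.4)) > 0))
  expect_true(all(diff(predict_competition(0, seq(-2, 2, 0.5), 0.4)) < 0))
})

test_that("allelic log-ratio follows its definition and is antisymmetric", {
  expect_equal(allelic_log_ratio(10, 10, 10, 10), 0)
  expect_equal(allelic_log_ratio(20, 10, 10, 10), 1.0)
  expect_error(allelic_log_ratio(10, 10, 10, 0), "positive")
  expect_equal(allelic_log_ratio(10, 10, 10, 0, pseudocount = 1),
               log2((11 / 11) / (11 / 1)))
  set.seed(33)
  for (i in 1:10) {
    cnt <- sample(1:50, 4)
    expect_equal(allelic_log_ratio(cnt[1], cnt[2], cnt[3], cnt[4]),
                 -allelic_log_ratio(cnt[3], cnt[4], cnt[1], cnt[2]))
  }
})

test_that("pathogenicity classification behaves at the separable and null extremes", {
  set.seed(34)
  n <- 400
  rows <- make_effect_rows(n, seed = 34)
  w <- c(1.5, -1, 2, 1, -0.5)
  lin <- as.matrix(rows[, 1:5]) %*% w
  rows$label <- as.integer(lin > 0)
  # complete separation makes glm emit convergence warnings; that is the
  # intended regime here
  cv <- suppressWarnings(cv_pathogenicity(rows, k = 5, seed = 1))
  expect_gte(cv$auroc, 0.99)
  # labels independent of features: cross-validated AUROC near 1/2
  null_rows <- make_effect_rows(2000, seed = 35)
  set.seed(36)
  null_rows$label <- rbinom(2000, 1, 0.5)
  cvn <- cv_pathogenicity(null_rows, k = 10, seed = 2)
  expect_gte(cvn$auroc, 0.45)
  expect_lte(cvn$auroc, 0.55)
  # all-zero features predict the intercept probability for every row
  zero <- null_rows
  zero[, 1:8] <- 0
  mz <- suppressWarnings(fit_pathogenicity(zero))
  pz <- predict_pathogenicity(mz, zero)
  expect_equal(pz, rep(sigmoid(unname(mz$coef[1])), nrow(zero)), tolerance = 1e-9)
  expect_error(fit_pathogenicity(transform(rows, label = 1)), "both")
})

test_that("splice-disruption calls rank by |delta-PSI| and respect thresholds", {
  dp <- c(0.6, -0.7, 0.05, -0.02)
  r <- classify_sdv(dp, threshold = 0.5)
  expect_equal(r$rank, c(2, 1, 3, 4))
  expect_equal(r$call, c(TRUE, TRUE, FALSE, FALSE))
  # all-zero predictions: every rank tied, auPR equals prevalence
  z <- classify_sdv(rep(0, 6))
  expect_true(all(z$rank == mean(z$rank)))
  obs <- c(1, 0, 0, 1, 0, 0)
  expect_equal(metric("auPR", obs, z$score), mean(obs))
  # separable magnitudes give perfect retrieval
  true_sdv <- c(1, 1, 0, 0)
  expect_equal(metric("auPR", true_sdv, classify_sdv(c(0.8, -0.6, 0.05, 0.01))$score), 1)
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(classify_sdv(dp[perm], threshold = 0.5)$call, r$call[perm])
})

test_that("per-variant aggregation keeps the largest-magnitude signed effect", {
  agg <- aggregate_by_variant(c("a", "a", "b"), c(0.2, -0.5, 0.1))
  expect_equal(agg$effect[agg$variant_id == "a"], -0.5)
  expect_equal(agg$effect[agg$variant_id == "b"], 0.1)
})
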