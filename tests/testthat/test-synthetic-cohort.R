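test_that("simulated sources are compact, extent-filter-proof and near-orthogonal", {
  src <- simulate_sources(c(20, 20, 10), 6, seed = 1)
  expect_equal(nrow(src$maps), 6)
  z <- t(apply(src$maps, 1, zscore_map))
  counts <- apply(z, 1, function(v) sum(abs(v) >= 1))
  expect_true(all(counts >= 50))
  norms <- sqrt(rowSums(src$maps^2))
  expect_equal(norms, rep(1, 6), tolerance = 1e-10)
  cs <- abs(tcrossprod(src$maps))
  diag(cs) <- 0
  expect_lt(max(cs), 0.2)

  # bit-identical reproduction from the seed
  expect_identical(src, simulate_sources(c(20, 20, 10), 6, seed = 1))
  expect_false(identical(src$maps,
                         simulate_sources(c(20, 20, 10), 6, seed = 2)$maps))

  expect_error(simulate_sources(c(6, 6, 4), 10, seed = 1), "too small")
})

test_that("noise-free subject BOLD is an exact low-rank mixture", {
  co <- tiny_cohort(seed = 2, noise_sd = 0, n_pd = 2, n_ctr = 2,
                    grid = c(16, 16, 8), n_components = 4, n_timepoints = 60)
  b <- co$bold[[1]]
  expect_equal(qr(b$data)$rank, 4)
  expect_true(all(is.finite(rowMeans(b$data))))
  expect_equal(b$tr_seconds, 2)
})

test_that("component time courses are dominated by the low-frequency band", {
  withr::with_seed(4, {
    for (i in 1:10) {
      tc <- icanets:::simulate_timecourse(150, 2, band = c(0.01, 0.08))
      expect_gte(low_freq_ratio(tc, 2, band_edge_hz = 0.10), 0.90)
    }
  })
})

test_that("generator rejects infeasible time-sampling requests", {
  co <- tiny_cohort(seed = 2, n_pd = 2, n_ctr = 2, grid = c(14, 14, 8),
                    n_components = 3, n_timepoints = 40)
  expect_error(simulate_subject_bold(co$truth, 1, n_timepoints = 10),
               ">= 30")
  expect_error(icanets:::simulate_timecourse(100, 2, band = c(0.01, 0.30)),
               "Nyquist")
})

test_that("default cohort matches the study design: 40 PD, 15 controls", {
  co <- simulate_cohort(cohort_config(), seed = 1, generate_bold = FALSE)
  expect_equal(sum(co$metadata$group == "PD"), 40)
  expect_equal(sum(co$metadata$group == "Ctr"), 15)
  # detailed cognitive battery administered to patients only
  ctr <- co$metadata$group == "Ctr"
  expect_true(all(is.na(co$metadata$moca_attention[ctr])))
  expect_true(all(!is.na(co$metadata$moca_attention[!ctr])))
  expect_true(all(co$metadata$mmse[ctr] >= 24))
  # scores lie in their declared integer ranges
  dom <- moca_domains()
  for (j in seq_len(nrow(dom))) {
    y <- co$metadata[[paste0("moca_", dom$domain[j])]][!ctr]
    expect_true(all(y == round(y)))
    expect_true(all(y >= 0 & y <= dom$max_score[j]))
  }
  expect_true(all(co$metadata$led[!ctr] >= 0))
  # nobody exceeds the motion threshold by construction
  expect_equal(nrow(screen_motion(co$metadata)$excluded), 0)
})

test_that("zero residual sd and no rounding make the planted model exact", {
  pm <- default_planted_models()
  pm$attention$residual_sd <- 0
  pm$attention$r2 <- NULL
  cfg <- cohort_config(n_pd = 10, n_ctr = 3, planted_models = pm,
                       round_scores = FALSE)
  co <- simulate_cohort(cfg, seed = 6, generate_bold = FALSE)
  pd <- co$metadata$group == "PD"
  y <- co$metadata$moca_attention[pd]
  x <- co$truth$subject_loadings[pd, c(1, 3, 5)]
  fit <- lm(y ~ x)
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1,
               tolerance = 1e-10)
})

test_that("residual-sd calibration hits the planted generating R^2 on average", {
  # the calibration target is a mean property across cohorts: at n = 40
  # a single draw scatters around it with sd ~0.12
  r2 <- vapply(1:100, function(s) {
    realized_model_r2(simulate_cohort(cohort_config(), seed = 10000 + s,
                                      generate_bold = FALSE), "attention")
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.6), 0.05)
  expect_lt(sd(r2), 0.2)
  # no planted support -> no defined generating R^2
  co <- simulate_cohort(cohort_config(), seed = 1, generate_bold = FALSE)
  expect_true(is.na(realized_model_r2(co, "delayed_recall")))
})

test_that("identical config and seed reproduce the written files exactly", {
  cfg <- cohort_config(n_pd = 2, n_ctr = 2, grid = c(14, 14, 8),
                       n_components = 3, n_timepoints = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, seed = 9, dir = d1)
  simulate_cohort(cfg, seed = 9, dir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted models referencing unknown components are rejected", {
  pm <- default_planted_models()
  pm$naming$components <- 9
  expect_error(cohort_config(n_components = 6, planted_models = pm),
               "unknown component")
  expect_error(cohort_config(n_pd = 1), "at least 2")
  pm2 <- default_planted_models()
  pm2$bogus_domain <- list(components = 1, beta = 1, r2 = 0.5)
  expect_error(cohort_config(planted_models = pm2), "unknown domain")
})

test_that("cohort config round-trips through its text representation", {
  cfg <- cohort_config(n_pd = 5, n_ctr = 3, noise_sd = 0.7, ar1 = 0.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n_pd, 5)
  expect_equal(back$noise_sd, 0.7)
  expect_equal(back$ar1, 0.3)
  expect_equal(back$planted_models$attention$components,
               cfg$planted_models$attention$components)
  expect_equal(back$planted_models$attention$r2, 0.6)
})
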