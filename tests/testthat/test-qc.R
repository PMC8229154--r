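test_that("map z-scoring uses the population scale and is affine-invariant", {
  z <- zscore_map(c(1, 2, 3, 4))
  expect_equal(z, c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  withr::with_seed(51, x <- rnorm(200))
  zz <- zscore_map(x)
  expect_equal(mean(zz), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(zz^2)), 1, tolerance = 1e-10)
  expect_equal(zscore_map(3.7 * x + 12), zz, tolerance = 1e-10)
  expect_error(zscore_map(rep(5, 10)), "constant")
})

test_that("the voxel-extent filter applies a strict fewer-than rule", {
  # build maps with an exactly known suprathreshold count
  mk <- function(n_supra, v = 1000) {
    x <- rep(0, v)
    x[seq_len(n_supra)] <- 100
    zscore_map(x)
  }
  expect_false(voxel_extent_filter(mk(49))$pass)
  r50 <- voxel_extent_filter(mk(50))
  expect_true(r50$pass)
  expect_equal(r50$count, 50)
  z0 <- rep(0, 100)
  expect_equal(voxel_extent_filter(z0)$count, 0)
  expect_false(voxel_extent_filter(z0)$pass)
})

test_that("low-frequency ratio separates slow signals, fast signals and noise", {
  t_idx <- seq(0, by = 2, length.out = 200)
  slow <- sin(2 * pi * 0.05 * t_idx)
  fast <- sin(2 * pi * 0.2 * t_idx)
  expect_gte(low_freq_ratio(slow, 2), 0.99)
  expect_lte(low_freq_ratio(fast, 2), 0.01)
  # white noise: expected ratio = band / Nyquist = 0.10 / 0.25
  withr::with_seed(52, {
    ratios <- replicate(100, low_freq_ratio(rnorm(200), 2))
  })
  expect_lt(abs(mean(ratios) - 0.4), 0.05)
  expect_error(low_freq_ratio(rep(1, 50), 2), "constant")
  expect_error(low_freq_ratio(rnorm(50), 2, band_edge_hz = 0.25), "Nyquist")
})

test_that("component assembly excludes by stability, label, then extent, with a reasoned report", {
  withr::with_seed(53, {
    v <- 800
    maps <- matrix(rnorm(5 * v), 5, v)
    maps[4, ] <- 0
    maps[4, 1:10] <- 50          # only 10 suprathreshold voxels
    icasso <- list(maps = maps, iq = c(0.95, 0.5, 0.9, 0.92, 0.99))
    rownames(icasso$maps) <- paste0("IC", 1:5)
    labels <- data.frame(ic_id = c("IC3", "IC5"),
                         label = c("artifact", "DMN"))
    set <- assemble_component_set(icasso, labels = labels)
  })
  expect_setequal(set$ic_ids, c("IC1", "IC5"))
  expect_equal(nrow(set$exclusions), 3)
  expect_equal(set$exclusions$reason[set$exclusions$ic_id == "IC2"], "low_iq")
  expect_equal(set$exclusions$reason[set$exclusions$ic_id == "IC3"], "artifact")
  expect_equal(set$exclusions$reason[set$exclusions$ic_id == "IC4"], "low_extent")
  expect_equal(unname(set$labels), c("unlabeled", "DMN"))
  # retained + excluded partition the input
  expect_equal(length(set$ic_ids) + nrow(set$exclusions), 5)

  # re-running the assembly on the retained set changes nothing
  again <- assemble_component_set(list(maps = set$z_maps, iq = set$iq),
                                  labels = data.frame(ic_id = "IC5",
                                                      label = "DMN"))
  expect_equal(again$ic_ids, set$ic_ids)
  expect_equal(nrow(again$exclusions), 0)
  expect_equal(again$z_maps, set$z_maps, tolerance = 1e-10)
})

test_that("labels are validated against the component set and duplicates rejected", {
  withr::with_seed(54, {
    icasso <- list(maps = matrix(rnorm(2 * 300), 2, 300), iq = c(0.9, 0.9))
    rownames(icasso$maps) <- c("IC1", "IC2")
  })
  expect_error(
    assemble_component_set(icasso,
                           labels = data.frame(ic_id = "IC9", label = "DMN")),
    "unknown component")
  expect_error(
    assemble_component_set(icasso,
                           labels = data.frame(ic_id = c("IC1", "IC1"),
                                               label = c("DMN", "VIS"))),
    "duplicate")
  expect_error(
    assemble_component_set(icasso,
                           labels = data.frame(ic_id = "IC1", label = "blah")),
    "unknown label")
  # no labels: everything retained as unlabeled
  set <- assemble_component_set(icasso)
  expect_equal(unname(set$labels), c("unlabeled", "unlabeled"))
  expect_equal(nrow(set$exclusions), 0)
})

test_that("label files and exclusion reports round-trip as text", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("IC1\tDMN", "IC2\tartifact"), path)
  lab <- read_component_labels(path)
  expect_equal(lab$label, c("DMN", "artifact"))

  withr::with_seed(55, {
    icasso <- list(maps = matrix(rnorm(2 * 300), 2, 300), iq = c(0.9, 0.2))
    rownames(icasso$maps) <- c("IC1", "IC2")
  })
  set <- assemble_component_set(icasso)
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_exclusion_report(set, rp)
  back <- read.delim(rp)
  expect_equal(back$ic_id, "IC2")
  expect_equal(back$reason, "low_iq")
})

test_that("reconstructed component time courses stay in the acquisition band", {
  co <- tiny_cohort(seed = 56, noise_sd = 0, n_pd = 2, n_ctr = 2,
                    grid = c(14, 14, 8), n_components = 3, n_timepoints = 60)
  red <- lapply(co$bold, reduce_subject, n_keep = 3)
  grp <- concat_group_pca(red, K = 3)
  z <- t(apply(co$truth$sources$maps, 1, zscore_map))
  tcs <- component_timecourses(grp, z)
  expect_equal(length(tcs), 4)
  expect_equal(dim(tcs[[1]]), c(60L, 3L))
  for (tc in tcs) {
    for (k in 1:3) expect_gte(low_freq_ratio(tc[, k], 2), 0.9)
  }
})
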