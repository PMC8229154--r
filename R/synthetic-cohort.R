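#' Simulate compact, near-orthogonal spatial sources
#'
#' Places `n_components` Gaussian blobs at well-separated centers inside an
#' ellipsoidal brain-like mask and returns them as unit-norm spatial maps
#' over the mask. The construction guarantees the properties downstream
#' stages assume of genuine intrinsic networks: each map has at least 50
#' suprathreshold voxels at |z| >= 1 after z-scoring, and map pairs are
#' nearly orthogonal (|cosine| < 0.2), which makes the ICA problem
#' identifiable without pretending to anatomical realism.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param n_components Number of sources (>= 1).
#' @param seed Integer seed; the same seed reproduces the maps bit for bit.
#' @param sigma Blob standard deviation in voxels.
#' @param min_separation Minimum distance between blob centers, voxels.
#' @param mask_scale Ellipsoid semi-axes as a fraction of the half-grid.
#' @return List with `maps` (components x voxels, unit-norm rows),
#'   `mask_index`, `dims`, `affine`, `centers`, `sigma`.
#' @export
simulate_sources <- function(grid_shape = c(20, 20, 10), n_components = 6,
                             seed = 1, sigma = 1.8, min_separation = 5.5,
                             mask_scale = 0.92) {
  if (!is_count(n_components) || n_components < 1) {
    stopf("n_components must be a positive integer")
  }
  dims <- as.integer(grid_shape)
  if (length(dims) != 3L || any(dims < 4L)) {
    stopf("grid_shape must be three dimensions of at least 4 voxels")
  }
  centre <- (dims + 1) / 2
  semi <- pmax((dims - 1) / 2 * mask_scale, 1)
  full <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                z = seq_len(dims[3])))
  r2 <- ((full[, 1] - centre[1]) / semi[1])^2 +
        ((full[, 2] - centre[2]) / semi[2])^2 +
        ((full[, 3] - centre[3]) / semi[3])^2
  mask <- array(0L, dims)
  mask[full[r2 <= 1, , drop = FALSE]] <- 1L
  co <- mask_coords(mask)

  # candidate centers: keep blobs away from the mask boundary
  cand_r2 <- ((co[, 1] - centre[1]) / semi[1])^2 +
             ((co[, 2] - centre[2]) / semi[2])^2 +
             ((co[, 3] - centre[3]) / semi[3])^2
  cand <- co[cand_r2 <= 0.55, , drop = FALSE]
  if (nrow(cand) < n_components) {
    stopf("grid %s too small to place %d sources",
          paste(dims, collapse = "x"), n_components)
  }

  centers <- withr::with_seed(seed, {
    placed <- NULL
    for (attempt in seq_len(200)) {
      ord <- sample.int(nrow(cand))
      placed <- cand[ord[1], , drop = FALSE]
      for (i in ord[-1]) {
        if (nrow(placed) == n_components) break
        d <- sqrt(rowSums((placed - matrix(cand[i, ], nrow(placed), 3,
                                           byrow = TRUE))^2))
        if (all(d >= min_separation)) placed <- rbind(placed, cand[i, ])
      }
      if (nrow(placed) == n_components) break
    }
    placed
  })
  if (nrow(centers) < n_components) {
    stopf("grid %s too small to place %d sources %g voxels apart",
          paste(dims, collapse = "x"), n_components, min_separation)
  }

  maps <- matrix(0, n_components, nrow(co))
  for (k in seq_len(n_components)) {
    d2 <- rowSums(sweep(co, 2, centers[k, ])^2)
    v <- exp(-d2 / (2 * sigma^2))
    v[d2 > (3 * sigma)^2] <- 0   # compact support
    maps[k, ] <- v / sqrt(sum(v^2))
  }
  # center over the mask and symmetrically decorrelate: the linear ICA
  # model assumes spatially uncorrelated sources, and raw positive blobs
  # acquire mutual correlation once their common positive mean is removed
  maps <- maps - rowMeans(maps)
  if (n_components > 1) {
    eg <- eigen(tcrossprod(maps), symmetric = TRUE)
    inv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(pmax(eg$values, 1e-12)))
    maps <- inv_sqrt %*% maps
  } else {
    maps <- maps / sqrt(sum(maps^2))
  }

  # construction invariants: extent-filter survivability and identifiability
  for (k in seq_len(n_components)) {
    z <- (maps[k, ] - mean(maps[k, ])) / sd_pop(maps[k, ])
    if (sum(abs(z) >= 1) < 50) {
      stopf("source %d has <50 voxels at |z|>=1; enlarge the grid or sigma", k)
    }
  }
  if (n_components > 1) {
    cs <- abs(tcrossprod(maps))
    diag(cs) <- 0
    if (max(cs) >= 0.2) {
      stopf("sources not near-orthogonal (max |cosine| = %.3f); increase separation",
            max(cs))
    }
  }
  list(maps = maps, mask_index = co, dims = dims,
       affine = diag(c(3, 3, 3, 1)), centers = centers, sigma = sigma)
}

# Band-limited time course: random phases/amplitudes on in-band Fourier
# bins, inverse transform, standardized to zero mean and unit variance.
simulate_timecourse <- function(n_timepoints, tr_seconds, band = c(0.01, 0.08)) {
  nyquist <- 1 / (2 * tr_seconds)
  if (band[2] >= nyquist) {
    stopf("band edge %.3f Hz is at or above Nyquist (%.3f Hz)", band[2], nyquist)
  }
  nf <- floor(n_timepoints / 2)
  freqs <- seq_len(nf) / (n_timepoints * tr_seconds)
  sel <- which(freqs >= band[1] & freqs <= band[2] & seq_len(nf) < n_timepoints / 2)
  if (length(sel) == 0L) {
    stopf("no Fourier bins inside band [%g, %g] Hz at T=%d, TR=%gs",
          band[1], band[2], n_timepoints, tr_seconds)
  }
  spec <- complex(n_timepoints)
  z <- complex(real = stats::rnorm(length(sel)),
               imaginary = stats::rnorm(length(sel)))
  spec[sel + 1] <- z
  spec[n_timepoints - sel + 1] <- Conj(z)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n_timepoints
  (x - mean(x)) / stats::sd(x)
}

#' Default planted domain-score models
#'
#' The generating models used unless a configuration overrides them: sparse
#' supports over the first six components with mixed-sign coefficients; the
#' attention domain carries the three-component reference model at
#' generating R^2 0.6, and delayed recall is left without signal. When the
#' cohort has fewer than six components, supports are truncated to the
#' available ones.
#'
#' @param n_components Number of generated components available.
#' @return Named per-domain list of `components`, `beta`, `r2`.
#' @export
default_planted_models <- function(n_components = 6) {
  pms <- list(
    visuospatial_executive = list(components = c(1, 2), beta = c(1.0, -0.7), r2 = 0.5),
    naming                 = list(components = 4, beta = 0.8, r2 = 0.35),
    attention              = list(components = c(1, 3, 5), beta = c(1.2, -0.8, 1.0), r2 = 0.6),
    language               = list(components = c(2, 6), beta = c(0.9, 0.6), r2 = 0.5),
    abstraction            = list(components = 6, beta = -0.5, r2 = 0.15),
    delayed_recall         = list(components = integer(0), beta = numeric(0), r2 = 0),
    orientation            = list(components = c(3, 4), beta = c(0.7, -0.6), r2 = 0.5)
  )
  lapply(pms, function(pm) {
    keep <- pm$components <= n_components
    list(components = pm$components[keep], beta = pm$beta[keep], r2 = pm$r2)
  })
}

#' Synthetic cohort configuration
#'
#' Default values define the emulated study conditions: 40 PD patients and
#' 15 controls, TR 2 s, 150 volumes, six compact sources on a 20x20x10
#' grid, component time courses band-limited to 0.01-0.08 Hz, additive
#' white Gaussian noise (optionally AR(1)), subject expression loadings
#' N(1, 0.3^2), and MoCA-like domain scores planted as sparse linear models
#' on the loadings. The attention domain carries a three-component model
#' with generating R^2 = 0.6; delayed recall has no planted signal, so a
#' correct modeling stage reports it as "not generated".
#'
#' @param grid,n_components,n_pd,n_ctr,n_timepoints,tr,band,noise_sd
#'   Cohort geometry and noise level.
#' @param amplitude Source amplitude multiplying unit-norm maps.
#' @param loading_mean,loading_sd Subject expression loading distribution.
#' @param planted_models Per-domain list of `components`, `beta`, and either
#'   `r2` (residual sd calibrated to hit that generating R^2, accounting for
#'   score rounding) or `residual_sd` (used as given).
#' @param round_scores Round and clip domain scores to their integer ranges.
#' @param ar1 AR(1) coefficient for temporally autocorrelated noise
#'   (0 = white, the default).
#' @param seed Base seed stored with the config.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(grid = c(20, 20, 10), n_components = 6,
                          n_pd = 40, n_ctr = 15, n_timepoints = 150,
                          tr = 2.0, band = c(0.01, 0.08), noise_sd = 1.0,
                          amplitude = 30, loading_mean = 1, loading_sd = 0.3,
                          planted_models = default_planted_models(n_components),
                          round_scores = TRUE, ar1 = 0, seed = 1) {
  if (n_pd < 2 || n_ctr < 2) stopf("each group needs at least 2 subjects")
  for (nm in names(planted_models)) {
    pm <- planted_models[[nm]]
    if (length(pm$components) != length(pm$beta)) {
      stopf("planted model '%s': components and beta lengths differ", nm)
    }
    if (length(pm$components) > 0 &&
        (any(pm$components < 1) || any(pm$components > n_components))) {
      stopf("planted model '%s' references unknown component(s): %s", nm,
            paste(setdiff(pm$components, seq_len(n_components)), collapse = ", "))
    }
  }
  unknown <- setdiff(names(planted_models), moca_domains()$domain)
  if (length(unknown) > 0L) {
    stopf("planted model(s) for unknown domain(s): %s",
          paste(unknown, collapse = ", "))
  }
  structure(list(grid = grid, n_components = n_components, n_pd = n_pd,
                 n_ctr = n_ctr, n_timepoints = n_timepoints, tr = tr,
                 band = band, noise_sd = noise_sd, amplitude = amplitude,
                 loading_mean = loading_mean, loading_sd = loading_sd,
                 planted_models = planted_models,
                 round_scores = round_scores, ar1 = ar1, seed = seed),
            class = "cohort_config")
}

#' Write / read a cohort configuration as structured text
#'
#' @param config A [cohort_config()].
#' @param path File path (tab-separated key-value text).
#' @export
write_cohort_config <- function(config, path) {
  flat <- config
  flat$planted_models <- NULL
  lines <- vapply(names(flat), function(k) {
    paste0(k, "\t", paste(flat[[k]], collapse = ","))
  }, character(1))
  for (nm in names(config$planted_models)) {
    pm <- config$planted_models[[nm]]
    lines <- c(lines, paste0(
      "planted_model\t", nm, "\t",
      paste(pm$components, collapse = ","), "\t",
      paste(pm$beta, collapse = ","), "\t",
      if (!is.null(pm$residual_sd)) paste0("residual_sd=", pm$residual_sd)
      else paste0("r2=", pm$r2)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  kv <- parts[vapply(parts, function(p) p[1] != "planted_model", logical(1))]
  args <- list()
  num_keys <- c("grid", "n_components", "n_pd", "n_ctr", "n_timepoints",
                "tr", "band", "noise_sd", "amplitude", "loading_mean",
                "loading_sd", "ar1", "seed")
  for (p in kv) {
    val <- strsplit(p[2], ",")[[1]]
    args[[p[1]]] <- if (p[1] %in% num_keys) as.numeric(val) else as.logical(val)
  }
  pms <- parts[vapply(parts, function(p) p[1] == "planted_model", logical(1))]
  if (length(pms) > 0) {
    planted <- list()
    for (p in pms) {
      comp <- if (nzchar(p[3])) as.numeric(strsplit(p[3], ",")[[1]]) else numeric(0)
      beta <- if (nzchar(p[4])) as.numeric(strsplit(p[4], ",")[[1]]) else numeric(0)
      kvs <- strsplit(p[5], "=")[[1]]
      pm <- list(components = comp, beta = beta)
      pm[[kvs[1]]] <- as.numeric(kvs[2])
      planted[[p[2]]] <- pm
    }
    args$planted_models <- planted
  }
  do.call(cohort_config, args)
}

# Calibrate the planted score model for one domain. The integer score is
# round(mid + c*(eta - E eta) + eps); rounding adds ~1/12 variance, which
# the residual calibration absorbs so the generating R^2 hits its target.
plant_domain_model <- function(pm, max_score, loading_sd, round_scores) {
  mid <- max_score / 2
  sd_total <- max_score / 5
  if (length(pm$components) == 0L) {
    return(list(components = integer(0), beta = numeric(0), scale = 0,
                mid = mid, sd_total = sd_total, residual_sd = sd_total,
                r2 = 0))
  }
  var_eta <- loading_sd^2 * sum(pm$beta^2)
  if (!is.null(pm$residual_sd)) {
    scale <- 1
    resid_sd <- pm$residual_sd
    r2 <- var_eta / (var_eta + resid_sd^2)
  } else {
    r2 <- pm$r2
    scale <- sqrt(r2 * sd_total^2 / var_eta)
    round_var <- if (round_scores) 1 / 12 else 0
    resid_sd <- sqrt(max((1 - r2) * sd_total^2 - round_var, 1e-4))
  }
  list(components = pm$components, beta = pm$beta, scale = scale,
       mid = mid, sd_total = sd_total, residual_sd = resid_sd, r2 = r2)
}

#' Build the ground truth for a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of class `ground_truth`: sources, per-subject loadings,
#'   time-course band/amplitude, noise sd, calibrated planted models, and
#'   domain ranges.
#' @export
ground_truth <- function(config = cohort_config(), seed = config$seed) {
  seeds <- spawn_seeds(seed, 2)
  src <- simulate_sources(config$grid, config$n_components, seed = seeds[1])
  n_sub <- config$n_pd + config$n_ctr
  loadings <- withr::with_seed(seeds[2], {
    matrix(stats::rnorm(n_sub * config$n_components, config$loading_mean,
                        config$loading_sd),
           n_sub, config$n_components)
  })
  dom <- moca_domains()
  planted <- list()
  for (nm in dom$domain) {
    pm <- config$planted_models[[nm]]
    if (is.null(pm)) pm <- list(components = integer(0), beta = numeric(0), r2 = 0)
    planted[[nm]] <- plant_domain_model(pm, dom$max_score[dom$domain == nm],
                                        config$loading_sd, config$round_scores)
  }
  structure(list(sources = src, subject_loadings = loadings,
                 band = config$band, amplitude = config$amplitude,
                 noise_sd = config$noise_sd, ar1 = config$ar1,
                 planted_models = planted, domain_ranges = dom,
                 config = config),
            class = "ground_truth")
}

#' Simulate one subject's BOLD series from the ground truth
#'
#' The voxels x time data matrix is the linear mixture of the subject's
#' loading-scaled source maps with band-limited time courses, plus Gaussian
#' noise (white by default, AR(1) if configured).
#'
#' @param truth A [ground_truth()] object.
#' @param subject_index Row of the loading matrix to use.
#' @param n_timepoints Number of volumes (>= 30).
#' @param tr_seconds Repetition time in seconds.
#' @param seed Integer seed (per subject).
#' @return A [masked_bold()] object.
#' @export
simulate_subject_bold <- function(truth, subject_index,
                                  n_timepoints = truth$config$n_timepoints,
                                  tr_seconds = truth$config$tr,
                                  seed = 1) {
  if (!is_count(n_timepoints) || n_timepoints < 30) {
    stopf("n_timepoints must be an integer >= 30")
  }
  if (tr_seconds <= 0) stopf("tr_seconds must be > 0")
  src <- truth$sources
  K <- nrow(src$maps)
  load_k <- truth$subject_loadings[subject_index, ]
  withr::with_seed(seed, {
    tc <- t(vapply(seq_len(K), function(k) {
      simulate_timecourse(n_timepoints, tr_seconds, truth$band)
    }, numeric(n_timepoints)))
    signal <- crossprod(src$maps, (load_k * truth$amplitude) * tc)
    noise <- 0
    if (truth$noise_sd > 0) {
      nv <- nrow(signal)
      eps <- matrix(stats::rnorm(nv * n_timepoints, sd = truth$noise_sd),
                    nv, n_timepoints)
      if (truth$ar1 != 0) {
        for (t in 2:n_timepoints) {
          eps[, t] <- truth$ar1 * eps[, t - 1] +
            sqrt(1 - truth$ar1^2) * eps[, t]
        }
      }
      noise <- eps
    }
    masked_bold(signal + noise, src$mask_index, src$dims, src$affine,
                tr_seconds, id = sprintf("sub%03d", subject_index))
  })
}

# Domain scores for the PD rows of the loading matrix.
planted_domain_scores <- function(truth, pd_rows, round_scores = TRUE) {
  dom <- truth$domain_ranges
  out <- matrix(NA_real_, length(pd_rows), nrow(dom),
                dimnames = list(NULL, paste0("moca_", dom$domain)))
  for (j in seq_len(nrow(dom))) {
    pm <- truth$planted_models[[dom$domain[j]]]
    eta <- if (length(pm$components) > 0) {
      drop(truth$subject_loadings[pd_rows, pm$components, drop = FALSE] %*% pm$beta)
    } else rep(0, length(pd_rows))
    mu_eta <- truth$config$loading_mean * sum(pm$beta)
    y <- pm$mid + pm$scale * (eta - mu_eta) +
      stats::rnorm(length(pd_rows), sd = pm$residual_sd)
    if (round_scores) y <- pmin(pmax(round(y), 0), dom$max_score[j])
    out[, j] <- y
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates ground truth, per-subject BOLD series, and a subject metadata
#' table. PD subjects receive MoCA domain scores from the planted linear
#' models on their expression loadings; controls receive MMSE only,
#' mirroring a design in which the detailed cognitive battery is
#' administered to patients alone. If `dir` is given, 4D NIfTI files, the
#' mask, the metadata TSV and the config are written there.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical config + seed reproduce the cohort
#'   (and any written files) exactly.
#' @param dir Optional output directory.
#' @param generate_bold If `FALSE`, skip BOLD simulation (metadata and
#'   ground truth only; useful for score-model calibration work).
#' @return List of class `synthetic_cohort`: `truth`, `metadata`, `bold`
#'   (list of [masked_bold()] or `NULL`), `config`, `files`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed,
                            dir = NULL, generate_bold = TRUE) {
  n_sub <- config$n_pd + config$n_ctr
  seeds <- spawn_seeds(seed, 2 + n_sub)
  truth <- ground_truth(config, seed = seeds[1])
  group <- c(rep("PD", config$n_pd), rep("Ctr", config$n_ctr))
  pd_rows <- which(group == "PD")

  metadata <- withr::with_seed(seeds[2], {
    md <- data.frame(
      id = sprintf("sub%03d", seq_len(n_sub)),
      group = group,
      age = round(ifelse(group == "PD", stats::rnorm(n_sub, 69, 9.0),
                         stats::rnorm(n_sub, 66, 13.9))),
      sex = ifelse(stats::runif(n_sub) < ifelse(group == "PD", 22 / 40, 7 / 15),
                   "M", "F"),
      handedness = ifelse(stats::runif(n_sub) <
                            ifelse(group == "PD", 36 / 40, 14 / 15), "R", "L"),
      disease_duration = ifelse(group == "PD",
                                round(pmax(stats::rnorm(n_sub, 5.1, 5.84), 0.5), 1),
                                NA),
      hoehn_yahr = ifelse(group == "PD",
                          pmin(pmax(round(stats::rnorm(n_sub, 2.1, 0.97)), 1), 5),
                          NA),
      mmse = ifelse(group == "PD",
                    pmin(pmax(round(stats::rnorm(n_sub, 26.5, 2.67)), 0), 30),
                    pmin(pmax(round(stats::rnorm(n_sub, 28.6, 1.55)), 24), 30)),
      stringsAsFactors = FALSE
    )
    scores <- matrix(NA_real_, n_sub, 7,
                     dimnames = list(NULL, moca_columns()))
    scores[pd_rows, ] <- planted_domain_scores(truth, pd_rows,
                                               config$round_scores)
    md <- cbind(md, as.data.frame(scores))
    # single-drug regimens whose LED matches a typical treated PD cohort
    dose <- ifelse(group == "PD",
                   round(stats::rgamma(n_sub, shape = 0.6, scale = 201 / 0.6)),
                   0)
    md$dose_levodopa_carbidopa <- dose
    md$led <- vapply(dose, function(d) {
      compute_led(c("levodopa/carbidopa" = d))
    }, numeric(1))
    md$led[group == "Ctr"] <- NA
    md$max_displacement_mm <- round(stats::runif(n_sub, 0.05, 2.5), 3)
    md
  })

  bold <- NULL
  if (generate_bold) {
    bold <- lapply(seq_len(n_sub), function(i) {
      simulate_subject_bold(truth, i, config$n_timepoints, config$tr,
                            seed = seeds[2 + i])
    })
  }

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    src <- truth$sources
    mask_path <- file.path(dir, "mask.nii")
    write_mask_nifti(src$mask_index, src$dims, src$affine, mask_path)
    bold_paths <- character(0)
    if (generate_bold) {
      bold_paths <- vapply(bold, function(b) {
        p <- file.path(dir, paste0(b$id, "_bold.nii"))
        write_bold_nifti(b, p)
        p
      }, character(1))
    }
    meta_path <- file.path(dir, "metadata.tsv")
    write_subject_table(metadata, meta_path)
    cfg_path <- file.path(dir, "config.tsv")
    write_cohort_config(config, cfg_path)
    files <- list(mask = mask_path, bold = bold_paths, metadata = meta_path,
                  config = cfg_path)
  }
  structure(list(truth = truth, metadata = metadata, bold = bold,
                 config = config, files = files),
            class = "synthetic_cohort")
}

#' Generating-model R-squared realized in a simulated cohort
#'
#' Computes, for one domain, the R^2 of the *planted* linear predictor (true
#' coefficients, no refitting) against the domain scores actually generated
#' for the PD group — the quantity the residual-sd calibration targets.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param domain Domain name, e.g. `"attention"`.
#' @return Scalar R^2, or `NA` if the domain has no planted components.
#' @export
realized_model_r2 <- function(cohort, domain) {
  truth <- cohort$truth
  pm <- truth$planted_models[[domain]]
  if (length(pm$components) == 0L) return(NA_real_)
  pd_rows <- which(cohort$metadata$group == "PD")
  y <- cohort$metadata[[paste0("moca_", domain)]][pd_rows]
  eta <- drop(truth$subject_loadings[pd_rows, pm$components, drop = FALSE] %*%
                pm$beta)
  mu_eta <- truth$config$loading_mean * sum(pm$beta)
  yhat <- pm$mid + pm$scale * (eta - mu_eta)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}
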