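#' Bidirectional stepwise multiple regression
#'
#' Classic p-value stepwise selection as implemented by mainstream
#' statistics packages: at each iteration the candidate with the smallest
#' partial-F p-value enters if that p-value is at most `alpha_enter`, then
#' any included predictor whose p-value has risen to `alpha_remove` or
#' above is removed (worst first). Iteration stops at a fixed point, with a
#' cycle guard capped at `2 * ncol(x)` iterations (on a cycle, the visited
#' state with the best R^2 is kept, with a warning). Candidates whose entry
#' would make the design numerically collinear (condition number > 1e8)
#' are refused.
#'
#' @param x Numeric matrix (or data frame) of candidate predictors with
#'   column names; for domain modeling these are network-score columns.
#' @param y Response vector, no missing values.
#' @param alpha_enter Entry threshold, default 0.05.
#' @param alpha_remove Removal threshold, default 0.10 (must exceed
#'   `alpha_enter`).
#' @param domain Optional name carried into the result.
#' @return List of class `domain_model`: `domain`, `ic_ids` (selected, in
#'   entry order), `coefficients` (data frame `ic_id`, `B`, `ci_lo`,
#'   `ci_hi`, `p`; t-based 95% intervals with df = n - k - 1), `intercept`,
#'   `r2`, `model_p`, `generated` (`FALSE` iff nothing was selected), `n`.
#' @export
stepwise_fit <- function(x, y, alpha_enter = 0.05, alpha_remove = 0.10,
                         domain = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- length(y)
  if (n <= 2) stopf("need more than 2 observations")
  if (nrow(x) != n) stopf("x and y disagree on the number of observations")
  if (any(is.na(y)) || any(is.na(x))) stopf("missing values are not allowed")
  if (!(alpha_enter < alpha_remove)) {
    stopf("alpha_enter must be smaller than alpha_remove")
  }
  p <- ncol(x)
  sel <- character(0)
  visited <- character(0)
  best <- list(r2 = -Inf, sel = sel)
  cycled <- FALSE

  coef_p <- function(fit) {
    # near-perfect fits warn in summary.lm; that case is guarded explicitly
    cf <- suppressWarnings(summary(fit))$coefficients
    cf[-1, 4]   # drop intercept row
  }
  fit_for <- function(vars) {
    stats::lm(y ~ ., data = as.data.frame(x[, vars, drop = FALSE]))
  }

  ss_tot <- sum((y - mean(y))^2)
  for (iter in seq_len(max(2L * p, 2L))) {
    changed <- FALSE
    # an (essentially) perfect fit leaves nothing for further candidates
    if (length(sel) > 0L &&
        sum(stats::residuals(fit_for(sel))^2) <= 1e-12 * ss_tot) {
      best <- list(r2 = 1, sel = sel)
      break
    }
    # forward: best admissible candidate
    cand <- setdiff(colnames(x), sel)
    if (length(cand) > 0L) {
      pvals <- vapply(cand, function(j) {
        design <- cbind(1, x[, c(sel, j), drop = FALSE])
        if (kappa(design, exact = TRUE) > 1e8) return(NA_real_)
        fit <- fit_for(c(sel, j))
        if (any(is.na(stats::coef(fit)))) return(NA_real_)
        unname(coef_p(fit)[length(sel) + 1L])
      }, numeric(1))
      if (any(!is.na(pvals))) {
        jbest <- cand[which.min(pvals)]
        if (min(pvals, na.rm = TRUE) <= alpha_enter) {
          sel <- c(sel, jbest)
          changed <- TRUE
        }
      }
    }
    # backward: drop anything that has become unnecessary
    while (length(sel) > 0L) {
      ps <- coef_p(fit_for(sel))
      if (max(ps) >= alpha_remove) {
        sel <- sel[-which.max(ps)]
        changed <- TRUE
      } else break
    }
    state <- paste(sort(sel), collapse = "|")
    if (length(sel) > 0L) {
      r2 <- suppressWarnings(summary(fit_for(sel)))$r.squared
      if (r2 > best$r2) best <- list(r2 = r2, sel = sel)
    }
    if (!changed) break
    if (state %in% visited) {
      warnf("stepwise selection cycled; keeping best-R^2 visited state")
      sel <- best$sel
      cycled <- TRUE
      break
    }
    visited <- c(visited, state)
  }

  if (length(sel) == 0L) {
    return(structure(list(domain = domain, ic_ids = character(0),
                          coefficients = data.frame(ic_id = character(0),
                                                    B = numeric(0),
                                                    ci_lo = numeric(0),
                                                    ci_hi = numeric(0),
                                                    p = numeric(0)),
                          intercept = mean(y), r2 = 0, model_p = NA_real_,
                          generated = FALSE, n = n),
                     class = "domain_model"))
  }
  fit <- fit_for(sel)
  sm <- suppressWarnings(summary(fit))
  ci <- stats::confint(fit, level = 0.95)
  cf <- sm$coefficients
  fstat <- sm$fstatistic
  model_p <- unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE))
  cfm <- cf[-1, , drop = FALSE]
  cim <- ci[-1, , drop = FALSE]
  coefs <- data.frame(
    ic_id = sel,
    B = unname(cfm[sel, 1]),
    ci_lo = unname(cim[sel, 1]),
    ci_hi = unname(cim[sel, 2]),
    p = unname(cfm[sel, 4]),
    stringsAsFactors = FALSE
  )
  structure(list(domain = domain, ic_ids = sel, coefficients = coefs,
                 intercept = unname(cf[1, 1]), r2 = sm$r.squared,
                 model_p = model_p, generated = TRUE, n = n,
                 cycled = cycled),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  if (!x$generated) {
    cat(sprintf("<domain_model> %s: not generated\n",
                if (is.null(x$domain)) "?" else x$domain))
    return(invisible(x))
  }
  cat(sprintf("<domain_model> %s: R^2 = %.2f (p = %.3g), n = %d\n",
              if (is.null(x$domain)) "?" else x$domain, x$r2, x$model_p, x$n))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit a stepwise model for every MoCA domain
#'
#' Restricts to patients (the group with domain scores), regresses each
#' domain on the network-score columns, and returns one model per domain.
#'
#' @param scores A `network_scores` object (or subjects x components
#'   matrix).
#' @param metadata Subject table with `group` and `moca_*` columns, rows
#'   aligned with the score matrix.
#' @param domains Domain names, default all seven.
#' @param group Which group's scores to model, default `"PD"`.
#' @inheritParams stepwise_fit
#' @return Named list of `domain_model` objects.
#' @export
fit_domain_models <- function(scores, metadata,
                              domains = moca_domains()$domain,
                              group = "PD", alpha_enter = 0.05,
                              alpha_remove = 0.10) {
  sm <- if (inherits(scores, "network_scores")) scores$scores else as.matrix(scores)
  rows <- metadata$group == group
  out <- list()
  for (d in domains) {
    y <- metadata[[paste0("moca_", d)]][rows]
    if (all(is.na(y))) next
    out[[d]] <- stepwise_fit(sm[rows, , drop = FALSE], y, alpha_enter,
                             alpha_remove, domain = d)
  }
  out
}

#' Compose a domain-related network map
#'
#' The domain-related network is the linear combination of the group
#' component z-maps weighted by the model coefficients; negative
#' coefficients contribute with negative sign.
#'
#' @param model A generated `domain_model`.
#' @param group_maps Components x voxels matrix with rows named by
#'   component id, covering every selected component.
#' @return List of class `composite_map`: `domain`, `values` (per-voxel
#'   vector), `ic_ids`, `coefficients`.
#' @export
compose_domain_network <- function(model, group_maps) {
  if (!isTRUE(model$generated)) {
    stopf("domain model '%s' was not generated; nothing to compose",
          if (is.null(model$domain)) "?" else model$domain)
  }
  g <- as.matrix(group_maps)
  ids <- rownames(g)
  missing_ids <- setdiff(model$ic_ids, ids)
  if (length(missing_ids) > 0L) {
    stopf("group maps missing component(s): %s",
          paste(missing_ids, collapse = ", "))
  }
  b <- stats::setNames(model$coefficients$B, model$coefficients$ic_id)
  values <- drop(crossprod(g[model$ic_ids, , drop = FALSE], b[model$ic_ids]))
  structure(list(domain = model$domain, values = values,
                 ic_ids = model$ic_ids, coefficients = b),
            class = "composite_map")
}

#' Find hub components shared across domain models
#'
#' Components selected in at least `min_membership` generated domain
#' models, with the domains they belong to, sorted by membership count
#' (descending) then component number.
#'
#' @param models List of `domain_model` objects (>= 2 generated).
#' @param min_membership Minimum number of models, default 2.
#' @return Data frame with columns `ic_id`, `n_domains`, `domains`.
#' @export
find_hubs <- function(models, min_membership = 2) {
  gen <- Filter(function(m) isTRUE(m$generated), models)
  if (length(gen) < 2L) stopf("need at least 2 generated models")
  pairs <- do.call(rbind, lapply(gen, function(m) {
    data.frame(ic_id = m$ic_ids, domain = m$domain, stringsAsFactors = FALSE)
  }))
  counts <- table(pairs$ic_id)
  hubs <- names(counts)[counts >= min_membership]
  if (length(hubs) == 0L) {
    return(data.frame(ic_id = character(0), n_domains = integer(0),
                      domains = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    ic_id = hubs,
    n_domains = as.integer(counts[hubs]),
    domains = vapply(hubs, function(h) {
      paste(pairs$domain[pairs$ic_id == h], collapse = ", ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_domains, ic_number(out$ic_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a table of fitted domain models
#'
#' Parses a tab-separated report with columns `domain`, `r2`, `ic_id`,
#' `region`, `network`, `b`, `ci_lo`, `ci_hi`, `p` (one row per selected
#' component; a domain whose `ic_id` is `NA` is a model that was not
#' generated) into a list of `domain_model` objects, e.g. the packaged
#' example table of published models from a PD cohort.
#'
#' @param path Path to the TSV file.
#' @return Named list of `domain_model` objects.
#' @export
read_domain_models <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("domain", "r2", "ic_id", "b", "ci_lo", "ci_hi", "p")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stopf("model table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  # p printed as a bound ("<0.001") is read at that bound
  if (is.character(tab$p)) tab$p <- as.numeric(sub("^<", "", tab$p))
  out <- list()
  for (d in unique(tab$domain)) {
    rows <- tab[tab$domain == d, , drop = FALSE]
    if (all(is.na(rows$ic_id))) {
      out[[d]] <- structure(list(domain = d, ic_ids = character(0),
                                 coefficients = data.frame(),
                                 intercept = NA_real_, r2 = NA_real_,
                                 model_p = NA_real_, generated = FALSE,
                                 n = NA_integer_),
                            class = "domain_model")
    } else {
      out[[d]] <- structure(list(
        domain = d, ic_ids = rows$ic_id,
        coefficients = data.frame(ic_id = rows$ic_id, B = rows$b,
                                  ci_lo = rows$ci_lo, ci_hi = rows$ci_hi,
                                  p = rows$p, stringsAsFactors = FALSE),
        intercept = NA_real_, r2 = rows$r2[1], model_p = NA_real_,
        generated = TRUE, n = NA_integer_), class = "domain_model")
    }
  }
  out
}

#' Write domain models as a structured report
#'
#' One row per selected component (dependent variable, R^2, component, B,
#' 95% CI, p); a non-generated domain contributes a single NA row.
#'
#' @param models List of `domain_model` objects.
#' @param path Output path.
#' @export
write_domain_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    if (!m$generated) {
      data.frame(domain = m$domain, r2 = NA_real_, ic_id = NA_character_,
                 b = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(domain = m$domain, r2 = m$r2, ic_id = m$coefficients$ic_id,
                 b = m$coefficients$B, ci_lo = m$coefficients$ci_lo,
                 ci_hi = m$coefficients$ci_hi, p = m$coefficients$p,
                 stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-component group comparison of network scores
#'
#' Two-tailed two-sample t-test of each score column between the two
#' groups: pooled-variance Student by default, Welch by flag. No
#' multiplicity correction is applied (per-component p-values are reported
#' as-is).
#'
#' @param scores A `network_scores` object or subjects x components matrix.
#' @param groups Group label per subject (exactly two levels, each with at
#'   least 2 subjects); differences are level1 - level2 in sorted label
#'   order.
#' @param alpha Significance level for the flag, default 0.05.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return Data frame: `ic_id`, `mean_diff`, `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(scores, groups = NULL, alpha = 0.05,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (inherits(scores, "network_scores")) {
    if (is.null(groups)) groups <- scores$groups
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) stopf("`groups` must have exactly 2 levels")
  i1 <- groups == lv[1]
  i2 <- groups == lv[2]
  if (sum(i1) < 2 || sum(i2) < 2) stopf("both groups need at least 2 subjects")
  ids <- colnames(scores)
  if (is.null(ids)) ids <- paste0("IC", seq_len(ncol(scores)))
  res <- lapply(seq_len(ncol(scores)), function(k) {
    x1 <- scores[i1, k]
    x2 <- scores[i2, k]
    if (stats::var(x1) == 0 && stats::var(x2) == 0) {
      stopf("zero variance in both groups for %s", ids[k])
    }
    tt <- stats::t.test(x1, x2, var.equal = variant == "student")
    data.frame(ic_id = ids[k], mean_diff = mean(x1) - mean(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' t-test from summary statistics
#'
#' Closed-form two-tailed two-sample t-test from group means, standard
#' deviations and sizes, pooled-variance (Student) or Welch. Agrees exactly
#' with [compare_groups()] on raw data constructed to match the summaries.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("standard deviations must be positive")
  if (variant == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
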