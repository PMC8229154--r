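test_that("exact linear dependence is found exactly", {
  withr::with_seed(81, {
    x <- matrix(rnorm(50 * 10), 50, 10)
    colnames(x) <- paste0("IC", 1:10)
    y <- 2 * x[, 3]
  })
  suppressWarnings(m <- stepwise_fit(x, y))
  expect_true(m$generated)
  expect_equal(m$ic_ids, "IC3")
  expect_equal(m$coefficients$B, 2, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-10)
})

test_that("a response orthogonal to every candidate generates no model", {
  withr::with_seed(82, {
    x <- matrix(rnorm(40 * 6), 40, 6)
    colnames(x) <- paste0("IC", 1:6)
    y0 <- rnorm(40)
    # project out every candidate so each marginal fit is exactly null
    y <- residuals(lm(y0 ~ x))
  })
  m <- stepwise_fit(x, y)
  expect_false(m$generated)
  expect_equal(length(m$ic_ids), 0)
  expect_equal(m$r2, 0)
  expect_equal(nrow(m$coefficients), 0)
})

test_that("strong planted effects are always included and CIs bracket the estimates", {
  withr::with_seed(83, {
    x <- matrix(rnorm(200 * 10), 200, 10)
    colnames(x) <- paste0("IC", 1:10)
    y <- drop(x[, c(2, 5, 9)] %*% c(1, -0.8, 0.6)) + rnorm(200)
  })
  m <- stepwise_fit(x, y)
  expect_true(all(c("IC2", "IC5", "IC9") %in% m$ic_ids))
  expect_true(all(m$coefficients$ci_lo <= m$coefficients$B))
  expect_true(all(m$coefficients$ci_hi >= m$coefficients$B))
  # CIs agree with the t-based intervals of the final least-squares fit
  fit <- lm(y ~ x[, m$ic_ids])
  ci <- unname(confint(fit)[-1, ])
  expect_equal(unname(as.matrix(m$coefficients[, c("ci_lo", "ci_hi")])), ci,
               tolerance = 1e-10)
  expect_lt(m$model_p, 1e-10)
})

test_that("on orthogonal candidates stepwise equals marginal screening", {
  withr::with_seed(84, {
    q <- qr.Q(qr(matrix(rnorm(60 * 8), 60, 8)))
    colnames(q) <- paste0("IC", 1:8)
    y <- drop(q %*% c(3, 0, 2.5, 0, 0, 2, 0, 0)) + rnorm(60, sd = 0.8)
  })
  marg_p <- apply(q, 2, function(col) summary(lm(y ~ col))$coefficients[2, 4])
  m <- stepwise_fit(q, y)
  expect_setequal(m$ic_ids, names(marg_p)[marg_p <= 0.05])
})

test_that("stepwise refuses collinear entries and validates its arguments", {
  withr::with_seed(85, {
    x <- matrix(rnorm(30 * 3), 30, 3)
    x <- cbind(x, x[, 1])
    colnames(x) <- paste0("IC", 1:4)
    y <- x[, 1] + rnorm(30, sd = 0.3)
  })
  m <- stepwise_fit(x, y)
  # only one of the duplicated pair can be selected
  expect_lte(sum(c("IC1", "IC4") %in% m$ic_ids), 1)
  expect_error(stepwise_fit(x, y, alpha_enter = 0.2, alpha_remove = 0.1),
               "smaller")
  expect_error(stepwise_fit(x, c(y[-1], NA)), "missing")
  expect_error(stepwise_fit(x[1:2, ], y[1:2]), "more than 2")
})

test_that("domain models compose linearly into network maps", {
  withr::with_seed(86, {
    g <- orthonormal_maps(3, 300)
    rownames(g) <- c("IC14", "IC48", "IC61")
  })
  one <- structure(list(domain = "abstraction", ic_ids = "IC61",
                        coefficients = data.frame(ic_id = "IC61", B = -0.025),
                        generated = TRUE), class = "domain_model")
  cm <- compose_domain_network(one, g)
  expect_equal(cm$values, -0.025 * g["IC61", ], tolerance = 1e-12)

  two <- structure(list(domain = "naming", ic_ids = c("IC14", "IC48"),
                        coefficients = data.frame(ic_id = c("IC14", "IC48"),
                                                  B = c(0.4, -0.2)),
                        generated = TRUE), class = "domain_model")
  cm2 <- compose_domain_network(two, g)
  a <- structure(list(domain = "naming", ic_ids = "IC14",
                      coefficients = data.frame(ic_id = "IC14", B = 0.4),
                      generated = TRUE), class = "domain_model")
  b <- structure(list(domain = "naming", ic_ids = "IC48",
                      coefficients = data.frame(ic_id = "IC48", B = -0.2),
                      generated = TRUE), class = "domain_model")
  expect_equal(cm2$values,
               compose_domain_network(a, g)$values +
                 compose_domain_network(b, g)$values,
               tolerance = 1e-12)

  zero <- structure(list(domain = "x", ic_ids = "IC14",
                         coefficients = data.frame(ic_id = "IC14", B = 0),
                         generated = TRUE), class = "domain_model")
  expect_true(all(compose_domain_network(zero, g)$values == 0))

  none <- structure(list(domain = "delayed_recall", generated = FALSE),
                    class = "domain_model")
  expect_error(compose_domain_network(none, g), "not generated")
  expect_error(compose_domain_network(one, g[1:2, ]), "missing component")
})

test_that("hub detection counts shared memberships and orders deterministically", {
  mk <- function(domain, ids) {
    structure(list(domain = domain, ic_ids = ids, generated = TRUE),
              class = "domain_model")
  }
  models <- list(mk("a", c("IC5", "IC2")), mk("b", c("IC2", "IC9")),
                 mk("c", c("IC2", "IC9", "IC11")))
  hubs <- find_hubs(models)
  expect_equal(hubs$ic_id, c("IC2", "IC9"))
  expect_equal(hubs$n_domains, c(3L, 2L))
  expect_equal(hubs$domains[1], "a, b, c")

  disjoint <- list(mk("a", "IC1"), mk("b", "IC2"))
  expect_equal(nrow(find_hubs(disjoint)), 0)

  shared <- list(mk("a", c("IC7", "IC1")), mk("b", "IC7"), mk("c", "IC7"))
  expect_equal(find_hubs(shared)$ic_id[1], "IC7")

  not_gen <- structure(list(domain = "d", generated = FALSE),
                       class = "domain_model")
  expect_error(find_hubs(list(mk("a", "IC1"), not_gen)), "2 generated")
})

test_that("fitted models round-trip through the structured report", {
  withr::with_seed(87, {
    x <- matrix(rnorm(60 * 5), 60, 5)
    colnames(x) <- paste0("IC", 1:5)
    y <- x[, 2] - 0.5 * x[, 4] + rnorm(60, sd = 0.5)
  })
  m <- stepwise_fit(x, y, domain = "attention")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_models(list(attention = m), path)
  back <- read_domain_models(path)
  expect_equal(back$attention$ic_ids, m$ic_ids)
  expect_equal(back$attention$coefficients$B, m$coefficients$B,
               tolerance = 1e-6)
  expect_equal(back$attention$r2, m$r2, tolerance = 1e-6)
})

test_that("group comparisons flag shifts with the right sign and guard degenerate input", {
  withr::with_seed(88, {
    n1 <- 10; n2 <- 12
    sc <- rbind(matrix(rnorm(n1 * 2), n1, 2),
                matrix(rnorm(n2 * 2, mean = c(2, -2)[col(matrix(0, n2, 2))]),
                       n2, 2))
    colnames(sc) <- c("IC1", "IC2")
    groups <- c(rep("Ctr", n1), rep("PD", n2))
  })
  res <- compare_groups(sc, groups)
  # Ctr - PD: planted PD shift +2 on IC1, -2 on IC2
  expect_lt(res$t[res$ic_id == "IC1"], 0)
  expect_gt(res$t[res$ic_id == "IC2"], 0)
  expect_true(all(res$significant))
  expect_equal(res$df, rep(n1 + n2 - 2, 2))

  w <- compare_groups(sc, groups, variant = "welch")
  expect_true(all(w$df < n1 + n2 - 2))

  expect_error(compare_groups(sc, c(rep("Ctr", 1), rep("PD", n1 + n2 - 1))),
               "at least 2")
  const <- matrix(1, 8, 1)
  expect_error(compare_groups(const, rep(c("a", "b"), each = 4)),
               "zero variance")
})

test_that("summary-statistic t-tests agree exactly with raw-data t-tests", {
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 12)$t, 0)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 12)$p, 1)

  withr::with_seed(89, {
    for (variant in c("student", "welch")) {
      m1 <- 3.2; s1 <- 1.1; n1 <- 14; m2 <- 2.6; s2 <- 0.9; n2 <- 9
      x1 <- as.vector(scale(rnorm(n1))) * s1 + m1
      x2 <- as.vector(scale(rnorm(n2))) * s2 + m2
      tt <- t.test(x1, x2, var.equal = variant == "student")
      ss <- ttest_from_summary(m1, s1, n1, m2, s2, n2, variant)
      expect_equal(ss$t, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(ss$df, unname(tt$parameter), tolerance = 1e-10)
      expect_equal(ss$p, tt$p.value, tolerance = 1e-10)
      # swapping the groups flips t, keeps p
      sw <- ttest_from_summary(m2, s2, n2, m1, s1, n1, variant)
      expect_equal(sw$t, -ss$t)
      expect_equal(sw$p, ss$p)
    }
  })
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})
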