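test_that("a gross outlier is masked and the screen then converges", {
  set.seed(1)
  tab <- data.frame(y = c(rnorm(50), 10),
                    group = rep(c("case", "control"), length.out = 51))
  out <- remove_outliers(tab, "y")
  expect_equal(out$log$row, 51L)
  expect_true(is.na(out$table$y[51]))
  expect_equal(sum(is.na(out$table$y)), 1)
  # direct studentized-residual computation agrees that row 51 is extreme
  m <- lm(y ~ group, data = tab)
  expect_equal(which.max(abs(rstudent(m))), c(`51` = 51L))

  again <- remove_outliers(out$table, "y")
  expect_equal(nrow(again$log), 0)

  tight <- data.frame(y = rnorm(40, 100, 5))
  expect_equal(nrow(remove_outliers(tight, "y")$log), 0)
})

test_that("model choice follows Shapiro-Wilk screening", {
  set.seed(2)
  expect_equal(as.character(choose_model(rnorm(100))), "linear")
  expect_equal(as.character(choose_model(exp(rnorm(100)))), "gamma-glm")
  expect_warning(m <- choose_model(c(exp(rnorm(99)), -1)), "non-positive")
  expect_equal(as.character(m), "linear")
  expect_error(choose_model(c(1, 2)), "at least 3")
})

test_that("group contrasts report Wald t, p, and partial eta squared", {
  set.seed(3)
  base <- rnorm(40, 100, 10)
  tab <- data.frame(y = rep(base, 2),
                    group = rep(c("case", "control"), each = 40),
                    IQ = rnorm(80, 110, 12))
  res <- group_contrast(tab, "y", covariates = character(0),
                        model = "linear")
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$eta_p_sq, 0, tolerance = 1e-12)

  # with a real effect, matches lm run by hand
  tab$y <- tab$y + ifelse(tab$group == "case", 8, 0) + 0.1 * tab$IQ
  res2 <- group_contrast(tab, "y", covariates = "IQ", model = "linear")
  ref <- summary(lm(y ~ factor(group) + IQ, data = tab))$coefficients
  expect_equal(res2$t, ref[2, 3])
  expect_equal(res2$p, ref[2, 4])
  expect_equal(res2$eta_p_sq, ref[2, 3]^2 / (ref[2, 3]^2 + 77))

  # a duplicated covariate is refused on the condition-index rule
  tab$IQ2 <- tab$IQ
  expect_error(group_contrast(tab, "y", covariates = c("IQ", "IQ2")),
               "condition index")
})

test_that("gamma GLM route handles skewed positive responses", {
  set.seed(4)
  tab <- data.frame(y = exp(rnorm(100, 5, 0.6) +
                              rep(c(-0.7, 0), each = 50)),
                    group = rep(c("case", "control"), each = 50),
                    IQ = rnorm(100, 110, 12))
  res <- group_contrast(tab, "y", covariates = "IQ")
  expect_equal(res$model, "gamma-glm")
  expect_lt(res$p, 0.01)
  expect_gt(res$t, 0)        # control (2nd level) higher than case
})

test_that("the null rejection rate of the contrast is nominal", {
  set.seed(5)
  rej <- mean(replicate(400, {
    tab <- data.frame(y = rnorm(60),
                      group = rep(c("case", "control"), each = 30),
                      IQ = rnorm(60, 110, 12))
    group_contrast(tab, "y", covariates = "IQ", model = "linear")$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("pooled t reproduces printed group-table rows", {
  age <- pooled_t_from_summary(23.55, 4.88, 53, 24.90, 3.40, 58)
  expect_equal(round(as.numeric(age), 2), -1.70)
  expect_equal(attr(age, "df"), 109)

  audit <- pooled_t_from_summary(5.09, 4.64, 53, 5.05, 3.38, 58)
  expect_equal(round(as.numeric(audit), 2), 0.05)

  expect_equal(as.numeric(pooled_t_from_summary(5, 2, 10, 5, 2, 10)), 0)
  expect_equal(as.numeric(pooled_t_from_summary(5, 0, 10, 5, 0, 10)), 0)
  expect_error(pooled_t_from_summary(5, 0, 10, 6, 0, 10), "zero pooled")
})

test_that("partial eta squared matches its closed form and invariances", {
  expect_equal(round(partial_eta_squared(-5.34, 109), 2), 0.21)
  expect_equal(round(partial_eta_squared(-4.68, 109), 2), 0.17)
  expect_equal(partial_eta_squared(0, 50), 0)
  expect_equal(partial_eta_squared(-2.5, 80), partial_eta_squared(2.5, 80))
  ts <- seq(0.1, 6, by = 0.1)
  expect_true(all(diff(partial_eta_squared(ts, 100)) > 0))
  expect_error(partial_eta_squared(2, 0), "df")
})

test_that("condition index flags collinearity and matches an eigen oracle", {
  q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  expect_equal(condition_index(q)$index, 1, tolerance = 1e-8)
  expect_false(condition_index(q)$flagged)

  dup <- cbind(1, rnorm(20))
  dup <- cbind(dup, dup[, 2])
  ci <- condition_index(dup)
  expect_true(ci$flagged)
  expect_equal(ci$index, Inf)

  set.seed(6)
  X <- cbind(rnorm(30), rnorm(30))
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  ev <- eigen(t(Xs) %*% Xs)$values
  expect_equal(condition_index(X)$index, sqrt(max(ev) / min(ev)),
               tolerance = 1e-10)
})

test_that("Spearman network applies BH within each group family", {
  set.seed(7)
  n <- 40
  z <- rnorm(n)
  tab <- data.frame(group = rep("case", n),
                    a = z + rnorm(n, 0, 0.1),
                    b = z + rnorm(n, 0, 0.1),
                    c = rnorm(n), d = rnorm(n))
  ed <- spearman_fdr(tab, c("a", "b", "c", "d"))
  expect_equal(nrow(ed), 6)
  ab <- ed[ed$var_i == "a" & ed$var_j == "b", ]
  expect_gt(ab$rho, 0.9)
  expect_true(ab$kept)
  expect_true(all(ed$p_adj >= ed$p - 1e-12))
  expect_equal(ed$p_adj, bh_stepup(ed$p))

  mono <- data.frame(group = "case", x = 1:20, y = (1:20)^3)
  em <- spearman_fdr(mono, c("x", "y"))
  expect_equal(em$rho, 1)

  # constant variable excluded from the FDR family
  tab$k <- 5
  ek <- spearman_fdr(tab, c("a", "b", "k"))
  expect_true(all(is.na(ek$p_adj[ek$var_i == "k" | ek$var_j == "k"])))
  fam <- is.finite(ek$p)
  expect_equal(ek$p_adj[fam], bh_stepup(ek$p[fam]))
})

test_that("independent variables rarely survive the FDR screen", {
  set.seed(8)
  fdp <- replicate(100, {
    tab <- data.frame(group = "g",
                      matrix(rnorm(25 * 5), 25, 5,
                             dimnames = list(NULL, letters[1:5])))
    mean(spearman_fdr(tab, letters[1:5])$kept)
  })
  expect_lte(mean(fdp), 0.05 + 0.03)
})
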