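# Oracle: stats::aov with Error(subject/(...)) strata provides an independent
# sums-of-squares decomposition for balanced within-subject designs.

random_within_table <- function(n_sub = 16, levels = list(session = c("pre", "post"),
                                                          condition = c("a", "b", "c"),
                                                          electrode = c("C3", "C4", "Cz")),
                                seed = 1) {
  set.seed(seed)
  g <- expand.grid(c(list(subject = sprintf("s%02d", 1:n_sub)), levels),
                   stringsAsFactors = FALSE)
  g$msi <- rnorm(nrow(g), sd = 0.2)
  g
}

aov_oracle <- function(d, factors) {
  for (f in c("subject", factors)) d[[f]] <- factor(d[[f]])
  rhs <- paste(factors, collapse = "*")
  fml <- stats::as.formula(sprintf("msi ~ %s + Error(subject/(%s))", rhs, rhs))
  fit <- summary(stats::aov(fml, data = d))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    for (i in seq_along(eff)) {
      if (eff[i] == "Residuals") next
      out[[gsub(" ", "", eff[i])]] <-
        list(ss = tab$`Sum Sq`[i], df1 = tab$Df[i],
             F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
             ss_err = tab$`Sum Sq`[eff == "Residuals"],
             df2 = tab$Df[eff == "Residuals"])
    }
  }
  out
}

test_that("rm_anova matches the aov stratum oracle on a random 16x2x3x3 table", {
  d <- random_within_table(seed = 42)
  res <- rm_anova(d, dv = "msi", subject = "subject",
                  factors = c("session", "condition", "electrode"))
  orc <- aov_oracle(d, c("session", "condition", "electrode"))
  expect_equal(nrow(res), 7)                       # 3 mains + 3 two-way + 1 three-way
  for (i in seq_len(nrow(res))) {
    o <- orc[[res$effect[i]]]
    expect_false(is.null(o))
    expect_equal(res$ss[i], o$ss, tolerance = 1e-8)
    expect_equal(res$ss_error[i], o$ss_err, tolerance = 1e-8)
    expect_equal(res$F[i], o$F, tolerance = 1e-8)
    expect_equal(res$p[i], o$p, tolerance = 1e-8)
    expect_equal(res$df1[i], o$df1)
    expect_equal(res$df2[i], o$df2)
  }
  # printed df for 3-level within factors with n = 16
  cond <- res[res$effect == "condition", ]
  expect_equal(c(cond$df1, cond$df2), c(2, 30))
  # epsilon bounds and partial eta^2 identity
  expect_true(all(res$gg_epsilon <= 1 + 1e-12))
  expect_true(all(res$gg_epsilon >= 1 / res$df1 - 1e-12))
  expect_equal(res$peta2, res$ss / (res$ss + res$ss_error))
})

test_that("total sum of squares decomposes exactly (balanced design)", {
  d <- random_within_table(n_sub = 8, seed = 7)
  res <- rm_anova(d, dv = "msi", subject = "subject",
                  factors = c("session", "condition", "electrode"))
  total <- attr(res, "ss_total")
  parts <- sum(res$ss) + sum(res$ss_error) + attr(res, "ss_subject")
  expect_equal(parts, total, tolerance = 1e-8 * total)
})

test_that("null effect structure gives F ~ 0 and missing cells error", {
  d <- random_within_table(n_sub = 10, seed = 3,
                           levels = list(condition = c("a", "b", "c"),
                                         electrode = c("C3", "C4", "Cz")))
  # wipe between-condition differences while keeping subject noise
  m <- tapply(d$msi, d$subject, mean)
  d$msi <- m[d$subject] + 0
  set.seed(9); d$msi <- d$msi + rnorm(nrow(d), sd = 1e-8)
  res <- rm_anova(d, dv = "msi", subject = "subject",
                  factors = c("condition",  "electrode"))
  expect_lt(res$F[res$effect == "condition"], 10)  # no real effect signal
  expect_error(rm_anova(d[-1, ], dv = "msi", subject = "subject",
                        factors = c("condition", "electrode")),
               class = "incomplete_design")
})

test_that("GG epsilon detects sphericity violations", {
  # build a 3-level factor whose contrast covariance is highly non-spherical
  set.seed(5)
  n <- 20
  base <- rnorm(n)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n), each = 3),
                  cond = rep(c("a", "b", "c"), n),
                  msi = NA_real_)
  for (i in 1:n) {
    idx <- (i - 1) * 3 + 1:3
    d$msi[idx] <- c(base[i] + rnorm(1, sd = 2), base[i] + rnorm(1, sd = 0.01),
                    base[i] + rnorm(1, sd = 0.01))
  }
  res <- rm_anova(d, dv = "msi", subject = "subject", factors = "cond")
  expect_lt(res$gg_epsilon, 0.8)
  expect_gte(res$gg_epsilon, 1 / res$df1)
})
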