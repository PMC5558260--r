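test_that("measurement table enforces the 18-condition design", {
  tab <- simulate_dose_table()                 # 11 F + 12 M defaults
  expect_identical(nrow(tab), 414L)            # 23 x 18
  expect_equal(tab$log_dose, log(tab$dose))
  expect_identical(levels(tab$configuration),
                   c("ring", "bi_cranial", "non_cephalic"))
  # missing cell
  expect_error(assemble_measurements(as.data.frame(tab)[-1, 1:6]),
               "missing cells")
  # non-positive dose
  bad <- as.data.frame(tab)[1:6]
  bad$dose[5] <- 0
  expect_error(assemble_measurements(bad), "non-positive")
  # duplicated cell
  dup <- rbind(as.data.frame(tab)[1:6], as.data.frame(tab)[1, 1:6])
  expect_error(assemble_measurements(dup), "duplicated")
})

test_that("intensity coefficients are exactly the doubling law", {
  tab <- simulate_dose_table(seed = 2L)
  fit <- fit_mixed_model(tab)
  expect_equal(anova_term(fit, "intensity1")$estimate, log(2),
               tolerance = 1e-8)
  expect_equal(anova_term(fit, "intensity2")$estimate, log(4),
               tolerance = 1e-8)
  expect_equal(anova_term(fit, "intensity2")$exp_coef, 4,
               tolerance = 1e-7)
  # CI brackets the coefficient, exp column consistent
  co <- fit$coefficients
  expect_true(all(co$ci_lo <= co$estimate & co$estimate <= co$ci_hi))
  expect_equal(co$exp_coef, exp(co$estimate))
})

test_that("balanced-design fixed effects equal cell-mean contrasts", {
  tab <- simulate_dose_table(seed = 8L)
  fit <- fit_mixed_model(tab)
  mm <- function(sel) mean(tab$log_dose[sel])
  contrasts <- c(
    configurationbi_cranial = mm(tab$configuration == "bi_cranial") -
      mm(tab$configuration == "ring"),
    configurationnon_cephalic = mm(tab$configuration == "non_cephalic") -
      mm(tab$configuration == "ring"),
    sexmale = mm(tab$sex == "male") - mm(tab$sex == "female"),
    siteF3 = mm(tab$site == "F3") - mm(tab$site == "C3"),
    intensity1 = mm(tab$intensity == "1") - mm(tab$intensity == "0.5"),
    intensity2 = mm(tab$intensity == "2") - mm(tab$intensity == "0.5"))
  for (term in names(contrasts))
    expect_equal(anova_term(fit, term)$estimate, unname(contrasts[term]),
                 tolerance = 1e-8)
})

test_that("cloned sex groups give a null sex effect", {
  tab <- simulate_dose_table(n_female = 6L, n_male = 6L,
                             effects = list(mu = 0.5, bi_cranial = 1,
                                            non_cephalic = 2.3, male = 0.7,
                                            F3 = 0.16), seed = 3L)
  half <- as.data.frame(tab)[tab$sex == "female", 1:6]
  clone <- half
  clone$sex <- "male"
  clone$subject <- sub("^F", "M", clone$subject)
  fit <- fit_mixed_model(assemble_measurements(rbind(half, clone)))
  expect_lt(abs(anova_term(fit, "sexmale")$estimate), 1e-8)
})

test_that("a known sex effect is recovered without bias (short run)", {
  est <- vapply(1:12, function(r) {
    tab <- simulate_dose_table(effects = list(mu = 0.5, bi_cranial = 1,
                                              non_cephalic = 2.3,
                                              male = log(2), F3 = 0.16),
                               subject_sd = 0.5, resid_sd = 0.3, seed = r)
    anova_term(fit_mixed_model(tab), "sexmale")$estimate
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(2)), 4 * se + 0.05)
})

test_that("interaction model returns the Table-3 term set", {
  tab <- simulate_dose_table(seed = 10L)
  fit <- fit_mixed_model(tab, interactions = TRUE)
  terms <- fit$coefficients$term
  expect_true(all(c("configurationbi_cranial:siteF3",
                    "configurationnon_cephalic:siteF3",
                    "configurationbi_cranial:sexmale",
                    "configurationnon_cephalic:sexmale",
                    "sexmale:siteF3") %in% terms))
})

test_that("cross-site correlation behaves like Pearson's r", {
  tab <- as.data.frame(simulate_dose_table(seed = 4L))[1:6]
  # copy C3 doses onto F3 -> r = 1
  for (cf in levels(factor(tab$configuration))) {
    sel_c3 <- tab$configuration == cf & tab$site == "C3"
    sel_f3 <- tab$configuration == cf & tab$site == "F3"
    tab$dose[sel_f3] <- tab$dose[sel_c3]
  }
  r1 <- cross_site_correlation(assemble_measurements(tab))
  expect_equal(r1$r, rep(1, 3), tolerance = 1e-12)
  # affine rescaling of one site leaves r unchanged
  tab2 <- tab
  tab2$dose[tab2$site == "F3"] <- 3 * tab2$dose[tab2$site == "F3"] + 0
  r2 <- cross_site_correlation(assemble_measurements(tab2))
  expect_equal(r2$r, r1$r, tolerance = 1e-12)
  # independent site effects -> r near zero on average
  set.seed(99)
  rs <- replicate(40, {
    d <- expand.grid(configuration = "ring", site = c("C3", "F3"),
                     intensity = c(0.5, 1, 2),
                     subject = sprintf("S%02d", 1:12),
                     stringsAsFactors = FALSE)
    base <- matrix(exp(rnorm(24, 1, 0.6)), nrow = 2)  # site x subject
    d$dose <- base[cbind(match(d$site, c("C3", "F3")),
                         match(d$subject, unique(d$subject)))] *
      (d$intensity / 0.5)
    c3 <- d$dose[d$site == "C3" & d$intensity == 2]
    f3 <- d$dose[d$site == "F3" & d$intensity == 2]
    cor(c3, f3)
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("cell summaries satisfy the aggregation identities", {
  tab <- simulate_dose_table(seed = 6L)
  cells <- summarize_cells(tab)
  expect_identical(sum(cells$sex %in% c("female", "male")), 36L)
  # overall mean = subject-count-weighted mean of sex-stratified means
  f <- cells[cells$sex == "female", ]
  m <- cells[cells$sex == "male", ]
  o <- cells[cells$sex == "overall", ]
  key <- function(d) paste(d$configuration, d$site, d$intensity)
  m <- m[match(key(f), key(m)), ]
  o <- o[match(key(f), key(o)), ]
  expect_equal(o$mean, (f$mean * f$n + m$mean * m$n) / (f$n + m$n),
               tolerance = 1e-12)
  # single subject: zero SD in every cell
  one <- simulate_dose_table(n_female = 1L, n_male = 0L, seed = 2L)
  class(one) <- c("measurement_table", "data.frame")
  cells1 <- summarize_cells(one)
  expect_true(all(cells1$sd[cells1$sex == "female"] == 0))
})

test_that("Q-Q diagnostics separate log-normal from normal residuals", {
  set.seed(11)
  qp <- qq_pairs(rnorm(400))
  fit <- lm(sample ~ theoretical, data = qp)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  expect_lt(abs(unname(coef(fit)[1])), 0.05)
  # identical residual vectors give identical pairs
  x <- rnorm(50)
  expect_identical(qq_pairs(x), qq_pairs(x))
  # log transform straightens a log-normal dose world
  tab <- simulate_dose_table(subject_sd = 0.4, resid_sd = 0.6, seed = 12L)
  qq <- qq_diagnostics(tab)
  maxdev <- vapply(split(qq, qq$transform), function(d)
    max(abs(d$sample - d$theoretical)), numeric(1))
  expect_lt(maxdev[["log"]], maxdev[["raw"]])
})
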