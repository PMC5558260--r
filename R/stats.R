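# Cohort-level statistics: the 18-condition measurement table and the
# mixed-effects ANOVA of log current density.

CONFIG_LEVELS <- c("ring", "bi_cranial", "non_cephalic")
SITE_LEVELS <- c("C3", "F3")
INTENSITY_LEVELS <- c(0.5, 1.0, 2.0)

#' Assemble the long measurement table
#'
#' Validates the fully crossed design (3 configurations x 2 sites x 3
#' intensities = 18 rows per subject), rejects non-positive doses, and
#' appends the natural-log dose column. Factors are released with the
#' modelled reference levels first: ring configuration, 0.5 mA, C3,
#' female.
#'
#' @param doses data frame with columns `subject`, `sex`,
#'   `configuration`, `site`, `intensity`, `dose` (uA/cm^2).
#' @return a validated `measurement_table` data frame with `log_dose`.
#' @export
assemble_measurements <- function(doses) {
  need <- c("subject", "sex", "configuration", "site", "intensity", "dose")
  miss <- setdiff(need, names(doses))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- doses$dose <= 0 | !is.finite(doses$dose)
  if (any(bad))
    stop("non-positive or non-finite dose for: ",
         paste(utils::head(paste0(doses$subject[bad], "/",
                                  doses$configuration[bad], "/",
                                  doses$site[bad], "/",
                                  doses$intensity[bad]), 5L),
               collapse = "; "))
  full <- expand.grid(configuration = CONFIG_LEVELS, site = SITE_LEVELS,
                      intensity = INTENSITY_LEVELS,
                      subject = unique(doses$subject),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$configuration, d$site, d$intensity)
  missing_cells <- setdiff(key(full), key(doses))
  if (length(missing_cells) > 0L)
    stop("incomplete design; missing cells: ",
         paste(utils::head(missing_cells, 5L), collapse = "; "),
         if (length(missing_cells) > 5L) " ...")
  if (anyDuplicated(key(doses)))
    stop("duplicated design cells in dose table")
  out <- doses
  out$configuration <- factor(out$configuration, levels = CONFIG_LEVELS)
  out$site <- factor(out$site, levels = SITE_LEVELS)
  out$intensity <- factor(out$intensity, levels = INTENSITY_LEVELS)
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out$subject <- factor(out$subject)
  out$log_dose <- log(out$dose)
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Fit the mixed-effects ANOVA of log current density
#'
#' Linear mixed model (REML via lme4) of natural-log dose with fixed
#' factors configuration, sex, site and intensity (3-level factor) and a
#' random intercept per subject. Reference levels: ring, female, C3,
#' 0.5 mA. Wald 95% confidence intervals and normal-approximation
#' p-values; coefficients are also reported exponentiated (fold-change
#' versus reference).
#'
#' @param table a [assemble_measurements()] result.
#' @param interactions add the three two-way interactions
#'   configuration:site, configuration:sex and site:sex.
#' @return object of class `tes_anova`: `coefficients` data frame
#'   (`term`, `estimate`, `ci_lo`, `ci_hi`, `p_value`, `exp_coef`),
#'   `varcomp` (subject and residual variance), `model` (the lmerMod).
#' @export
fit_mixed_model <- function(table, interactions = FALSE) {
  stopifnot(inherits(table, "measurement_table"))
  if (length(unique(table$subject[table$sex == "female"])) < 2L ||
      length(unique(table$subject[table$sex == "male"])) < 2L)
    stop("need at least 2 subjects per sex to estimate the sex term")
  rhs <- "configuration + sex + site + intensity"
  if (interactions)
    rhs <- paste(rhs, "+ configuration:site + configuration:sex",
                 "+ site:sex")
  fml <- stats::as.formula(paste("log_dose ~", rhs, "+ (1 | subject)"))
  fit <- lme4::lmer(fml, data = table, REML = TRUE)
  if (interactions && lme4::isSingular(fit, tol = 1e-5))
    stop("singular fit with interactions; refit with the ",
         "main-effects-only model (interactions = FALSE)")
  est <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  z <- est / se
  ci <- stats::qnorm(0.975) * se
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      ci_lo = unname(est - ci), ci_hi = unname(est + ci),
                      p_value = unname(2 * stats::pnorm(-abs(z))),
                      exp_coef = unname(exp(est)))
  structure(list(coefficients = coefs,
                 varcomp = c(subject = vc$vcov[vc$grp == "subject"],
                             residual = vc$vcov[vc$grp == "Residual"]),
                 model = fit, interactions = interactions),
            class = "tes_anova")
}

#' @export
print.tes_anova <- function(x, ...) {
  cat("Mixed-effects ANOVA of log current density",
      if (x$interactions) "(with two-way interactions)" else
        "(main effects)", "\n")
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat(sprintf("Variance components: subject %.4g, residual %.4g\n",
              x$varcomp[["subject"]], x$varcomp[["residual"]]))
  invisible(x)
}

#' Extract one coefficient row by term name
#' @param fit a `tes_anova`.
#' @param term coefficient name, e.g. `"intensity2"`.
#' @return one-row data frame.
#' @export
anova_term <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L)
    stop("term '", term, "' not found; available: ",
         paste(fit$coefficients$term, collapse = ", "))
  row
}

#' Cross-site correlation of dose between C3 and F3
#'
#' Pearson correlation across subjects of the C3 versus F3 dose, per
#' configuration at one intensity (default 2 mA).
#'
#' @param table a [assemble_measurements()] result.
#' @param intensity intensity (mA) at which to correlate.
#' @return data frame with `configuration`, `r`, `n`, plus the paired
#'   doses as attribute `"scatter"`.
#' @export
cross_site_correlation <- function(table, intensity = 2.0) {
  stopifnot(inherits(table, "measurement_table"))
  sub <- table[table$intensity == intensity, ]
  if (nrow(sub) == 0L) stop("no rows at intensity ", intensity)
  scat <- list()
  out <- lapply(CONFIG_LEVELS, function(cf) {
    c3 <- sub[sub$configuration == cf & sub$site == "C3", ]
    f3 <- sub[sub$configuration == cf & sub$site == "F3", ]
    c3 <- c3[order(c3$subject), ]
    f3 <- f3[order(f3$subject), ]
    if (nrow(c3) < 3L) stop("fewer than 3 subjects for configuration ", cf)
    if (!identical(as.character(c3$subject), as.character(f3$subject)))
      stop("C3/F3 subject sets differ for configuration ", cf)
    scat[[cf]] <<- data.frame(configuration = cf, subject = c3$subject,
                              dose_C3 = c3$dose, dose_F3 = f3$dose)
    data.frame(configuration = cf,
               r = stats::cor(c3$dose, f3$dose), n = nrow(c3))
  })
  res <- do.call(rbind, out)
  attr(res, "scatter") <- do.call(rbind, scat)
  res
}

#' Cell means and SDs of untransformed dose
#'
#' Mean (SD) of dose per sex x configuration x site x intensity, plus
#' pooled `"overall"` rows, mirroring a descriptive summary grid.
#'
#' @param table a [assemble_measurements()] result.
#' @return data frame with `sex` (female/male/overall), `configuration`,
#'   `site`, `intensity`, `mean`, `sd`, `n`.
#' @export
summarize_cells <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  agg <- function(d, sexlab) {
    a <- stats::aggregate(dose ~ configuration + site + intensity, d,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1L)
                                          stats::sd(v) else 0,
                                        n = length(v)))
    data.frame(sex = sexlab, a[1:3], mean = a$dose[, "mean"],
               sd = a$dose[, "sd"], n = a$dose[, "n"])
  }
  strata <- lapply(intersect(c("female", "male"), unique(table$sex)),
                   function(s) agg(table[table$sex == s, ], s))
  do.call(rbind, c(strata, list(agg(table, "overall"))))
}

#' Normal Q-Q pairs for a residual vector
#' @param x numeric vector.
#' @return data frame `theoretical`, `sample` (standardized, sorted).
#' @export
qq_pairs <- function(x) {
  n <- length(x)
  s <- (x - mean(x)) / stats::sd(x)
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
             sample = sort(s))
}

#' Residual Q-Q diagnostics across dose transforms
#'
#' Fits the fixed-effects design (configuration + sex + site + intensity +
#' subject) to the raw, natural-log and square-root transformed dose and
#' returns the normal Q-Q pairs of each residual set, for deciding which
#' transform straightens the tails.
#'
#' @param table a [assemble_measurements()] result.
#' @return long data frame: `transform` (raw/log/sqrt), `theoretical`,
#'   `sample`.
#' @export
qq_diagnostics <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  out <- lapply(c(raw = "raw", log = "log", sqrt = "sqrt"), function(tr) {
    y <- switch(tr, raw = table$dose, log = log(table$dose),
                sqrt = sqrt(table$dose))
    d <- cbind(table, .y = y)
    fit <- stats::lm(.y ~ configuration + sex + site + intensity + subject,
                     data = d)
    cbind(transform = tr, qq_pairs(stats::residuals(fit)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
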