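#' Fit the half-sib trial mixed model by REML
#'
#' Fits the multi-location, multi-season, multi-year HS family trial model:
#' fixed location, season and year main effects; random family,
#' family-by-location, family-by-season and family-by-year effects;
#' optionally random replicate (within location-season-year), row (within
#' replicate) and column (within row) effects; and a residual. Estimation is
#' REML via [lme4::lmer()] with tight convergence tolerances; variance
#' components are bounded at zero.
#'
#' @param data a data frame of plot records with columns `family`,
#'   `location`, `season`, `year`, `rep`, `value`, and optionally `row`,
#'   `col`. Unbalanced (missing-cell) data are accepted.
#' @param terms character vector of random terms to fit, a subset of
#'   `c("family", "family:location", "family:season", "family:year", "rep",
#'   "row", "col")`. `rep` is nested as replicate within (location, season,
#'   year) and `row`/`col` as row and column within replicate, encoded by
#'   compound keys (a column-within-row effect is confounded with the plot
#'   residual, so columns enter at the replicate level).
#' @param tol convergence tolerance passed to the bobyqa optimizer
#'   (`rhoend`).
#' @param polish run an extra derivative-free (Nelder-Mead) refinement of
#'   the REML optimum followed by a tight local restart. With `polish =
#'   TRUE` balanced complete data reproduce the closed-form ANOVA
#'   estimators to ~1e-6 relative; the default fit stops at ~1e-5, which is
#'   far below the statistical uncertainty of the estimates.
#' @return An object of class `hs_varcomp`: variance component estimates,
#'   fixed effects, family BLUP effects, overall mean, convergence flag,
#'   REML log-likelihood and the underlying `lmerMod` fit.
#' @examples
#' spec <- mock_trial_spec(
#'   design = trial_design(2, 3, 2, 2, n_families = 40),
#'   components = variance_components(14170, 2222, 13406, 38511, 221768),
#'   mean = 3262, seed = 1)
#' fit <- fit_trial_reml(generate_trial(spec))
#' fit
#' @export
fit_trial_reml <- function(data,
                           terms = c("family", "family:location",
                                     "family:season", "family:year",
                                     "rep", "row", "col"),
                           tol = 1e-10, polish = FALSE) {
  all_terms <- c("family", "family:location", "family:season", "family:year",
                 "rep", "row", "col")
  terms <- match.arg(terms, all_terms, several.ok = TRUE)
  req <- c("family", "location", "season", "year", "rep", "value")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(data$family)) < 2) stop("need at least 2 families")
  if (any(!is.finite(data$value))) stop("non-finite responses")

  d <- data
  d$family <- factor(d$family)
  d$location <- factor(d$location)
  d$season <- factor(d$season)
  d$year <- factor(d$year)
  # nested blocking keys (replicate within l:s:y, rows/cols within rep)
  d$.rep <- interaction(d$location, d$season, d$year, d$rep, drop = TRUE)
  if (all(c("row", "col") %in% names(data))) {
    d$.row <- interaction(d$.rep, data$row, drop = TRUE)
    d$.col <- interaction(d$.rep, data$col, drop = TRUE)
  } else {
    terms <- setdiff(terms, c("row", "col"))
  }

  re <- c(family = "(1 | family)",
          `family:location` = "(1 | family:location)",
          `family:season` = "(1 | family:season)",
          `family:year` = "(1 | family:year)",
          rep = "(1 | .rep)", row = "(1 | .row)", col = "(1 | .col)")
  form <- stats::as.formula(paste(
    "value ~ location + season + year +",
    paste(re[terms], collapse = " + ")))

  ctrl <- function(rhobeg, rhoend) lme4::lmerControl(
    optimizer = "bobyqa", calc.derivs = FALSE,
    optCtrl = list(rhobeg = rhobeg, rhoend = rhoend),
    check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = d, REML = TRUE, control = ctrl(2e-3, tol))
  if (polish) {
    dv <- lme4::lmer(form, data = d, REML = TRUE, devFunOnly = TRUE)
    o <- stats::optim(lme4::getME(fit, "theta"), dv,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 2000))
    fit <- lme4::lmer(form, data = d, REML = TRUE, start = o$par,
                      control = ctrl(1e-7, 1e-13))
  }
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    fit@optinfo$conv$opt == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- setNames(vc$vcov, vc$grp)
  key <- c(family = "family", `family:location` = "family:location",
           `family:season` = "family:season", `family:year` = "family:year",
           rep = ".rep", row = ".row", col = ".col")
  comps <- setNames(numeric(length(terms) + 1), c(terms, "residual"))
  for (t in terms) comps[[t]] <- unname(est[[key[[t]]]])
  comps[["residual"]] <- unname(est[["Residual"]])

  fe <- lme4::fixef(fit)
  # overall mean with sum-to-zero averaging over fixed-effect levels
  X <- stats::model.matrix(fit)
  mu <- as.numeric(colMeans(X) %*% fe)
  blup <- lme4::ranef(fit)$family[["(Intercept)"]]
  names(blup) <- rownames(lme4::ranef(fit)$family)

  structure(list(components = comps, fixef = fe, overall_mean = mu,
                 blup = blup, converged = converged,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d), n_families = nlevels(d$family),
                 fit = fit),
            class = "hs_varcomp")
}

#' @export
print.hs_varcomp <- function(x, ...) {
  cat(sprintf("REML fit of HS trial model: %d records, %d families%s\n",
              x$n_obs, x$n_families,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  REML log-likelihood: %.2f\n", x$logLik))
  cat("  Variance components:\n")
  for (nm in names(x$components))
    cat(sprintf("    %-16s %12.1f\n", nm, x$components[[nm]]))
  invisible(x)
}

#' @export
summary.hs_varcomp <- function(object, design = NULL, ...) {
  out <- list(components = object$components,
              overall_mean = object$overall_mean,
              converged = object$converged,
              blup_range = range(family_blups(object)))
  if (!is.null(design)) {
    vc <- as_variance_components(object)
    out$heritability <- heritability_family_mean(vc, design)
    out$family_mean_sd <- family_mean_sd(vc, design)
  }
  class(out) <- "summary.hs_varcomp"
  out
}

#' @export
print.summary.hs_varcomp <- function(x, ...) {
  cat("HS trial REML summary\n")
  cat(sprintf("  overall mean: %.1f\n", x$overall_mean))
  for (nm in names(x$components))
    cat(sprintf("  %-16s %12.1f\n", nm, x$components[[nm]]))
  if (!is.null(x$heritability))
    cat(sprintf("  family-mean h2: %.3f (sigma_PF %.2f)\n",
                x$heritability, x$family_mean_sd))
  invisible(x)
}

#' @export
coef.hs_varcomp <- function(object, ...) object$components

#' Shrunken family means (BLUP-based)
#'
#' Overall mean plus the BLUP of each family effect. BLUPs are shrunken
#' towards the overall mean relative to raw family means, in proportion to
#' the family-mean reliability.
#'
#' @param fit an `hs_varcomp` object from [fit_trial_reml()].
#' @return Named numeric vector of shrunken family means (trait units).
#' @export
family_blups <- function(fit) {
  stopifnot(inherits(fit, "hs_varcomp"))
  fit$overall_mean + fit$blup
}

#' Map a REML fit onto engine variance components
#'
#' Copies the family, family-by-location, family-by-season, family-by-year
#' and residual estimates into a [variance_components()] object for the
#' deterministic gain engine. Refuses unconverged fits.
#'
#' @param fit an `hs_varcomp` object.
#' @return A [variance_components()] object.
#' @export
as_variance_components <- function(fit) {
  stopifnot(inherits(fit, "hs_varcomp"))
  if (!fit$converged)
    stop("REML fit did not converge; refusing to extract components")
  cp <- fit$components
  need <- c("family", "family:location", "family:season", "family:year",
            "residual")
  if (!all(need %in% names(cp)))
    stop("fit lacks required components: ",
         paste(setdiff(need, names(cp)), collapse = ", "))
  variance_components(fam_var = cp[["family"]],
                      fam_x_year = cp[["family:year"]],
                      fam_x_season = cp[["family:season"]],
                      fam_x_location = cp[["family:location"]],
                      residual = cp[["residual"]])
}

#' Closed-form ANOVA (expected mean squares) variance components
#'
#' Method-of-moments estimators for balanced complete HS trial data, from
#' the sequential ANOVA mean squares. Used as an independent check on the
#' REML fit: on balanced data with interior solutions the two coincide.
#'
#' @param data balanced complete plot records (see [fit_trial_reml()]).
#' @return Named vector: family, family:location, family:season,
#'   family:year, residual.
#' @export
anova_components <- function(data) {
  d <- data
  for (nm in c("family", "location", "season", "year"))
    d[[nm]] <- factor(d[[nm]])
  nl <- nlevels(d$location); ns <- nlevels(d$season); ny <- nlevels(d$year)
  nr <- nrow(d) / (nlevels(d$family) * nl * ns * ny)
  if (abs(nr - round(nr)) > 1e-9) stop("data are not balanced")
  a <- anova(aov(value ~ location + season + year + family +
                   family:location + family:season + family:year, d))
  ms <- setNames(a[["Mean Sq"]], rownames(a))
  s2e <- ms[["Residuals"]]
  s2fl <- (ms[["location:family"]] - s2e) / (ns * ny * nr)
  s2fs <- (ms[["season:family"]] - s2e) / (nl * ny * nr)
  s2fy <- (ms[["year:family"]] - s2e) / (nl * ns * nr)
  s2f <- (ms[["family"]] - s2e - ns * ny * nr * s2fl - nl * ny * nr * s2fs -
            nl * ns * nr * s2fy) / (nl * ns * ny * nr)
  c(family = s2f, `family:location` = s2fl, `family:season` = s2fs,
    `family:year` = s2fy, residual = s2e)
}
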