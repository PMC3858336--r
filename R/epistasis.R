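#' Design mapping from dataset genotype labels to the four analysis roles
#'
#' The interaction analysis uses four genotype roles: `WT0` (wild type),
#' `CM1` (c-Myb heterozygous null), `CP2` (CBP/p300 KIX double
#' heterozygote) and `TH3` (triple heterozygote).  Datasets may carry
#' arbitrary genotype labels; the design maps each role to its label.
#'
#' @param WT0,CM1,CP2,TH3 genotype labels in the dataset assigned to each
#'   role; defaults are the role names themselves.
#' @return named character vector of class `epistasis_design`.
#' @export
epistasis_design <- function(WT0 = "WT0", CM1 = "CM1",
                             CP2 = "CP2", TH3 = "TH3") {
  d <- c(WT0 = WT0, CM1 = CM1, CP2 = CP2, TH3 = TH3)
  if (anyDuplicated(d)) {
    stop("the four roles must map to distinct genotype labels", call. = FALSE)
  }
  class(d) <- "epistasis_design"
  d
}

#' Natural-log transform of one phenotype
#'
#' Blood counts are log transformed to stabilise their variance; the
#' interaction statistic is then a contrast of log means.  Any value <= 0
#' is rejected (the offending animals are named) unless a positive
#' `offset` is supplied, which is added to every value first.
#'
#' @param dataset a `blood_counts` data frame (or any data frame with an
#'   `animal_id` column and a numeric phenotype column).
#' @param phenotype name of the phenotype column.
#' @param offset optional constant added before taking logs (default 0,
#'   i.e. off).
#' @return numeric vector of natural-log values with attributes
#'   `log_base = "e"` and `offset`.
#' @export
log_transform <- function(dataset, phenotype, offset = 0) {
  if (!phenotype %in% names(dataset)) {
    stop("phenotype column not found: ", phenotype, call. = FALSE)
  }
  y <- dataset[[phenotype]] + offset
  if (any(y <= 0)) {
    bad <- dataset$animal_id[y <= 0]
    stop("non-positive ", phenotype, " value for animal(s): ",
         paste(bad, collapse = ", "),
         " (supply a positive offset to proceed)", call. = FALSE)
  }
  structure(log(y), log_base = "e", offset = offset)
}

#' Fit the per-genotype model for one phenotype
#'
#' Fits, by REML, `log(count) ~ 0 + role + (1 | experiment)` — genotype
#' means with a random experiment intercept absorbing batch-to-batch
#' machine drift.  With a single experiment, or with
#' `batch_as_random = FALSE`, the model reduces to fixed-effects group
#' means with a pooled residual variance.  A batch variance estimated at
#' the boundary (zero) is reported as a fixed-effects-equivalent fit with
#' a warning, not an error.
#'
#' @param dataset a `blood_counts` data frame.
#' @param phenotype phenotype column to analyse.
#' @param design an [epistasis_design()] mapping roles to genotype labels.
#' @param batch_as_random treat `experiment_id` as a random intercept
#'   (default `TRUE`).
#' @param covariates optional character vector of extra fixed covariates
#'   (e.g. `"strain"`, `"age_months"`); excluded by default.
#' @param offset passed to [log_transform()].
#' @return an object of class `genotype_fit`: list with `phenotype`,
#'   `means` (named log-scale genotype means for WT0/CM1/CP2/TH3), `vcov`
#'   (their covariance), `sigma_b2`, `sigma_e2`, `flavor`
#'   (`"mixed"`/`"fixed"`), `n` (animals per role).
#' @export
fit_genotype_model <- function(dataset, phenotype,
                               design = epistasis_design(),
                               batch_as_random = TRUE,
                               covariates = NULL,
                               offset = 0) {
  roles <- names(unclass(design))
  label2role <- stats::setNames(roles, unclass(design))
  keep <- dataset$genotype %in% unclass(design)
  d <- dataset[keep, , drop = FALSE]
  role <- factor(label2role[d$genotype], levels = roles)
  n_role <- table(role)
  if (any(n_role < 2)) {
    stop("role(s) with fewer than 2 animals: ",
         paste(names(n_role)[n_role < 2], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(logy = log_transform(d, phenotype, offset = offset),
                   role = role,
                   experiment_id = factor(d$experiment_id))
  for (cv in covariates) df[[cv]] <- d[[cv]]
  n_expt <- nlevels(df$experiment_id)

  fixed_rhs <- paste(c("0 + role", covariates), collapse = " + ")
  use_mixed <- batch_as_random && n_expt >= 2
  if (use_mixed) {
    fml <- stats::as.formula(paste("logy ~", fixed_rhs, "+ (1 | experiment_id)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                       control = lme4::lmerControl(
                                         check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_b2 <- vc$vcov[vc$grp == "experiment_id"]
    sigma_e2 <- stats::sigma(fit)^2
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    flavor <- "mixed"
    if (sigma_b2 <= .Machine$double.eps) {
      warning("batch variance estimated at 0; fit is fixed-effects-equivalent",
              call. = FALSE)
    }
  } else {
    fml <- stats::as.formula(paste("logy ~", fixed_rhs))
    fit <- stats::lm(fml, data = df)
    sigma_b2 <- 0
    sigma_e2 <- stats::sigma(fit)^2
    if (!is.finite(sigma_e2)) sigma_e2 <- 0  # zero residual df / exact fit
    beta <- stats::coef(fit)
    V <- suppressWarnings(stats::vcov(fit))  # zero-residual fits warn in summary.lm
    V[!is.finite(V)] <- 0
    flavor <- "fixed"
  }
  role_coef <- paste0("role", roles)
  means <- stats::setNames(beta[role_coef], roles)
  V <- V[role_coef, role_coef, drop = FALSE]
  dimnames(V) <- list(roles, roles)
  structure(list(phenotype = phenotype,
                 means = means,
                 vcov = V,
                 sigma_b2 = sigma_b2,
                 sigma_e2 = sigma_e2,
                 flavor = flavor,
                 n = as.integer(n_role),
                 n_experiments = n_expt,
                 df_residual = nrow(df) - length(roles) - length(covariates)),
            class = "genotype_fit")
}

#' Epistasis estimate from a fitted genotype model
#'
#' The interaction statistic on log-transformed counts is
#' `E = (WT0 + TH3) - (CM1 + CP2)`; `E = 0` means the triple
#' heterozygote's phenotype is exactly the multiplicative prediction from
#' the intermediate genotypes, `E > 0` positive epistasis (higher than
#' expected), `E < 0` negative epistasis.  The standard error is the
#' contrast SE `sqrt(c' V c)` with weights `c = (+1, -1, -1, +1)`; the
#' default interval is `E +/- z * SE` (normal quantile), with a
#' t-interval on the residual degrees of freedom available via
#' `df_method = "residual"`.
#'
#' @param fit a `genotype_fit`.
#' @param level confidence level (default 0.95).
#' @param df_method `"z"` (default) or `"residual"` (t quantile).
#' @return object of class `epistasis_estimate`: list with `phenotype`,
#'   `E_hat`, `se`, `ci_low`, `ci_high`, `level`, `sign_class`
#'   (`"positive"` iff `ci_low > 0`, `"negative"` iff `ci_high < 0`,
#'   else `"none"`), plus the per-role sample sizes and model flavor.
#' @export
estimate_epistasis <- function(fit, level = 0.95, df_method = c("z", "residual")) {
  stopifnot(inherits(fit, "genotype_fit"))
  df_method <- match.arg(df_method)
  roles <- c("WT0", "CM1", "CP2", "TH3")
  if (any(!roles %in% names(fit$means)) || anyNA(fit$means[roles])) {
    stop("fit is missing one or more role means", call. = FALSE)
  }
  cw <- stats::setNames(c(1, -1, -1, 1), roles)
  E <- sum(cw * fit$means[roles])
  se <- sqrt(max(0, drop(t(cw) %*% fit$vcov[roles, roles] %*% cw)))
  q <- if (df_method == "z") {
    stats::qnorm(1 - (1 - level) / 2)
  } else {
    stats::qt(1 - (1 - level) / 2, df = max(1, fit$df_residual))
  }
  ci <- E + c(-1, 1) * q * se
  sign_class <- if (ci[1] > 0) "positive" else if (ci[2] < 0) "negative" else "none"
  structure(list(phenotype = fit$phenotype,
                 E_hat = unname(E), se = unname(se),
                 ci_low = ci[1], ci_high = ci[2],
                 level = level, sign_class = sign_class,
                 n = fit$n, flavor = fit$flavor),
            class = "epistasis_estimate")
}

#' @export
print.epistasis_estimate <- function(x, ...) {
  cat(sprintf("%s: E = %.4f (SE %.4f), %g%% CI [%.4f, %.4f], epistasis: %s\n",
              x$phenotype, x$E_hat, x$se, 100 * x$level,
              x$ci_low, x$ci_high, x$sign_class))
  invisible(x)
}

#' Epistasis panel over several phenotypes
#'
#' One estimate per cell type, in the requested order.  No multiple
#' comparison adjustment is applied across phenotypes; each interval is at
#' the stated per-phenotype level.  A phenotype whose fit fails is
#' reported with a warning and skipped rather than aborting the panel.
#'
#' @param dataset a `blood_counts` data frame.
#' @param design an [epistasis_design()].
#' @param phenotypes character vector of phenotype columns; defaults to
#'   all phenotype columns of `dataset`.
#' @param level confidence level.
#' @param batch_as_random,df_method passed through.
#' @return data frame with columns `phenotype`, `E_hat`, `se`, `ci_low`,
#'   `ci_high`, `level`, `sign_class`, `n_WT0`, `n_CM1`, `n_CP2`, `n_TH3`,
#'   `model_flavor`.
#' @export
run_epistasis_panel <- function(dataset, design = epistasis_design(),
                                phenotypes = blood_phenotypes(dataset),
                                level = 0.95, batch_as_random = TRUE,
                                df_method = "z") {
  rows <- lapply(phenotypes, function(ph) {
    est <- tryCatch({
      fit <- fit_genotype_model(dataset, ph, design,
                                batch_as_random = batch_as_random)
      estimate_epistasis(fit, level = level, df_method = df_method)
    }, error = function(e) {
      warning("phenotype '", ph, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(est)) return(NULL)
    data.frame(phenotype = est$phenotype, E_hat = est$E_hat, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, level = est$level,
               sign_class = est$sign_class,
               n_WT0 = est$n[1], n_CM1 = est$n[2],
               n_CP2 = est$n[3], n_TH3 = est$n[4],
               model_flavor = est$flavor, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phenotype = character(), E_hat = numeric(),
                      se = numeric(), ci_low = numeric(), ci_high = numeric(),
                      level = numeric(), sign_class = character(),
                      n_WT0 = integer(), n_CM1 = integer(),
                      n_CP2 = integer(), n_TH3 = integer(),
                      model_flavor = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post test
#'
#' The supporting pairwise genotype comparison used alongside the
#' interaction analysis: one-way ANOVA on (optionally log-transformed)
#' phenotype values followed by Tukey honest-significant-difference
#' adjusted p-values for every genotype pair, with star codes at
#' 0.05 / 0.01 / 0.001.
#'
#' @param dataset a `blood_counts` data frame.
#' @param phenotype phenotype column.
#' @param genotypes genotype labels to include (default: all present).
#' @param log_scale analyse log-transformed values (default `TRUE`).
#' @return list of class `anova_tukey` with `F`, `p`, `df` and a `pairs`
#'   data frame (`pair`, `diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @export
anova_tukey <- function(dataset, phenotype,
                        genotypes = unique(dataset$genotype),
                        log_scale = TRUE) {
  d <- dataset[dataset$genotype %in% genotypes, , drop = FALSE]
  tab <- table(d$genotype)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 genotypes with >= 2 observations each", call. = FALSE)
  }
  y <- if (log_scale) log_transform(d, phenotype) else d[[phenotype]]
  df <- data.frame(y = as.numeric(y), genotype = factor(d$genotype))
  fit <- stats::aov(y ~ genotype, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$genotype
  stars <- cut(tk[, "p adj"], breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stars = as.character(stars),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                 df = unname(an[, "Df"]), pairs = pairs,
                 log_scale = log_scale, phenotype = phenotype),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s%s: F(%d, %d) = %.3f, p = %.3g\n",
              x$phenotype, if (x$log_scale) " (log)" else "",
              x$df[1], x$df[2], x$F, x$p))
  print(x$pairs, ...)
  invisible(x)
}
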