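#' Configuration for the blood-count simulator
#'
#' Describes the generative model for a four-genotype complete-blood-count
#' experiment: log(count) = genotype mean + experiment random intercept +
#' residual noise.  The four genotype roles are `WT0` (wild type), `CM1`
#' (c-Myb heterozygous null), `CP2` (CBP/p300 KIX double heterozygote) and
#' `TH3` (triple heterozygote).  Log-scale genotype means are built from a
#' baseline, two additive allele effects and an interaction term so that
#'
#'   mu_WT0 = baseline
#'   mu_CM1 = baseline + delta_cm1
#'   mu_CP2 = baseline + delta_cp2
#'   mu_TH3 = baseline + delta_cm1 + delta_cp2 + true_E
#'
#' which makes `true_E = (mu_WT0 + mu_TH3) - (mu_CM1 + mu_CP2)` hold
#' exactly: `true_E` IS the epistasis the estimator should recover.
#' All logs are natural logs.
#'
#' @param n_per_group animals per genotype (integer >= 1).
#' @param n_experiments number of independent experiments (batches).
#' @param baseline_log_mean named numeric, log-scale mean of each phenotype
#'   in `WT0`.  Names become phenotype column names.
#' @param delta_cm1,delta_cp2 additive log-scale allele effects, recycled
#'   across phenotypes.
#' @param true_E interaction term on the log scale, recycled across
#'   phenotypes.
#' @param batch_sd standard deviation of the per-experiment random
#'   intercept (>= 0).
#' @param residual_sd standard deviation of per-animal noise (>= 0).
#' @param balanced if `TRUE` (default) every genotype is spread evenly
#'   across experiments; if `FALSE` each animal's experiment is drawn at
#'   random.
#' @param strain,age_months cosmetic metadata values carried into the
#'   dataset; they have no effect on the generated counts.
#' @param seed integer random seed.
#' @return an object of class `blood_sim_config`.
#' @export
blood_sim_config <- function(n_per_group = 15,
                             n_experiments = 5,
                             baseline_log_mean = c(platelets = log(1000)),
                             delta_cm1 = 0,
                             delta_cp2 = 0,
                             true_E = 0,
                             batch_sd = 0.1,
                             residual_sd = 0.2,
                             balanced = TRUE,
                             strain = "B6x129SvF1",
                             age_months = 1.5,
                             seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    stop("n_per_group must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(n_experiments) || n_experiments < 1) {
    stop("n_experiments must be an integer >= 1", call. = FALSE)
  }
  if (batch_sd < 0) stop("batch_sd must be >= 0", call. = FALSE)
  if (residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (is.null(names(baseline_log_mean))) {
    names(baseline_log_mean) <- paste0("phenotype", seq_along(baseline_log_mean))
  }
  p <- length(baseline_log_mean)
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_experiments = as.integer(n_experiments),
    baseline_log_mean = baseline_log_mean,
    delta_cm1 = rep_len(delta_cm1, p),
    delta_cp2 = rep_len(delta_cp2, p),
    true_E = rep_len(true_E, p),
    batch_sd = batch_sd,
    residual_sd = residual_sd,
    balanced = isTRUE(balanced),
    strain = strain,
    age_months = age_months,
    seed = as.integer(seed)
  )
  class(cfg) <- "blood_sim_config"
  cfg
}

#' Log-scale genotype means implied by a simulator configuration
#'
#' @param config a [blood_sim_config()].
#' @return a 4 x n_phenotypes matrix with rows WT0, CM1, CP2, TH3.
#' @export
genotype_log_means <- function(config) {
  b <- config$baseline_log_mean
  rbind(
    WT0 = b,
    CM1 = b + config$delta_cm1,
    CP2 = b + config$delta_cp2,
    TH3 = b + config$delta_cm1 + config$delta_cp2 + config$true_E
  )
}

genotype_roles <- c("WT0", "CM1", "CP2", "TH3")

# Even allocation of one genotype's animals over experiments; the remainder
# is handed out round-robin starting at a genotype-specific offset so that
# remainders from different genotypes do not all pile into experiment 1.
balanced_experiments <- function(n, k, offset = 0L) {
  base <- rep(seq_len(k), times = n %/% k)
  r <- n %% k
  if (r > 0) {
    extra <- ((offset + seq_len(r) - 1L) %% k) + 1L
    base <- c(base, extra)
  }
  sort(base)
}

#' Simulate a four-genotype blood-count dataset
#'
#' Draws one random intercept per experiment from N(0, batch_sd^2) and one
#' residual per animal from N(0, residual_sd^2), adds them to the genotype
#' log-means of `config` and exponentiates, so counts are lognormal on the
#' natural scale.  Deterministic given `config$seed`.
#'
#' @param config a [blood_sim_config()].
#' @return a `data.frame` of class `blood_counts` with columns `animal_id`,
#'   `genotype`, `experiment_id`, `strain`, `age_months` and one numeric
#'   column per phenotype (all values > 0).  The log base used by the
#'   generative model is recorded in `attr(, "log_base")` (`"e"`).
#' @export
simulate_blood_counts <- function(config) {
  stopifnot(inherits(config, "blood_sim_config"))
  mu <- genotype_log_means(config)
  n <- config$n_per_group
  k <- config$n_experiments
  set.seed(config$seed)
  b <- stats::rnorm(k, 0, config$batch_sd)

  if (config$balanced) {
    expt <- unlist(lapply(seq_along(genotype_roles) - 1L,
                          function(off) balanced_experiments(n, k, off)))
  } else {
    expt <- sample(k, 4L * n, replace = TRUE)
  }
  genotype <- rep(genotype_roles, each = n)

  n_animals <- 4L * n
  p <- length(config$baseline_log_mean)
  eps <- matrix(stats::rnorm(n_animals * p, 0, config$residual_sd),
                nrow = n_animals, ncol = p)
  logy <- mu[genotype, , drop = FALSE] + b[expt] + eps
  counts <- exp(logy)
  colnames(counts) <- names(config$baseline_log_mean)

  out <- data.frame(
    animal_id = sprintf("animal_%04d", seq_len(n_animals)),
    genotype = genotype,
    experiment_id = sprintf("expt_%02d", expt),
    strain = config$strain,
    age_months = config$age_months,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(counts))
  attr(out, "log_base") <- "e"
  attr(out, "true_E") <- stats::setNames(config$true_E,
                                         names(config$baseline_log_mean))
  class(out) <- c("blood_counts", "data.frame")
  out
}

#' @export
print.blood_counts <- function(x, ...) {
  cat(sprintf("Blood-count dataset: %d animals, %d experiments, phenotypes: %s\n",
              nrow(x), length(unique(x$experiment_id)),
              paste(setdiff(names(x), c("animal_id", "genotype",
                                        "experiment_id", "strain",
                                        "age_months")), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Phenotype column names of a blood-count dataset
#' @param dataset a `blood_counts` data frame.
#' @return character vector of phenotype column names.
#' @export
blood_phenotypes <- function(dataset) {
  setdiff(names(dataset),
          c("animal_id", "genotype", "experiment_id", "strain", "age_months"))
}
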