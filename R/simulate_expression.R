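#' Configuration for the expression-matrix simulator
#'
#' Emulates the design of the MEF transduction experiment: two genotypes
#' (`WT` and a KIX-domain mutant, `KIX`) each profiled with and without a
#' c-Myb-expressing treatment, with replicate arrays per condition.  A
#' chosen fraction of genes is planted as c-Myb activated (log2 signal
#' raised by `activation_log2fc` under treatment) or repressed (lowered by
#' `|repression_log2fc|`); within each regulated class a fraction is
#' KIX-sensitive, meaning the treatment effect is attenuated to zero in
#' the mutant genotype.  A further fraction of unregulated genes is planted
#' "absent", sitting below the detection floor in every condition.
#'
#' @param n_genes number of genes (probe sets).
#' @param n_replicates replicates per genotype x treatment condition.
#' @param frac_activated,frac_repressed fractions of genes planted as
#'   activated / repressed (`frac_activated + frac_repressed <= 1`).
#' @param activation_log2fc treatment effect for activated genes (> 0).
#' @param repression_log2fc treatment effect for repressed genes (< 0).
#' @param frac_kix_sensitive fraction of each regulated class whose effect
#'   is lost in the mutant genotype.
#' @param frac_absent fraction of unregulated genes parked below
#'   `presence_floor` in all conditions.
#' @param baseline_log2_mean mean log2 signal of expressed genes.
#' @param noise_sd per-measurement noise sd on the log2 scale (>= 0).
#' @param presence_floor log2 signal under which "absent" genes sit
#'   (default 3.4, twice a typical array background).
#' @param seed integer random seed.
#' @return an object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 1000,
                            n_replicates = 2,
                            frac_activated = 0.05,
                            frac_repressed = 0.05,
                            activation_log2fc = 2,
                            repression_log2fc = -2,
                            frac_kix_sensitive = 0.5,
                            frac_absent = 0.1,
                            baseline_log2_mean = 7,
                            noise_sd = 0.25,
                            presence_floor = 3.4,
                            seed = 1L) {
  fr <- c(frac_activated = frac_activated, frac_repressed = frac_repressed,
          frac_kix_sensitive = frac_kix_sensitive, frac_absent = frac_absent)
  bad <- fr < 0 | fr > 1
  if (any(bad)) {
    stop("fractions must lie in [0, 1]: ", paste(names(fr)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (frac_activated + frac_repressed > 1) {
    stop("frac_activated + frac_repressed must be <= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (activation_log2fc <= 0) stop("activation_log2fc must be > 0", call. = FALSE)
  if (repression_log2fc >= 0) stop("repression_log2fc must be < 0", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              frac_activated = frac_activated,
              frac_repressed = frac_repressed,
              activation_log2fc = activation_log2fc,
              repression_log2fc = repression_log2fc,
              frac_kix_sensitive = frac_kix_sensitive,
              frac_absent = frac_absent,
              baseline_log2_mean = baseline_log2_mean,
              noise_sd = noise_sd,
              presence_floor = presence_floor,
              seed = as.integer(seed))
  class(cfg) <- "expr_sim_config"
  cfg
}

#' Construct an expression-matrix container
#'
#' Genes x samples log2 signals plus per-sample annotations and optional
#' per-gene truth labels (used by simulator recovery tests).
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names required, no missing values.
#' @param samples data frame with one row per column of `values`:
#'   `sample_id`, `genotype`, `treatment`, `replicate`.
#' @param truth optional data frame: `gene_id`, `class` (one of
#'   `"activated"`, `"repressed"`, `"null"`), `kix_sensitive` (logical),
#'   `absent` (logical).
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, truth = NULL) {
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene (row) and sample (column) names", call. = FALSE)
  }
  req <- c("sample_id", "genotype", "treatment", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample annotation rows (", nrow(samples),
         ") do not match matrix columns (", ncol(values), ")", call. = FALSE)
  }
  if (!identical(samples$sample_id, colnames(values))) {
    stop("samples$sample_id must equal colnames(values) in order", call. = FALSE)
  }
  structure(list(values = values, samples = samples, truth = truth),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(paste(x$samples$genotype, x$samples$treatment,
                                 sep = ".")), collapse = ", ")))
  if (!is.null(x$truth)) {
    cat("  planted truth:", sum(x$truth$class == "activated"), "activated,",
        sum(x$truth$class == "repressed"), "repressed,",
        sum(x$truth$kix_sensitive), "KIX-sensitive\n")
  }
  invisible(x)
}

#' Simulate a two-genotype, two-treatment expression experiment
#'
#' @param config an [expr_sim_config()].
#' @return an [expr_matrix()] with samples for the four conditions
#'   `WT.ctrl`, `WT.myb`, `KIX.ctrl`, `KIX.myb` and truth labels attached.
#'   Deterministic given `config$seed`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  n_act <- round(config$frac_activated * g)
  n_rep <- round(config$frac_repressed * g)
  cls <- rep("null", g)
  cls[seq_len(n_act)] <- "activated"
  if (n_rep > 0) cls[n_act + seq_len(n_rep)] <- "repressed"
  kix <- rep(FALSE, g)
  kix[seq_len(round(config$frac_kix_sensitive * n_act))] <- TRUE
  if (n_rep > 0) {
    kix[n_act + seq_len(round(config$frac_kix_sensitive * n_rep))] <- TRUE
  }
  null_idx <- which(cls == "null")
  absent <- rep(FALSE, g)
  absent[null_idx[seq_len(round(config$frac_absent * length(null_idx)))]] <- TRUE

  gene_ids <- sprintf("gene_%05d", seq_len(g))
  base <- rep(config$baseline_log2_mean, g)
  base[absent] <- config$presence_floor - 1

  conditions <- expand.grid(treatment = c("ctrl", "myb"),
                            genotype = c("WT", "KIX"),
                            stringsAsFactors = FALSE)[, 2:1]
  samples <- conditions[rep(seq_len(4), each = config$n_replicates), ]
  samples$replicate <- rep(seq_len(config$n_replicates), times = 4)
  samples$sample_id <- paste(samples$genotype, samples$treatment,
                             samples$replicate, sep = ".")
  samples <- samples[, c("sample_id", "genotype", "treatment", "replicate")]
  rownames(samples) <- NULL

  effect <- numeric(g)
  effect[cls == "activated"] <- config$activation_log2fc
  effect[cls == "repressed"] <- config$repression_log2fc

  vals <- matrix(0, g, nrow(samples),
                 dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- base
    if (samples$treatment[j] == "myb") {
      eff <- effect
      if (samples$genotype[j] == "KIX") eff[kix] <- 0  # sensitivity planted here
      mu <- mu + eff
    }
    vals[, j] <- mu + stats::rnorm(g, 0, config$noise_sd)
  }

  truth <- data.frame(gene_id = gene_ids, class = cls,
                      kix_sensitive = kix, absent = absent,
                      stringsAsFactors = FALSE)
  expr_matrix(vals, samples, truth)
}
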