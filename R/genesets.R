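#' Filter and classification thresholds for c-Myb response calling
#'
#' Defaults follow the array analysis they implement: probes are called
#' present when their mean log2 signal is at least 3.4 (twice background);
#' a gene is "activated" when c-Myb treatment raises its signal at least
#' twofold, "repressed" when it lowers it at least 50%; a regulated gene
#' is "KIX-sensitive" when the KIX mutation blunts its response at least
#' 1.5-fold.  All thresholds are inclusive (`>=` / `<=`).
#'
#' @param presence_floor minimum mean log2 signal for a probe to count as
#'   present (default 3.4).
#' @param induce_ratio minimum linear-scale treated/control ratio for
#'   "activated" (default 2, must be > 1).
#' @param repress_ratio maximum ratio for "repressed" (default 0.5, must
#'   be in (0, 1)).
#' @param sensitivity_ratio minimum WT/mutant (activated) or mutant/WT
#'   (repressed) ratio for "KIX-sensitive" (default 1.5, must be >= 1).
#' @param p_threshold per-gene p cutoff for the optional replicate-level
#'   t-test filter (default 0.05).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(presence_floor = 3.4, induce_ratio = 2,
                          repress_ratio = 0.5, sensitivity_ratio = 1.5,
                          p_threshold = 0.05) {
  if (induce_ratio <= 1) stop("induce_ratio must be > 1", call. = FALSE)
  if (repress_ratio <= 0 || repress_ratio >= 1) {
    stop("repress_ratio must be in (0, 1)", call. = FALSE)
  }
  if (sensitivity_ratio < 1) stop("sensitivity_ratio must be >= 1", call. = FALSE)
  structure(list(presence_floor = presence_floor, induce_ratio = induce_ratio,
                 repress_ratio = repress_ratio,
                 sensitivity_ratio = sensitivity_ratio,
                 p_threshold = p_threshold),
            class = "filter_params")
}

#' Average replicate arrays within conditions
#'
#' @param expr an [expr_matrix()].
#' @param grouping sample-annotation columns that define a condition
#'   (default genotype x treatment).
#' @param scale `"log2"` (default) averages log2 signals arithmetically,
#'   matching log-scale scatter axes; `"linear"` averages linear signals
#'   and returns their log2 (sensitivity analysis).
#' @return numeric matrix, genes x conditions; condition names join the
#'   grouping values with `"."`; replicate counts in
#'   `attr(, "n_replicates")`.
#' @export
average_replicates <- function(expr, grouping = c("genotype", "treatment"),
                               scale = c("log2", "linear")) {
  stopifnot(inherits(expr, "expr_matrix"))
  scale <- match.arg(scale)
  key <- interaction(expr$samples[grouping], sep = ".", drop = TRUE)
  if (any(table(key) < 1)) stop("condition with no samples", call. = FALSE)
  groups <- levels(key)
  out <- matrix(0, nrow(expr$values), length(groups),
                dimnames = list(rownames(expr$values), groups))
  for (gp in groups) {
    m <- expr$values[, key == gp, drop = FALSE]
    out[, gp] <- if (scale == "log2") rowMeans(m) else log2(rowMeans(2^m))
  }
  attr(out, "n_replicates") <- as.integer(table(key)[groups])
  attr(out, "scale") <- scale
  out
}

#' Presence filter on condition means
#'
#' A gene is retained iff its mean log2 signal is at least `floor` in
#' EVERY named condition (the boundary value itself is kept).
#'
#' @param means condition-mean matrix from [average_replicates()].
#' @param conditions condition column names that must all pass.
#' @param floor detection floor in log2 units (default from
#'   [filter_params()]).
#' @return character vector of retained gene ids.
#' @export
presence_filter <- function(means, conditions,
                            floor = filter_params()$presence_floor) {
  missing_cond <- setdiff(conditions, colnames(means))
  if (length(missing_cond)) {
    stop("condition(s) not found: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  keep <- rowSums(means[, conditions, drop = FALSE] >= floor) == length(conditions)
  rownames(means)[keep]
}

#' Classify c-Myb activated and repressed genes by fold change
#'
#' Computes the linear-scale treated/control ratio `r = 2^(treated -
#' control)` from condition-mean log2 signals; a gene is activated iff
#' `r >= induce_ratio` and repressed iff `r <= repress_ratio`.  The sets
#' are disjoint by construction since `induce_ratio > 1 > repress_ratio`.
#'
#' @param means condition-mean matrix from [average_replicates()].
#' @param control,treated condition column names.
#' @param params a [filter_params()].
#' @param genes optional gene ids to restrict to (e.g. the output of
#'   [presence_filter()]).
#' @return list with `activated`, `repressed` (gene id vectors) and
#'   `ratio` (named linear-scale ratios for the genes considered).
#' @export
classify_myb_response <- function(means, control, treated,
                                  params = filter_params(),
                                  genes = rownames(means)) {
  if (identical(control, treated)) {
    stop("control and treated conditions must differ", call. = FALSE)
  }
  missing_cond <- setdiff(c(control, treated), colnames(means))
  if (length(missing_cond)) {
    stop("condition(s) not found: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  m <- means[genes, , drop = FALSE]
  ratio <- 2^(m[, treated] - m[, control])
  names(ratio) <- genes
  list(activated = genes[ratio >= params$induce_ratio],
       repressed = genes[ratio <= params$repress_ratio],
       ratio = ratio)
}

#' KIX-mutation sensitivity of regulated gene sets
#'
#' An activated gene is KIX-sensitive when its treated signal is at least
#' `sensitivity_ratio`-fold higher in wild type than in the mutant; for a
#' repressed gene the comparison is reversed (mutant over wild type),
#' since loss of repression leaves the mutant signal higher.
#'
#' @param sets list with `activated` and `repressed` gene id vectors
#'   (from [classify_myb_response()]).
#' @param means condition-mean matrix.
#' @param wt_treated,mutant_treated condition column names for the two
#'   genotypes under c-Myb treatment.
#' @param params a [filter_params()].
#' @return object of class `gene_set_result`: the parent sets, the
#'   KIX-sensitive subsets, their fractions (`NA` when the parent set is
#'   empty) and the per-gene WT/mutant ratios used.
#' @export
kix_sensitivity <- function(sets, means, wt_treated, mutant_treated,
                            params = filter_params()) {
  missing_cond <- setdiff(c(wt_treated, mutant_treated), colnames(means))
  if (length(missing_cond)) {
    stop("condition(s) not found: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  ratio_wt_mut <- 2^(means[, wt_treated] - means[, mutant_treated])
  names(ratio_wt_mut) <- rownames(means)
  sens_act <- sets$activated[
    ratio_wt_mut[sets$activated] >= params$sensitivity_ratio]
  sens_rep <- sets$repressed[
    1 / ratio_wt_mut[sets$repressed] >= params$sensitivity_ratio]
  frac <- function(sub, parent) {
    if (length(parent) == 0) NA_real_ else length(sub) / length(parent)
  }
  structure(list(activated = sets$activated, repressed = sets$repressed,
                 kix_sensitive_activated = sens_act,
                 kix_sensitive_repressed = sens_rep,
                 frac_sensitive_activated = frac(sens_act, sets$activated),
                 frac_sensitive_repressed = frac(sens_rep, sets$repressed),
                 ratio_wt_mut = ratio_wt_mut),
            class = "gene_set_result")
}

#' @export
print.gene_set_result <- function(x, ...) {
  fmt <- function(sub, parent, fr) {
    if (is.na(fr)) "none (empty parent set)" else
      sprintf("%d of %d (%.0f%%)", length(sub), length(parent), 100 * fr)
  }
  cat("c-Myb response gene sets:\n",
      " activated:", length(x$activated),
      "| KIX-sensitive:", fmt(x$kix_sensitive_activated, x$activated,
                              x$frac_sensitive_activated), "\n",
      " repressed:", length(x$repressed),
      "| KIX-sensitive:", fmt(x$kix_sensitive_repressed, x$repressed,
                              x$frac_sensitive_repressed), "\n")
  invisible(x)
}

#' Collapse probe sets to genes
#'
#' Keeps, for each gene, the probe with the highest mean signal across all
#' samples; ties are broken lexicographically by probe id.
#'
#' @param expr an [expr_matrix()].
#' @param probe2gene data frame with columns `probe_id`, `gene_id`.
#' @return named character vector: selected probe id for each gene.
#' @export
collapse_probes <- function(expr, probe2gene) {
  m <- rowMeans(expr$values)
  p2g <- probe2gene[probe2gene$probe_id %in% names(m), , drop = FALSE]
  p2g$mean_signal <- m[p2g$probe_id]
  p2g <- p2g[order(p2g$gene_id, -p2g$mean_signal, p2g$probe_id), ]
  keep <- p2g[!duplicated(p2g$gene_id), ]
  stats::setNames(keep$probe_id, keep$gene_id)
}

#' Per-gene replicate-level t-test filter
#'
#' Unpaired two-sample t-tests on replicate log2 signals between two
#' conditions, unadjusted; genes with p below the threshold pass.
#'
#' @param expr an [expr_matrix()].
#' @param condition_a,condition_b conditions as `"genotype.treatment"`.
#' @param p_threshold cutoff (default from [filter_params()]).
#' @return list with `pass` (gene ids) and `p` (named p-value vector).
#' @export
replicate_t_filter <- function(expr, condition_a, condition_b,
                               p_threshold = filter_params()$p_threshold) {
  key <- paste(expr$samples$genotype, expr$samples$treatment, sep = ".")
  ia <- which(key == condition_a); ib <- which(key == condition_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both conditions need >= 2 replicates for the t-test", call. = FALSE)
  }
  p <- apply(expr$values, 1, function(v) {
    a <- v[ia]; b <- v[ib]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  })
  list(pass = names(p)[p < p_threshold], p = p)
}

#' Direction-of-regulation concordance between two signed gene lists
#'
#' @param list_a,list_b data frames with columns `gene_id` and `direction`
#'   (`"up"` or `"down"`), one row per gene.
#' @return list with `n_overlap`, `n_same_direction`, `frac_of_a`
#'   (overlap / |A|), `frac_same_of_overlap`, and a per-gene `table` of
#'   the shared ids with both directions and agreement.
#' @export
direction_concordance <- function(list_a, list_b) {
  for (l in list(list_a, list_b)) {
    if (anyDuplicated(l$gene_id)) {
      stop("signed gene lists must contain each gene once", call. = FALSE)
    }
  }
  shared <- intersect(list_a$gene_id, list_b$gene_id)
  da <- stats::setNames(list_a$direction, list_a$gene_id)[shared]
  db <- stats::setNames(list_b$direction, list_b$gene_id)[shared]
  tab <- data.frame(gene_id = shared, direction_a = unname(da),
                    direction_b = unname(db), same = unname(da == db),
                    stringsAsFactors = FALSE)
  list(n_overlap = length(shared),
       n_same_direction = sum(tab$same),
       frac_of_a = if (nrow(list_a)) length(shared) / nrow(list_a) else NA_real_,
       frac_same_of_overlap = if (length(shared)) sum(tab$same) / length(shared)
                              else NA_real_,
       table = tab)
}
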