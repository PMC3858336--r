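#' Signal-to-noise ranking metric for a two-class comparison
#'
#' For each gene, `(mean_A - mean_B) / (sd_A + sd_B)`, with each class sd
#' floored at `min_frac * |class mean|` to keep near-constant genes from
#' blowing up the ratio; when a class has both zero sd and zero mean the
#' absolute floor `abs_floor` is used.  A gene identical in all samples
#' has metric 0.
#'
#' @param expr an [expr_matrix()] or plain numeric matrix (genes x
#'   samples).
#' @param classes factor/character of length `ncol`, exactly two levels;
#'   the first level (or `positive_class`) is class A.
#' @param positive_class optional class treated as A (metric > 0 means
#'   higher in A).
#' @param min_frac sd floor as a fraction of |class mean| (default 0.2).
#' @param abs_floor absolute sd floor applied when mean and sd are both 0
#'   (default 0.2).
#' @return named numeric vector of per-gene metrics, in input gene order.
#' @export
signal_to_noise <- function(expr, classes, positive_class = NULL,
                            min_frac = 0.2, abs_floor = 0.2) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2) stop("exactly two classes required", call. = FALSE)
  if (!is.null(positive_class)) {
    if (!positive_class %in% lev) stop("unknown positive_class", call. = FALSE)
    lev <- c(positive_class, setdiff(lev, positive_class))
  }
  ia <- classes == lev[1]; ib <- classes == lev[2]
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("each class needs >= 2 samples", call. = FALSE)
  }
  s2n_core(m, ia, ib, min_frac, abs_floor)
}

# vectorised core shared with the permutation loop
s2n_core <- function(m, ia, ib, min_frac = 0.2, abs_floor = 0.2) {
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  sa <- sqrt(rowSums((m[, ia, drop = FALSE] - ma)^2) / (na - 1))
  sb <- sqrt(rowSums((m[, ib, drop = FALSE] - mb)^2) / (nb - 1))
  sa <- pmax(sa, min_frac * abs(ma))
  sb <- pmax(sb, min_frac * abs(mb))
  sa[sa == 0] <- abs_floor
  sb[sb == 0] <- abs_floor
  num <- ma - mb
  out <- num / (sa + sb)
  out[num == 0] <- 0
  out
}

#' Rank genes by a metric
#'
#' Descending order; ties keep the original (stable) gene order.
#'
#' @param metric named numeric vector.
#' @return list of class `ranked_genes` with `ids` and `metric` (sorted).
#' @export
rank_genes <- function(metric) {
  ord <- order(-metric)  # radix sort: stable on ties
  structure(list(ids = names(metric)[ord], metric = unname(metric[ord])),
            class = "ranked_genes")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: each gene in the set ("hit") increments the sum
#' by `|r_i|^p_w / sum_hits |r_j|^p_w`, each miss decrements it by
#' `1 / (N - N_hits)`.  The enrichment score is the signed maximum
#' deviation of the walk from zero; the walk ends exactly at zero.  When
#' all hit weights are zero (possible with `p_w > 0` and an all-zero
#' metric) hits fall back to equal weights.
#'
#' @param ranked a [rank_genes()] result.
#' @param set character vector of member gene ids.
#' @param p_w weight exponent (default 1; `p_w = 0` gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @return list with `ES`, `running_sum` (length N), `hit_positions`.
#' @export
compute_es <- function(ranked, set, p_w = 1) {
  ids <- ranked$ids
  N <- length(ids)
  hit <- ids %in% set
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (nh == N) stop("gene set equals the ranked universe", call. = FALSE)
  w <- abs(ranked$metric)^p_w
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- nh }
  step <- ifelse(hit, w / tot, -1 / (N - nh))
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(ES = rs[i], running_sum = rs, hit_positions = which(hit))
}

# ES for many sets against one metric vector; sorts once and then runs,
# per set, exactly the same cumsum walk as compute_es so permutation and
# observed scores share tie-breaking and rounding behaviour.
es_for_sets <- function(metric, set_idx_list, p_w) {
  N <- length(metric)
  ord <- order(-metric)
  absw_ord <- abs(metric[ord])^p_w
  rankpos <- integer(N); rankpos[ord] <- seq_len(N)
  vapply(set_idx_list, function(idx) {
    nh <- length(idx)
    hit <- logical(N); hit[rankpos[idx]] <- TRUE
    w <- absw_ord; w[!hit] <- 0
    tot <- sum(w)
    if (tot == 0) { w[hit] <- 1; tot <- nh }
    step <- ifelse(hit, w / tot, -1 / (N - nh))
    rs <- cumsum(step)
    rs[which.max(abs(rs))]
  }, numeric(1))
}

#' Permutation configuration for enrichment analysis
#'
#' @param n_permutations number of permutations (default 1000).
#' @param mode `"phenotype"` (shuffle class labels; default) or
#'   `"gene_set"` (draw random same-size sets).
#' @param p_w weight exponent (default 1).
#' @param min_size,max_size gene-set size limits after restriction to the
#'   ranked universe (defaults 15 and 500).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000,
                               mode = c("phenotype", "gene_set"),
                               p_w = 1, min_size = 15, max_size = 500,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (p_w < 0) stop("p_w must be >= 0", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations), mode = mode,
                 p_w = p_w, min_size = as.integer(min_size),
                 max_size = as.integer(max_size), seed = as.integer(seed)),
            class = "permutation_config")
}

# all distinct assignments of na labels among n samples, as a logical
# matrix (columns = assignments); used when C(n, na) <= cap
enumerate_assignments <- function(n, na, cap) {
  if (choose(n, na) > cap) return(NULL)
  combs <- utils::combn(n, na)
  apply(combs, 2, function(ix) { v <- logical(n); v[ix] <- TRUE; v },
        simplify = FALSE)
}

#' Gene set enrichment analysis with permutation significance
#'
#' For each gene set: ranks genes by signal-to-noise between the two
#' classes, computes the weighted running-sum enrichment score, then
#' builds a null distribution by permuting class labels (phenotype mode)
#' or drawing random same-size sets (gene_set mode).  The nominal p uses
#' the same-signed tail of the set's own null; NES divides ES by the mean
#' magnitude of same-signed null scores; FDR q and FWER p are computed
#' across the whole set collection from the normalized null
#' distributions.  In phenotype mode, when the number of distinct label
#' assignments is at most `n_permutations` they are enumerated
#' exhaustively instead of sampled.
#'
#' @param expr an [expr_matrix()] or numeric matrix.
#' @param classes two-level class labels, length `ncol`.
#' @param sets named list of gene-id vectors.
#' @param config a [permutation_config()].
#' @param positive_class optional class treated as A in the metric.
#' @return data frame of class `enrichment_result` with one row per
#'   retained set: `set`, `size`, `ES`, `NES`, `p_nominal`,
#'   `p_nominal_label` (`"<1/n"` display when the tail count is zero),
#'   `fdr_q`, `fwer_p`.  Per-set running sums and hit positions are in
#'   `attr(, "walks")`; sets excluded by the size limits are named in
#'   `attr(, "excluded")`.
#' @export
permutation_significance <- function(expr, classes, sets,
                                     config = permutation_config(),
                                     positive_class = NULL) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2) stop("exactly two classes required", call. = FALSE)
  if (!is.null(positive_class)) {
    lev <- c(positive_class, setdiff(lev, positive_class))
  }
  ia0 <- classes == lev[1]
  if (config$mode == "phenotype" && (sum(ia0) < 2 || sum(!ia0) < 2)) {
    stop("phenotype permutation requires >= 2 samples per class", call. = FALSE)
  }

  universe <- rownames(m)
  sets <- lapply(sets, function(s) intersect(s, universe))
  sizes <- lengths(sets)
  keep <- sizes >= config$min_size & sizes <= config$max_size &
    sizes < length(universe)
  excluded <- names(sets)[!keep]
  sets <- sets[keep]
  if (length(sets) == 0) stop("no gene set within the size limits", call. = FALSE)
  set_idx <- lapply(sets, function(s) match(s, universe))

  metric <- s2n_core(m, ia0, !ia0)
  names(metric) <- universe
  ranked <- rank_genes(metric)
  obs <- lapply(sets, function(s) compute_es(ranked, s, config$p_w))
  es_obs <- vapply(obs, `[[`, numeric(1), "ES")

  set.seed(config$seed)
  nperm <- config$n_permutations
  if (config$mode == "phenotype") {
    enum <- enumerate_assignments(length(classes), sum(ia0), nperm)
    perms <- if (!is.null(enum)) enum else
      lapply(seq_len(nperm), function(i) {
        v <- logical(length(classes))
        v[sample(length(classes), sum(ia0))] <- TRUE
        v
      })
    es_null <- vapply(perms, function(ia) {
      es_for_sets(s2n_core(m, ia, !ia), set_idx, config$p_w)
    }, numeric(length(sets)))
  } else {
    perms <- seq_len(nperm)
    es_null <- vapply(perms, function(i) {
      vapply(sizes[keep], function(sz) {
        es_for_sets(metric, list(sample(length(universe), sz)), config$p_w)
      }, numeric(1))
    }, numeric(length(sets)))
  }
  es_null <- matrix(es_null, nrow = length(sets))  # sets x permutations
  n_used <- ncol(es_null)

  res <- summarize_permutations(es_obs, es_null)
  res <- data.frame(set = names(sets), size = unname(sizes[keep]), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "walks") <- lapply(obs, function(o)
    o[c("running_sum", "hit_positions")])
  attr(res, "excluded") <- excluded
  attr(res, "n_permutations_used") <- n_used
  attr(res, "ranked") <- ranked
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# nominal p, NES, FDR q and FWER p from observed ES and a sets x perms
# null matrix, following the standard positive/negative split
summarize_permutations <- function(es_obs, es_null) {
  ns <- length(es_obs)
  nperm <- ncol(es_null)
  pos_mean <- apply(es_null, 1, function(v) mean(v[v >= 0]))
  neg_mean <- apply(es_null, 1, function(v) mean(abs(v[v < 0])))
  pos_mean[!is.finite(pos_mean) | pos_mean == 0] <- NA
  neg_mean[!is.finite(neg_mean) | neg_mean == 0] <- NA

  norm1 <- function(es, i) {
    if (es >= 0) es / pos_mean[i] else es / neg_mean[i]
  }
  nes_obs <- vapply(seq_len(ns), function(i) norm1(es_obs[i], i), numeric(1))
  nes_null <- es_null
  for (i in seq_len(ns)) {
    v <- es_null[i, ]
    v[v >= 0] <- v[v >= 0] / pos_mean[i]
    v[v < 0] <- v[v < 0] / neg_mean[i]
    nes_null[i, ] <- v
  }
  nes_obs[is.na(nes_obs)] <- 0
  nes_null[is.na(nes_null)] <- 0

  p_nom <- p_lab <- numeric(ns)
  p_lab <- character(ns)
  for (i in seq_len(ns)) {
    v <- es_null[i, ]
    if (es_obs[i] >= 0) {
      same <- v[v >= 0]; k <- sum(same >= es_obs[i])
    } else {
      same <- v[v < 0]; k <- sum(same <= es_obs[i])
    }
    denom <- length(same)
    p_nom[i] <- if (denom == 0) NA_real_ else k / denom
    p_lab[i] <- if (!is.na(p_nom[i]) && k == 0)
      sprintf("<%.2g", 1 / max(1, denom)) else format(p_nom[i], digits = 3)
  }

  all_null <- as.vector(nes_null)
  fdr_q <- fwer_p <- numeric(ns)
  max_pos <- apply(nes_null, 2, max)
  min_neg <- apply(nes_null, 2, min)
  for (i in seq_len(ns)) {
    x <- nes_obs[i]
    if (x >= 0) {
      null_tail <- mean(all_null[all_null >= 0] >= x)
      obs_tail <- mean(nes_obs[nes_obs >= 0] >= x)
      fwer_p[i] <- mean(max_pos >= x)
    } else {
      null_tail <- mean(all_null[all_null < 0] <= x)
      obs_tail <- mean(nes_obs[nes_obs < 0] <= x)
      fwer_p[i] <- mean(min_neg <= x)
    }
    fdr_q[i] <- if (is.na(obs_tail) || obs_tail == 0) NA_real_ else
      min(1, null_tail / obs_tail)
  }
  data.frame(ES = es_obs, NES = nes_obs, p_nominal = p_nom,
             p_nominal_label = p_lab, fdr_q = fdr_q, fwer_p = fwer_p,
             stringsAsFactors = FALSE)
}
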