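# Independent oracles, coded separately from the implementation paths
# they check.

# Brute-force weighted running-sum walk: explicit loop, no vectorised
# shortcuts shared with compute_es().
oracle_es_walk <- function(ids_ranked, metric_ranked, set, p_w) {
  N <- length(ids_ranked)
  in_set <- ids_ranked %in% set
  nh <- sum(in_set)
  denom_hit <- sum(abs(metric_ranked[in_set])^p_w)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) {
      cur <- cur + if (denom_hit > 0) abs(metric_ranked[i])^p_w / denom_hit
                   else 1 / nh
    } else {
      cur <- cur - 1 / (N - nh)
    }
    rs[i] <- cur
  }
  best <- 0; best_abs <- -1
  for (i in seq_len(N)) {
    if (abs(rs[i]) > best_abs) { best_abs <- abs(rs[i]); best <- rs[i] }
  }
  list(ES = best, running_sum = rs)
}

# Batch-centering oracle for the balanced mixed-model fit: subtract each
# experiment's grand mean, then average per genotype, then add back the
# overall mean so the contrast is comparable.
oracle_centered_means <- function(dataset, phenotype) {
  logy <- log(dataset[[phenotype]])
  centered <- logy - ave(logy, dataset$experiment_id)
  tapply(centered, dataset$genotype, mean) + mean(logy)
}

# Tiny hand-built blood dataset: four genotypes, explicit values.
make_blood_df <- function(values_by_genotype, experiment = "e1") {
  rows <- do.call(rbind, lapply(names(values_by_genotype), function(g) {
    v <- values_by_genotype[[g]]
    data.frame(genotype = g, value = v, stringsAsFactors = FALSE)
  }))
  d <- data.frame(animal_id = sprintf("a%03d", seq_len(nrow(rows))),
                  genotype = rows$genotype,
                  experiment_id = rep_len(experiment, nrow(rows)),
                  strain = "s", age_months = 1.5,
                  platelets = rows$value, stringsAsFactors = FALSE)
  class(d) <- c("blood_counts", "data.frame")
  d
}

# Toy expression matrix with explicit values and two replicates per
# condition.
make_expr <- function(values, genotypes, treatments, replicates = NULL) {
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(genotypes),
                             paste(genotypes, treatments), FUN = seq_along)
  }
  ids <- paste(genotypes, treatments, replicates, sep = ".")
  colnames(values) <- ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  expr_matrix(values,
              data.frame(sample_id = ids, genotype = genotypes,
                         treatment = treatments, replicate = replicates,
                         stringsAsFactors = FALSE))
}
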