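# small in-code fixtures shared across test files

make_em <- function(values, scale = "log2", platform = "array",
                    genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale, platform = platform)
}

# metadata frame for a plain one-platform design
make_meta <- function(sample_ids, group, zt, platform = "array",
                      mouse_id = sample_ids) {
  data.frame(sample_id = sample_ids, group = group, zt = zt,
             platform = platform, mouse_id = mouse_id)
}

# noiseless three-group ZT0/ZT12 matrix with planted deltas, for the
# correction classifier: value = gene baseline + delta[group] * (zt == 0)
make_correction_em <- function(delta_young, delta_neph, delta_rem,
                               n_rep = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n_genes <- length(delta_young)
  groups <- c("young", "nephritic", "remission")
  deltas <- rbind(young = delta_young, nephritic = delta_neph,
                  remission = delta_rem)
  meta <- expand.grid(group = groups, zt = c(0, 12), rep = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_zt%d_r%d", meta$group, meta$zt, meta$rep)
  meta$platform <- "array"
  meta$mouse_id <- meta$sample_id
  v <- matrix(0, n_genes, nrow(meta))
  for (i in seq_len(nrow(meta)))
    v[, i] <- 5 + deltas[meta$group[i], ] * (meta$zt[i] == 0) +
      rnorm(n_genes, 0, noise_sd)
  em <- make_em(v, samples = meta$sample_id)
  list(em = em, meta = meta[, c("sample_id", "group", "zt", "platform",
                                "mouse_id")])
}
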