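# Shared fixtures built in code.

# small gaussian cloud for solver tests
gaussian_cloud <- function(n, d = 2, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * d, sd = sd), n, d)
}

# tiny two-condition expression matrix with planted disease genes, used
# where a full generate_expression() run would be overkill
tiny_expression <- function(n_genes = 40, n_planted = 8, delta = 4,
                            nd = 6, nh = 6, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (nd + nh), mean = 8), n_genes)
  vals[seq_len(n_planted), seq_len(nd)] <-
    vals[seq_len(n_planted), seq_len(nd)] + delta
  expression_matrix(
    vals, gene_ids = sprintf("g%02d", seq_len(n_genes)),
    sample_ids = c(sprintf("AML_%d", seq_len(nd)),
                   sprintf("healthy_%d", seq_len(nh))),
    condition = c(rep("disease", nd), rep("healthy", nh)))
}

# benchmark with cleanly separated positive/unlabeled feature clusters
separable_benchmark <- function(n_pos = 60, n_unl = 80, d = 6, gap = 5,
                                seed = 1) {
  set.seed(seed)
  pos_f <- matrix(rnorm(n_pos * d, mean = gap), n_pos, d)
  unl_f <- matrix(rnorm(n_unl * d, mean = 0), n_unl, d)
  feats <- rbind(pos_f, unl_f)
  rownames(feats) <- sprintf("g%03d", seq_len(n_pos + n_unl))
  pu_benchmark(rownames(feats)[seq_len(n_pos)],
               rownames(feats)[-seq_len(n_pos)], feats)
}

# dual objective of the nu-one-class SVM at a given alpha
ocsvm_dual_objective <- function(K, alpha) {
  0.5 * drop(alpha %*% K %*% alpha)
}
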