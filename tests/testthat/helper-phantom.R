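# Shared fixtures: small single-slice phantoms keep the unit tests fast;
# the acceptance suite uses the full-size grid.

tiny_config <- function(...) phantom_config(nz = 1, ...)

# Independent FA/MD from eigenvalues (closed form, no package code)
fa_closed_form <- function(lam) {
  m <- mean(lam)
  sqrt(1.5 * sum((lam - m)^2) / sum(lam^2))
}

true_md_map <- function(truth) {
  array(truth$tensor[, , , 1] + truth$tensor[, , , 2] +
          truth$tensor[, , , 3], dim(truth$labels)) / 3
}

true_fa_map <- function(truth) {
  lam <- as.matrix(truth$truth[, c("lambda1", "lambda2", "lambda3")])
  fa <- apply(lam, 1, fa_closed_form)
  out <- array(NA_real_, dim(truth$labels))
  for (i in seq_len(nrow(truth$truth)))
    out[truth$labels == truth$truth$label[i]] <- fa[i]
  out
}

# Brute-force mid-rank assignment, independent of base R rank()
midrank_oracle <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

spearman_oracle <- function(x, y) {
  rx <- midrank_oracle(x); ry <- midrank_oracle(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive null distribution of the Wilcoxon signed-rank statistic
# (no ties, no zeros): all 2^n sign assignments.
signed_rank_p_oracle <- function(x, y) {
  d <- x - y
  r <- midrank_oracle(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_ge <- mean(vs >= v); p_le <- mean(vs <= v)
  min(1, 2 * min(p_ge, p_le))
}

# Exhaustive Mann-Whitney: all assignments of ranks to group 1.
mann_whitney_p_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- midrank_oracle(c(x, y))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # U statistic as in wilcox.test
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(i) sum(r[i])) - n * (n + 1) / 2
  p_ge <- mean(ws >= w); p_le <- mean(ws <= w)
  min(1, 2 * min(p_ge, p_le))
}
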