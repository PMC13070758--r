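# Shared fixture builders: tiny abundance tables and random logistic
# datasets, all generated in code.

# samples x taxa relative table from a plain matrix, rows renormalised
rel_table <- function(values, taxa, ids = sprintf("S%02d", seq_len(nrow(values)))) {
  values <- values / rowSums(values)
  abundance_table(values, ids, taxa, is_relative = TRUE)
}

# mark a table as relative without renormalising (for scale-property
# checks where rows deliberately do not sum to 1)
as_relative_unchecked <- function(tab) {
  tab$is_relative <- TRUE
  tab
}

lineage <- function(p, f, g) {
  sprintf("k__Bacteria;p__%s;c__C;o__O;f__%s;g__%s", p, f, g)
}

balance_taxa <- c(
  bif = lineage("Actinobacteriota", "Bifidobacteriaceae", "Bifidobacterium"),
  pha = lineage("Firmicutes", "Acidaminococcaceae", "Phascolarctobacterium"),
  lac = lineage("Firmicutes", "Lachnospiraceae", "Lachnoclostridium")
)

# random logistic dataset with a planted coefficient vector
random_logit_data <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta) - 1
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  prob <- plogis(beta[1] + drop(X %*% beta[-1]))
  list(X = X, y = rbinom(n, 1, prob), prob = prob)
}

# independent log-likelihood maximiser for the logistic model (oracle)
optim_logistic <- function(X, y) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X1)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# brute-force two-sided Fisher p: sum hypergeometric probabilities not
# exceeding that of the observed table
fisher_bruteforce <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(ks, r1, r2, c1)
  sum(pr[pr <= dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

# trapezoidal area under the empirical ROC curve (oracle for the
# rank-based AUC on tie-free scores)
roc_trapezoid <- function(scores, y) {
  ths <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(ths, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[y == 0] >= t), numeric(1))
  ord <- order(fpr, sens)
  sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
}
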