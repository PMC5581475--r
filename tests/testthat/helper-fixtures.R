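# Shared test fixtures, all generated in code.

# straight-chain record: residue k at (spacing * (k-1), 0, 0)
line_record <- function(L, spacing = 4, seq = NULL) {
  if (is.null(seq)) seq <- paste(rep("A", L), collapse = "")
  protein_record("line", seq, cbind((seq_len(L) - 1) * spacing, 0, 0))
}

# rank-based AUC of scores for logical labels
auc_of <- function(score, lab) {
  lab <- as.logical(lab)
  r <- rank(score)
  (mean(r[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
}

# small deterministic feature table: L x 32 of uniform noise
noise_table <- function(L, seed = 1) {
  with_seed(seed, {
    rec <- protein_record("noise", paste(sample(c("A", "G", "L", "S"), L,
                                                replace = TRUE), collapse = ""))
    pssm <- structure(list(scores = matrix(round(rnorm(L * 20, 0, 2)), L, 20),
                           info_per_pos = runif(L), rel_weight = runif(L),
                           sequence = rec$sequence),
                      class = "pssm_profile")
    ss <- paste(sample(c("H", "E", "C"), L, replace = TRUE), collapse = "")
    sa <- paste(sample(c("b", "e"), L, replace = TRUE), collapse = "")
    build_feature_table(rec, pssm, ss, sa)
  })
}

# independent convex oracle for the ranking-SVM objective: solve the primal
# QP in (w, xi) with quadprog (hinge constraints explicit, tiny ridge on xi
# so the Hessian is positive definite) and evaluate the true hinge objective
rank_svm_qp_oracle <- function(X, C, eps = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  D <- diag(c(rep(1, p), rep(eps, n)))
  d <- c(rep(0, p), rep(-C, n))
  A <- rbind(cbind(matrix(0, n, p), diag(n)),   # xi >= 0
             cbind(X, diag(n)))                 # X w + xi >= 1
  b <- c(rep(0, n), rep(1, n))
  sol <- quadprog::solve.QP(D, d, t(A), b)
  w <- sol$solution[1:p]
  list(w = w, objective = rank_svm_objective(w, X, C))
}

# cache heavyweight shared fixtures across test files within one run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}
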