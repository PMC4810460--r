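# Shared fixtures, built in code at test time.

# mixed supergaussian (Laplacian) sources with a random square mixing,
# whitened: the canonical ICA recovery fixture
whitened_sources <- function(C = 3, N = 2000, seed = 3) {
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), C * N, TRUE) * stats::rexp(C * N), C)
  A <- matrix(stats::rnorm(C * C), C)
  X <- A %*% S
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc) / N, symmetric = TRUE)
  list(S = S, A = A,
       Xw = diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% Xc)
}

# small noiseless cohort without the patient coupling deficit: exact rank-k
noiseless_config <- function(seed = 11, ...) {
  cohort_config(n_control = 2, n_patient = 2, noise_sd = 0,
                intra_deficit = list(component = 1, n_voxels = 30,
                                     scale = c(control = 1, patient = 1)),
                seed = seed, ...)
}

# covariates with no built-in group effect, for inference fixtures
null_covariates <- function(n_control, n_patient, seed = 1) {
  set.seed(seed)
  n <- n_control + n_patient
  data.frame(group = factor(rep(c("control", "patient"), c(n_control, n_patient)),
                            levels = c("control", "patient")),
             age = stats::rnorm(n, 52, 7),
             gender = stats::rbinom(n, 1, 0.5),
             education = stats::rnorm(n, 11, 2.5))
}

# best-match absolute correlations between two map stacks (rows = maps)
matched_abs_cor <- function(est, truth) {
  cc <- abs(stats::cor(t(est), t(truth)))
  apply(cc, 2, max)
}
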