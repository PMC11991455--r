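# Shared fixtures: small random SPD matrices and sets, built in code.

rand_spd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n)
  S <- scale * (crossprod(A) / n + 0.5 * diag(n))
  (S + t(S)) / 2
}

rand_spd_set <- function(K, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov_set(lapply(seq_len(K), function(i) rand_spd(n)), validate = FALSE)
}

# brute-force AUC over all positive-negative pairs (independent oracle)
auc_brute <- function(scores, labels) {
  labels <- factor(labels)
  sp <- scores[labels == levels(labels)[2]]
  sn <- scores[labels == levels(labels)[1]]
  cnt <- 0
  for (a in sp) for (b in sn) cnt <- cnt + (a > b) + 0.5 * (a == b)
  cnt / (length(sp) * length(sn))
}

hkey <- function(h) formatC(h, format = "g")

field_mean <- function(field, class, h) field$means[[class]][[hkey(h)]]
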