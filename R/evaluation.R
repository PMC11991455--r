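# Within-session stratified k-fold cross-validation with AUC-ROC, and the
# meta-analytic comparison statistics: exact paired permutation test (fewer
# than 20 subjects), Wilcoxon signed-rank (20 or more), weighted Liptak
# p-value combination, and standardized-mean-difference aggregation with
# weights sqrt(number of subjects).

# Evaluate an expression with a private RNG stream, restoring the caller's
# generator state afterwards: fold assignment and simulation are pure
# functions of their seed argument.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified k-fold assignment
#'
#' Deterministic stratified fold assignment: a pure function of
#' `(labels, k, seed)`, so every pipeline compared on the same data sees
#' identical folds. Class proportions per fold match the global proportions
#' within one trial.
#'
#' @param labels class labels (factor or coercible).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..k`, one per trial.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop(sprintf("every class needs at least k = %d members (smallest has %d)",
                 k, min(tab)))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks:
#' \eqn{P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)} over all positive-negative
#' pairs. The positive class is the second factor level.
#'
#' @param scores numeric scores, larger = more positive-class.
#' @param labels binary labels; second level (or `TRUE`) is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly 2 classes required")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact paired permutation test (one-sided)
#'
#' Enumerates all \eqn{2^n} sign assignments of the paired differences and
#' returns the fraction whose mean is at least the observed mean (the
#' observed assignment included). Exact and deterministic; restricted to
#' n < 20 where full enumeration is the intended regime — for larger n use
#' [wilcoxon_signed_rank()].
#'
#' @param diffs paired differences (alternative: positive location).
#' @return one-sided p-value.
#' @export
paired_permutation_test <- function(diffs) {
  n <- length(diffs)
  if (n < 1L) stop("need at least one difference")
  if (n >= 20L)
    stop("n >= 20: use wilcoxon_signed_rank() (enumeration regime is n < 20)")
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  sums <- as.vector(signs %*% diffs)
  obs <- sum(diffs)
  eps <- 1e-12 * max(1, sum(abs(diffs)))
  mean(sums >= obs - eps)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Zeros dropped, ties midranked, normal approximation with tie-corrected
#' variance and continuity correction (delegated to [stats::wilcox.test()]).
#' The all-zero degenerate case returns p = 1 with a warning.
#'
#' @param diffs paired differences (alternative: positive location).
#' @return one-sided p-value.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  if (all(diffs == 0)) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(diffs, alternative = "greater", mu = 0,
                       exact = FALSE, correct = TRUE)$p.value
  )
}

# Dispatch rule: exact enumeration below 20 subjects, rank test otherwise.
paired_pvalue <- function(diffs) {
  if (length(diffs) < 20L) paired_permutation_test(diffs)
  else wilcoxon_signed_rank(diffs)
}

#' Weighted Liptak (Stouffer) combination of one-sided p-values
#'
#' \eqn{z_i = \Phi^{-1}(1 - p_i)}; combined
#' \eqn{z = \sum w_i z_i / \sqrt{\sum w_i^2}}; returns \eqn{1 - \Phi(z)}.
#' p-values are clipped to `[1e-15, 1 - 1e-15]` before the transform.
#'
#' @param pvals one-sided p-values in (0, 1).
#' @param weights positive weights (for database combination: the square
#'   root of the number of subjects per database).
#' @return combined one-sided p-value.
#' @export
liptak_combine <- function(pvals, weights = rep(1, length(pvals))) {
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (length(weights) != length(pvals) || any(weights <= 0))
    stop("weights must be positive, one per p-value")
  p <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(1 - p)
  1 - stats::pnorm(sum(weights * z) / sqrt(sum(weights^2)))
}

#' Standardized-mean-difference meta-analysis of paired scores
#'
#' Per database: SMD = mean(paired differences) / sd(paired differences)
#' (sd divisor n - 1), 95% CI via
#' \eqn{\mathrm{SMD} \pm 1.96 \sqrt{1/n + \mathrm{SMD}^2/(2n)}}, and a
#' one-sided p-value (exact permutation below 20 subjects, Wilcoxon
#' signed-rank otherwise). Databases are combined with weights
#' \eqn{w_d = \sqrt{n_d}}: combined SMD is the weighted arithmetic mean and
#' the combined p-value the weighted Liptak combination. Databases with
#' fewer than 2 subjects are excluded with a warning; a database with
#' zero-variance differences reports SMD 0 with an infinite-width CI flag.
#'
#' @param scores_a,scores_b per-subject scores, as a list of numeric
#'   vectors (one element per database) for pipelines A and B; the tested
#'   alternative is B > A.
#' @param databases optional database names.
#' @return object of class `meta_analysis`: per-database table plus
#'   combined SMD and p-value.
#' @export
smd_meta <- function(scores_a, scores_b, databases = NULL) {
  if (is.numeric(scores_a)) scores_a <- list(scores_a)
  if (is.numeric(scores_b)) scores_b <- list(scores_b)
  if (length(scores_a) != length(scores_b))
    stop("scores_a and scores_b must have one element per database")
  nd <- length(scores_a)
  if (is.null(databases)) databases <- paste0("db", seq_len(nd))
  rows <- list()
  for (d in seq_len(nd)) {
    if (length(scores_a[[d]]) != length(scores_b[[d]]))
      stop("paired scores must have equal length within a database")
    diffs <- scores_b[[d]] - scores_a[[d]]
    n <- length(diffs)
    if (n < 2L) {
      warning(sprintf("database '%s' has fewer than 2 subjects; excluded",
                      databases[d]))
      next
    }
    s <- stats::sd(diffs)
    degenerate <- !is.finite(s) || s < 1e-12
    smd <- if (degenerate) 0 else mean(diffs) / s
    half <- if (degenerate) Inf else 1.96 * sqrt(1 / n + smd^2 / (2 * n))
    rows[[length(rows) + 1L]] <- data.frame(
      database = databases[d], n = n, smd = smd,
      ci_lo = smd - half, ci_hi = smd + half,
      p = paired_pvalue(diffs), weight = sqrt(n),
      degenerate = degenerate)
  }
  if (length(rows) == 0L) stop("no database with at least 2 subjects")
  tab <- do.call(rbind, rows)
  w <- tab$weight
  structure(list(per_database = tab,
                 combined_smd = sum(w * tab$smd) / sum(w),
                 combined_p = liptak_combine(tab$p, w)),
            class = "meta_analysis")
}

#' @export
print.meta_analysis <- function(x, ...) {
  cat("Meta-analysis of paired pipeline scores (alternative: B > A)\n")
  print(x$per_database, row.names = FALSE, digits = 4)
  cat(sprintf("combined SMD = %.4f, combined one-sided p = %.4g\n",
              x$combined_smd, x$combined_p))
  invisible(x)
}

# ---- Cross-validated benchmarking ----------------------------------------

fit_pipeline <- function(train, pipeline, h_values, tol, maxit, robust,
                         adcsp) {
  filt <- NULL
  if (adcsp) {
    filt <- adcsp_fit(train, tol = tol, maxit = maxit)
    train <- apply_filter(filt, train)
  }
  model <- switch(pipeline,
    mdm = mdm(train, tol = tol, maxit = maxit, robust = robust),
    mdmf = mdmf(train, h_values, tol, maxit, robust = robust),
    mf = mf(train, h_values, tol, maxit, robust = robust),
    stop(sprintf("unknown pipeline '%s'", pipeline)))
  list(model = model, filter = filt)
}

predict_pipeline <- function(fit, test) {
  if (!is.null(fit$filter)) test <- apply_filter(fit$filter, test)
  predict(fit$model, test)
}

#' Cross-validated AUC for one pipeline
#'
#' Stratified k-fold cross-validation on a labeled covariance set. Any
#' spatial filter is fitted on the training folds only and applied to the
#' test fold by congruence. For two classes the per-fold AUC-ROC is
#' computed from the pipeline's continuous score; for more classes a
#' one-versus-rest macro-averaged AUC over the per-class score columns.
#'
#' @param set labeled [cov_set()].
#' @param pipeline one of `"mdm"`, `"mdmf"`, `"mf"`.
#' @param k folds (default 5).
#' @param seed fold seed; identical seeds give identical folds across
#'   pipelines.
#' @param h_values,tol,maxit,robust,adcsp pipeline options.
#' @return data frame with one row per fold: `fold`, `auc`.
#' @export
cross_val_auc <- function(set, pipeline = c("mf", "mdmf", "mdm"), k = 5L,
                          seed = 1L, h_values = default_h_field(),
                          tol = 1e-7, maxit = 150L, robust = FALSE,
                          adcsp = FALSE) {
  pipeline <- match.arg(pipeline)
  check_set(set)
  fold <- stratified_kfold(set$labels, k, seed)
  auc <- vapply(seq_len(k), function(f) {
    train <- subset_cov_set(set, which(fold != f))
    test <- subset_cov_set(set, which(fold == f))
    fit <- fit_pipeline(train, pipeline, h_values, tol, maxit, robust,
                        adcsp)
    pred <- predict_pipeline(fit, test)
    fold_auc(pred, test$labels)
  }, numeric(1))
  data.frame(fold = seq_len(k), auc = auc)
}

fold_auc <- function(pred, labels) {
  if (nlevels(labels) == 2L) return(auc_roc(pred$score, labels))
  # one-versus-rest macro average over predicted class indicators is not
  # continuous; use the per-class score columns when present
  stop("multi-class AUC requires per-class scores; use binary problems")
}

#' Benchmark several pipelines on identical folds
#'
#' Runs [cross_val_auc()] for each requested pipeline with the same fold
#' seed (the folds are a pure function of labels, k and seed, so all
#' pipelines see identical splits) and returns a tidy score table. Fully
#' deterministic: two runs on identical input are bitwise identical.
#'
#' @param set labeled [cov_set()].
#' @param pipelines character vector among `"mdm"`, `"mdmf"`, `"mf"`.
#' @param k,seed,h_values,tol,maxit,robust,adcsp see [cross_val_auc()].
#' @param database,subject,session identifiers recorded in the table.
#' @return data frame with columns database, subject, session, pipeline,
#'   fold, auc.
#' @export
benchmark_pipelines <- function(set, pipelines = c("mdm", "mdmf", "mf"),
                                k = 5L, seed = 1L,
                                h_values = default_h_field(), tol = 1e-7,
                                maxit = 150L, robust = FALSE,
                                adcsp = FALSE, database = "synthetic",
                                subject = 1L, session = 1L) {
  out <- lapply(pipelines, function(p) {
    cv <- cross_val_auc(set, p, k, seed, h_values, tol, maxit, robust,
                        adcsp)
    data.frame(database = database, subject = subject, session = session,
               pipeline = p, fold = cv$fold, auc = cv$auc)
  })
  do.call(rbind, out)
}

#' Compare two pipelines from a score table
#'
#' Averages AUC per (database, subject) for each pipeline, forms paired
#' differences per database, and runs [smd_meta()] (alternative:
#' `pipeline_b` better than `pipeline_a`).
#'
#' @param scores score table as returned by [benchmark_pipelines()].
#' @param pipeline_a,pipeline_b pipeline identifiers found in the table.
#' @return a `meta_analysis`.
#' @export
compare_score_tables <- function(scores, pipeline_a, pipeline_b) {
  per_subject <- function(p) {
    s <- scores[scores$pipeline == p, ]
    if (nrow(s) == 0L) stop(sprintf("pipeline '%s' not in table", p))
    stats::aggregate(auc ~ database + subject, data = s, FUN = mean)
  }
  a <- per_subject(pipeline_a)
  b <- per_subject(pipeline_b)
  m <- merge(a, b, by = c("database", "subject"),
             suffixes = c("_a", "_b"))
  dbs <- sort(unique(m$database))
  smd_meta(split(m$auc_a, factor(m$database, dbs)),
           split(m$auc_b, factor(m$database, dbs)), databases = dbs)
}
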