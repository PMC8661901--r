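#' Choose the SVM validation scheme from the group sizes
#'
#' Small cohorts (at most 15 animals per group) use the non-exhaustive
#' two-out strategy — repeatedly holding out one animal per group — while
#' larger cohorts afford a completely independent test set.
#'
#' @param n_per_group integer vector of per-group sample sizes.
#' @return `"two_out"` or `"holdout"`.
#' @export
choose_scheme <- function(n_per_group) {
  if (any(n_per_group < 3)) {
    bseq_abort("need at least 3 animals per group", "group_too_small")
  }
  if (min(n_per_group) <= 15) "two_out" else "holdout"
}

#' Cohen's kappa for pooled predictions
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the pooled
#' confusion matrix; returns 1 when observed and expected agreement are
#' both perfect.
#'
#' @param truth,pred factors/characters of equal length.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(truth, pred) {
  lev <- union(as.character(truth), as.character(pred))
  tab <- table(factor(truth, lev), factor(pred, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

# fit an SVM on the training fold (dropping zero-variance features, which
# e1071's internal scaling cannot handle) and predict the test fold
svm_fold <- function(Xtr, ytr, Xte, kernel) {
  keep <- apply(Xtr, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) {
    return(factor(rep(names(which.max(table(ytr))), nrow(Xte)), levels(ytr)))
  }
  fit <- e1071::svm(x = Xtr[, keep, drop = FALSE], y = ytr, kernel = kernel,
                    cost = 1, scale = TRUE)
  predict(fit, Xte[, keep, drop = FALSE])
}

#' SVM group prediction with two-out or holdout validation
#'
#' Trains a support vector machine (radial or linear kernel, cost 1,
#' features standardized on the training fold via the fitter's scaling) to
#' predict group membership, and validates it:
#' \describe{
#'   \item{two_out}{`repeats` random cross-group pairs (one held-out animal
#'     per group, sampled without replacement over distinct pairs, so the
#'     procedure is non-exhaustive); predictions pooled over repeats.}
#'   \item{holdout}{one stratified split with `holdout_fraction` of each
#'     group as an independent test set.}
#' }
#' Accuracy and Cohen's kappa are computed on the pooled predictions.
#'
#' @param matrix feature matrix with exactly 2 groups.
#' @param kernel `"radial"` or `"linear"`.
#' @param scheme `"two_out"`, `"holdout"`, or `NULL` to pick via
#'   [choose_scheme()].
#' @param seed integer seed.
#' @param repeats two-out repeats (capped at the number of distinct pairs).
#' @param holdout_fraction test fraction for the holdout scheme.
#' @return an `ml_result`: list with `predictions` (tibble `truth`,
#'   `pred`), `accuracy`, `kappa`, `kernel`, `scheme`, `repeats`, `seed`.
#' @export
svm_validate <- function(matrix, kernel = c("radial", "linear"), scheme = NULL,
                         seed = 1L, repeats = 100L, holdout_fraction = 1 / 3) {
  kernel <- match.arg(kernel)
  y <- factor(matrix$group)
  if (nlevels(y) != 2) {
    bseq_abort("svm_validate needs exactly two groups; see pairwise_groups()",
               "non_binary")
  }
  if (repeats < 1) bseq_abort("repeats must be >= 1", "bad_repeats")
  scheme <- scheme %||% choose_scheme(as.integer(table(y)))
  scheme <- match.arg(scheme, c("two_out", "holdout"))
  X <- as.matrix(matrix[feature_cols(matrix)])
  set.seed(seed)
  res <- run_validation(X, y, kernel, scheme, repeats, holdout_fraction,
                        permute_train = FALSE)
  structure(list(predictions = res$predictions,
                 accuracy = res$accuracy,
                 kappa = cohen_kappa(res$predictions$truth, res$predictions$pred),
                 kernel = kernel, scheme = scheme,
                 repeats = if (scheme == "two_out") res$repeats else NA_integer_,
                 seed = seed),
            class = "ml_result")
}

# one full validation pass; assumes the RNG is already positioned.
# permute_train shuffles the training labels after each split (the
# permutation-null variant); permute_all shuffles all labels up front.
run_validation <- function(X, y, kernel, scheme, repeats, holdout_fraction,
                           permute_train = FALSE, permute_all = FALSE) {
  if (permute_all) y <- sample(y)
  idx1 <- which(y == levels(y)[1])
  idx2 <- which(y == levels(y)[2])
  if (scheme == "two_out") {
    pairs <- expand.grid(i = idx1, j = idx2)
    reps <- min(repeats, nrow(pairs))
    pairs <- pairs[sample.int(nrow(pairs), reps), , drop = FALSE]
    truth <- pred <- character(0)
    for (r in seq_len(reps)) {
      te <- c(pairs$i[r], pairs$j[r])
      ytr <- y[-te]
      if (permute_train) ytr <- sample(ytr)
      p <- svm_fold(X[-te, , drop = FALSE], ytr, X[te, , drop = FALSE], kernel)
      truth <- c(truth, as.character(y[te]))
      pred <- c(pred, as.character(p))
    }
    out <- tibble(truth = truth, pred = pred)
    list(predictions = out, accuracy = mean(out$truth == out$pred), repeats = reps)
  } else {
    te <- c(sample(idx1, max(1, round(length(idx1) * holdout_fraction))),
            sample(idx2, max(1, round(length(idx2) * holdout_fraction))))
    ytr <- y[-te]
    if (permute_train) ytr <- sample(ytr)
    p <- svm_fold(X[-te, , drop = FALSE], ytr, X[te, , drop = FALSE], kernel)
    out <- tibble(truth = as.character(y[te]), pred = as.character(p))
    list(predictions = out, accuracy = mean(out$truth == out$pred), repeats = NA_integer_)
  }
}

#' Permutation null and binomial-CI p-value range for the SVM validation
#'
#' Computes the observed pooled validation accuracy once, then repeats the
#' entire validation `n_perm` times with the training labels randomly
#' permuted after each split (set `perm_scope = "all"` to instead shuffle
#' all labels before splitting). The exceedance count
#' `k = #\{permuted accuracy >= observed\}` gives the point estimate
#' `p = (k + 1) / (n_perm + 1)` and a 95% Clopper-Pearson confidence
#' interval for `k / n_perm` — the reported p-value range. The number of
#' permutations is reported alongside.
#'
#' @inheritParams svm_validate
#' @param n_perm number of label permutations.
#' @param perm_scope `"train"` (default) or `"all"`.
#' @return an `ml_result` with additional fields `perm_accuracies`,
#'   `n_exceed`, `p`, `p_range`, `n_permutations`, `perm_scope`.
#' @export
permutation_pvalue <- function(matrix, kernel = c("radial", "linear"),
                               scheme = NULL, n_perm = 100L, seed = 1L,
                               repeats = 100L, holdout_fraction = 1 / 3,
                               perm_scope = c("train", "all")) {
  kernel <- match.arg(kernel)
  perm_scope <- match.arg(perm_scope)
  if (n_perm < 10) bseq_warn("fewer than 10 permutations: p-value range is crude",
                             "few_permutations")
  obs <- svm_validate(matrix, kernel = kernel, scheme = scheme, seed = seed,
                      repeats = repeats, holdout_fraction = holdout_fraction)
  X <- as.matrix(matrix[feature_cols(matrix)])
  y <- factor(matrix$group)
  perm_acc <- vapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    run_validation(X, y, kernel, obs$scheme, repeats, holdout_fraction,
                   permute_train = perm_scope == "train",
                   permute_all = perm_scope == "all")$accuracy
  }, numeric(1))
  k <- sum(perm_acc >= obs$accuracy)
  ci <- binom.test(k, n_perm)$conf.int
  out <- c(unclass(obs),
           list(perm_accuracies = perm_acc, n_exceed = k,
                p = (k + 1) / (n_perm + 1),
                p_range = c(lower = ci[1], upper = ci[2]),
                n_permutations = as.integer(n_perm), perm_scope = perm_scope))
  class(out) <- "ml_result"
  out
}

#' @export
print.ml_result <- function(x, ...) {
  cat("<ml_result>", x$kernel, "SVM,", x$scheme, "validation\n  accuracy =",
      signif(x$accuracy, 3), ", kappa =", signif(x$kappa, 3), "\n")
  if (!is.null(x$n_permutations)) {
    cat("  p =", signif(x$p, 3), " range [", signif(x$p_range[1], 3), ",",
        signif(x$p_range[2], 3), "] from", x$n_permutations, "permutations\n")
  }
  invisible(x)
}

#' Split a 2- or 3-group feature matrix into group pairs
#'
#' The analysis handles at most three experimental groups; with three, it is
#' run on every unordered pair.
#'
#' @param matrix feature matrix.
#' @return named list of 2-group feature matrices (`"A_vs_B"`).
#' @export
pairwise_groups <- function(matrix) {
  g <- unique(as.character(matrix$group))
  if (length(g) > 3) {
    bseq_abort("more than three groups are not supported", "too_many_groups")
  }
  if (length(g) < 2) bseq_abort("need at least two groups", "single_group")
  combs <- utils::combn(sort(g), 2, simplify = FALSE)
  out <- lapply(combs, function(p) matrix[matrix$group %in% p, , drop = FALSE])
  names(out) <- vapply(combs, paste, character(1), collapse = "_vs_")
  out
}
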