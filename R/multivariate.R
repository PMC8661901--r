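#' Double random-forest variable selection
#'
#' Two sequential classification forests rank the feature columns by mean
#' decrease in Gini impurity. The first forest, fit on all variables, keeps
#' the best 20; the second forest re-ranks those 20 and the best eight
#' variables — or all variables whose second-pass importance, normalized by
#' its maximum, exceeds 0.95, whichever set is larger — are kept for the
#' ICA embedding. The selection therefore always has between 8 and 20
#' variables (when at least 8 exist). Ties are broken by variable name.
#'
#' @param matrix feature matrix with >= 2 groups, >= 2 rows per group.
#' @param seed integer seed (forests are stochastic).
#' @param ntree trees per forest.
#' @param gini_threshold normalized second-pass importance cutoff.
#' @return an `rf_selection`: list with `selected` (character), `pass1`,
#'   `pass2` (tibbles `variable`, `importance`, ranked), `seed`.
#' @export
rf_select <- function(matrix, seed = 1L, ntree = 500L, gini_threshold = 0.95) {
  cols <- feature_cols(matrix)
  y <- factor(matrix$group)
  if (nlevels(y) < 2) bseq_abort("need at least two groups", "single_group")
  if (any(table(y) < 2)) bseq_abort("need >= 2 rows per group", "group_too_small")
  if (length(cols) < 2) bseq_abort("need at least two variables", "too_few_variables")
  X <- as.data.frame(matrix[cols])

  rank_imp <- function(fit) {
    imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    tibble(variable = names(imp), importance = unname(imp)) %>%
      arrange(desc(.data$importance), .data$variable)
  }

  set.seed(seed)
  r1 <- rank_imp(randomForest::randomForest(x = X, y = y, ntree = ntree))
  top20 <- head(r1$variable, 20L)

  set.seed(seed + 1L)
  r2 <- rank_imp(randomForest::randomForest(x = X[top20], y = y, ntree = ntree))
  r2 <- mutate(r2, normalized = .data$importance / max(.data$importance))
  above <- r2$variable[r2$normalized > gini_threshold]
  top8 <- head(r2$variable, min(8L, nrow(r2)))
  selected <- if (length(above) > length(top8)) above else top8

  structure(list(selected = sort(selected), pass1 = r1, pass2 = r2,
                 ntree = ntree, gini_threshold = gini_threshold, seed = seed),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat("<rf_selection>", length(x$selected), "of", nrow(x$pass1),
      "variables (seed", paste0(x$seed, "):\n  "),
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Three-component ICA embedding of the selected variables
#'
#' Runs FastICA on the column-centered selected features and returns the
#' first three independent components per animal, for interactive 3-D
#' visualization of group structure. If the centered data have rank below
#' three, the embedding falls back to the available rank with a warning.
#'
#' @param matrix feature matrix.
#' @param selected character vector of >= 3 feature columns (e.g.
#'   `rf_select(...)$selected`).
#' @param seed integer seed (ICA initialization is stochastic).
#' @return `ica_embedding`: tibble `animal_id`, `test_id`, `group`,
#'   `IC1..IC3`; attributes `mixing` (components x variables) and `center`.
#' @export
ica_embed <- function(matrix, selected, seed = 1L) {
  if (length(selected) < 3) bseq_abort("need at least three selected variables",
                                       "too_few_variables")
  X <- as.matrix(matrix[selected])
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  rk <- qr(Xc)$rank
  nc <- 3L
  if (rk < 3) {
    bseq_warn(paste0("centered data rank ", rk, " < 3; embedding in ", rk,
                     " component(s)"), "low_rank")
    nc <- rk
  }
  set.seed(seed)
  fit <- ica::icafast(Xc, nc = nc)
  S <- fit$S
  colnames(S) <- paste0("IC", seq_len(ncol(S)))
  out <- bind_cols(matrix[intersect(c("animal_id", "test_id", "group"),
                                    names(matrix))], as_tibble(S))
  attr(out, "mixing") <- t(fit$M)
  attr(out, "center") <- ctr
  attr(out, "seed") <- seed
  class(out) <- c("ica_embedding", class(out))
  out
}

#' PCA first-component nonparametric group test
#'
#' The guard against p-hacking over up to 162 behavior variables: a single
#' pre-registered test. Features are column-centered (they already share the
#' sqrt-proportion scale, so no rescaling) and projected onto the first
#' principal component; PC1 scores are then compared across groups with a
#' nonparametric rank test. For two groups this is a two-sided Wilcoxon
#' rank-sum with normal approximation and tie correction, reported as Z, p,
#' and the effect size r = |Z| / sqrt(n); for three groups a Kruskal-Wallis
#' test (no r). More than three groups is an error.
#'
#' @param matrix feature matrix with a `group` column (2 or 3 levels).
#' @return a `group_test`: list with `scores` (tibble incl. `pc1`),
#'   `var_explained`, `method`, `Z`, `p`, `effect_size_r`, `n`.
#' @export
pca_group_test <- function(matrix) {
  cols <- feature_cols(matrix)
  y <- factor(matrix$group)
  k <- nlevels(y)
  if (k < 2) bseq_abort("need at least two groups", "single_group")
  if (k > 3) {
    bseq_abort("more than three groups are not supported; split into pairs",
               "too_many_groups")
  }
  X <- as.matrix(matrix[cols])
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n <- length(pc1)

  if (k == 2) {
    rst <- rank_sum_z(pc1[y == levels(y)[1]], pc1[y == levels(y)[2]])
    res <- list(method = "Wilcoxon rank-sum (normal approximation, tie-corrected)",
                Z = rst$Z, p = rst$p, effect_size_r = abs(rst$Z) / sqrt(n))
  } else {
    kt <- kruskal.test(pc1, y)
    res <- list(method = "Kruskal-Wallis rank-sum", Z = unname(kt$statistic),
                p = kt$p.value, effect_size_r = NA_real_)
  }
  scores <- bind_cols(matrix[intersect(c("animal_id", "test_id", "group"),
                                       names(matrix))], tibble(pc1 = unname(pc1)))
  structure(c(list(scores = scores, var_explained = ve, n = n), res),
            class = "group_test")
}

# two-sided rank-sum Z with tie correction; Z = 0 when all values tie
rank_sum_z <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(v)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(Z = 0, p = 1))
  Z <- (W - mu) / sqrt(sig2)
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test>", x$method, "\n  PC1 explains",
      sprintf("%.1f%%", 100 * x$var_explained[1]), "of variance; Z =",
      signif(x$Z, 4), ", p =", signif(x$p, 4))
  if (!is.na(x$effect_size_r)) cat(", r = Z/sqrt(n) =", signif(x$effect_size_r, 3))
  cat("\n")
  invisible(x)
}
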