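# k-fold cross-validated hyperparameter selection for the gamma-learning
# kernel: grid and randomized searches scored by RMSE on flattened 1-RDM
# residuals (the field's negative-RMSE convention, stored positive here and
# minimized).

#' Hyperparameter search space
#'
#' @param kinds kernel kinds to consider.
#' @param alphas ridge grid; the defaults include the two canonical values
#'   0.0 and 0.1.
#' @param gamma_factors multiples of the data-set default
#'   `Gamma = 1/N_features`.
#' @param k number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return a `search_space`.
#' @export
search_space <- function(kinds = c("LIN", "POL", "RBF"),
                         alphas = c(0, 1e-6, 1e-4, 1e-2, 0.1, 1),
                         gamma_factors = c(0.1, 0.3, 1, 3, 10),
                         k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (!length(kinds) || !length(alphas) || !length(gamma_factors))
    stop("empty search space")
  structure(list(kinds = kinds, alphas = alphas,
                 gamma_factors = gamma_factors, k = as.integer(k),
                 seed = as.integer(seed)), class = "search_space")
}

# contiguous fold blocks after one seeded shuffle; folds are fixed across
# candidates so comparisons are paired
make_folds <- function(n, k, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  split(idx, cut(seq_len(n), breaks = k, labels = FALSE))
}

#' Cross-validated RMSE of a kernel spec
#'
#' Mean over folds of the RMSE of flattened 1-RDM residuals on the held-out
#' fold; deterministic given the fold seed.
#'
#' @param ts a `training_set`.
#' @param k a [kernel_spec()].
#' @param folds number of folds.
#' @param seed fold seed.
#' @return mean CV RMSE (per matrix element).
#' @export
cv_score <- function(ts, k, folds = 5L, seed = 1L) {
  n <- nrow(ts$X)
  if (n < folds) stop("fewer records than folds")
  fl <- make_folds(n, folds, seed)
  rmses <- vapply(fl, function(hold) {
    tr <- setdiff(seq_len(n), hold)
    sub <- ts
    sub$X <- ts$X[tr, , drop = FALSE]; sub$Y <- ts$Y[tr, , drop = FALSE]
    model <- fit_gamma(sub, k)
    pred <- kernel_matrix(ts$X[hold, , drop = FALSE], sub$X, model$kernel) %*%
      model$B
    sqrt(mean((pred - ts$Y[hold, , drop = FALSE])^2))
  }, 0)
  mean(rmses)
}

expand_candidates <- function(ts, space) {
  nf <- ncol(ts$X)
  g0 <- 1 / nf
  out <- list()
  for (kind in space$kinds)
    for (a in space$alphas)
      for (gf in space$gamma_factors) {
        # Gamma only matters for RBF/POL; collapse duplicates for LIN
        if (kind == "LIN" && gf != 1) next
        out[[length(out) + 1L]] <-
          kernel_spec(kind, alpha = a, gamma_scale = gf * g0)
      }
  out
}

rank_candidates <- function(cands, scores) {
  # ties broken toward smaller alpha, then simpler kernel LIN < POL < RBF
  kind_rank <- vapply(cands, function(k)
    match(k$kind, c("LIN", "POL", "RBF")), 0)
  alphas <- vapply(cands, function(k) k$alpha, 0)
  order(scores, alphas, kind_rank)
}

#' Grid search over the kernel space
#'
#' Exhaustive evaluation of every candidate with fixed folds; ties are
#' broken toward smaller alpha, then the simpler kernel.
#'
#' @param ts a `training_set`.
#' @param space a [search_space()].
#' @return list `best` ([kernel_spec()]), `table` (data.frame of candidates
#'   and scores).
#' @export
grid_search_kernel <- function(ts, space) {
  cands <- expand_candidates(ts, space)
  if (!length(cands)) stop("empty search space")
  scores <- vapply(cands, function(k)
    cv_score(ts, k, folds = space$k, seed = space$seed), 0)
  ord <- rank_candidates(cands, scores)
  tab <- data.frame(
    kind = vapply(cands, function(k) k$kind, ""),
    alpha = vapply(cands, function(k) k$alpha, 0),
    gamma_scale = vapply(cands, function(k) k$gamma_scale %||% NA_real_, 0),
    cv_rmse = scores)
  list(best = cands[[ord[1]]], table = tab[ord, ])
}

#' Randomized search over the kernel space
#'
#' Draws `n_draws` candidates uniformly over the kinds/alpha grid and
#' log-uniformly between the extreme Gamma factors; seeded.
#'
#' @inheritParams grid_search_kernel
#' @param n_draws number of sampled candidates.
#' @param seed draw seed.
#' @return as [grid_search_kernel()].
#' @export
randomized_search_kernel <- function(ts, space, n_draws = 50L, seed = 1L) {
  nf <- ncol(ts$X); g0 <- 1 / nf
  set.seed(seed)
  lg <- log(range(space$gamma_factors))
  cands <- lapply(seq_len(n_draws), function(i) {
    kind <- sample(space$kinds, 1)
    a <- sample(space$alphas, 1)
    gf <- if (lg[1] == lg[2]) exp(lg[1]) else exp(stats::runif(1, lg[1], lg[2]))
    kernel_spec(kind, alpha = a,
                gamma_scale = if (kind == "LIN") g0 else gf * g0)
  })
  scores <- vapply(cands, function(k)
    cv_score(ts, k, folds = space$k, seed = space$seed), 0)
  ord <- rank_candidates(cands, scores)
  tab <- data.frame(
    kind = vapply(cands, function(k) k$kind, ""),
    alpha = vapply(cands, function(k) k$alpha, 0),
    gamma_scale = vapply(cands, function(k) k$gamma_scale, 0),
    cv_rmse = scores)
  list(best = cands[[ord[1]]], table = tab[ord, ])
}

#' Write a search result table to a tab-separated audit file
#' @param result output of a search.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_search_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
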