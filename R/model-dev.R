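# Model development: Lasso feature ranking, cross-validated subset
# search, and train/test evaluation. The Lasso path and CV come from
# glmnet; OLS fitting is fit_cre_model().

# numeric feature matrix + aligned target, dropping ids, non-numeric
# and all-constant columns (warned) and incomplete rows
.feature_matrix <- function(data, target, drop = c("child_id", "id")) {
  if (is.character(target) && length(target) == 1) {
    .need_cols(data, target, "feature matrix")
    y <- data[[target]]
    data <- data[setdiff(names(data), target)]
  } else {
    y <- as.numeric(target)
  }
  data <- data[setdiff(names(data), drop)]
  num <- vapply(data, is.numeric, logical(1))
  data <- data[num]
  keep <- stats::complete.cases(data) & is.finite(y)
  x <- as.matrix(data[keep, , drop = FALSE])
  y <- y[keep]
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding all-constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  list(x = x, y = y)
}

#' Lasso-based feature ranking
#'
#' Ranks candidate features for predicting one-day creatinine excretion
#' using the Lasso regularization path with the penalty tuned by k-fold
#' cross-validation (logarithmic lambda grid, 100 points, MSE loss;
#' 1-SE rule available). Features are centred/scaled inside the Lasso
#' only.
#'
#' Ranking semantics (\code{ranker = "path"}, default): features are
#' ordered by the step at which they first enter the Lasso path as the
#' penalty relaxes (earliest entry = most important), with features
#' entering at the same grid step sharing a group. The rank-1 group is
#' then the shortest CV-optimal prefix of that ordering: for every
#' candidate number of leading features (by whole entry groups, plus the
#' empty model), an OLS refit on the prefix is scored by k-fold
#' out-of-fold R-squared, and the prefix with the best mean score forms
#' rank 1. This follows the usual practice of examining how the number
#' of selected features affects cross-validated fit, and it is robust to
#' near-collinear features trading places deep in the path. Remaining
#' features take ranks 2, 3, ... by entry group; features that never
#' enter the path share the last rank, and exactly duplicated columns
#' always share a rank. \code{ranker = "coef"} instead ranks by the
#' magnitude of the standardized coefficient at the CV-tuned lambda.
#'
#' @param data data.frame of candidate features (non-numeric and id
#'   columns are dropped; all-constant columns excluded with a warning).
#' @param target numeric response (mg/day) or the name of a column of
#'   \code{data}.
#' @param cv_folds number of CV folds (default 20).
#' @param seed integer seed (mandatory; controls fold assignment).
#' @param lambda_rule "min" (CV-minimising lambda, default) or "1se";
#'   determines the tuned lambda reported in attribute \code{selected}
#'   (its active set) and used by \code{ranker = "coef"}.
#' @param ranker "path" or "coef".
#' @return object of class \code{feature_ranking}: data.frame
#'   \code{feature, rank}. Attributes: \code{selected} (active set at
#'   the tuned lambda), \code{lambda} (tuned penalty), \code{rank1}
#'   (the rank-1 group), \code{prefix_scores} (mean CV R-squared per
#'   candidate prefix size).
#' @export
lasso_rank <- function(data, target, cv_folds = 20, seed,
                       lambda_rule = c("min", "1se"),
                       ranker = c("path", "coef")) {
  lambda_rule <- match.arg(lambda_rule)
  ranker <- match.arg(ranker)
  fm <- .feature_matrix(data, target)
  if (nrow(fm$x) < cv_folds) {
    stop("lasso_rank: need at least cv_folds complete rows", call. = FALSE)
  }
  set.seed(seed)
  cv <- glmnet::cv.glmnet(fm$x, fm$y, nfolds = cv_folds, nlambda = 100,
                          standardize = TRUE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(cv$glmnet.fit$beta)
  active <- abs(as.numeric(stats::coef(cv, s = lam))[-1]) > 0
  feats <- rownames(beta)
  # first path step (largest lambda) at which each feature is non-zero
  entry <- apply(beta, 1, function(b) {
    nz <- which(abs(b) > 0)
    if (length(nz)) min(nz) else Inf
  })
  # exact duplicates share their twin's (earliest) entry
  for (i in seq_along(feats)) {
    for (j in seq_along(feats)) {
      if (i != j && identical(fm$x[, i], fm$x[, j])) {
        entry[c(i, j)] <- min(entry[i], entry[j])
      }
    }
  }

  if (ranker == "path") {
    steps <- sort(unique(entry[is.finite(entry)]))
    sizes <- vapply(steps, function(s) sum(entry <= s), integer(1))
    folds <- .make_folds(nrow(fm$x), cv_folds, seed)
    prefix_score <- function(cols) {
      r2 <- numeric(cv_folds)
      for (k in seq_len(cv_folds)) {
        tr <- folds != k
        yt <- fm$y[!tr]
        pred <- if (length(cols) == 0) {
          rep(mean(fm$y[tr]), sum(!tr))
        } else {
          cf <- stats::lm.fit(cbind(1, fm$x[tr, cols, drop = FALSE]),
                              fm$y[tr])$coefficients
          cf[is.na(cf)] <- 0
          cbind(1, fm$x[!tr, cols, drop = FALSE]) %*% cf
        }
        r2[k] <- 1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
      }
      mean(r2)
    }
    ord <- order(entry, seq_along(feats))
    cand_sizes <- c(0L, sizes)
    scores <- vapply(cand_sizes, function(k) {
      prefix_score(if (k == 0) character() else feats[ord[seq_len(k)]])
    }, numeric(1))
    kstar <- cand_sizes[which.max(scores)]
    rank <- integer(length(feats))
    in_rank1 <- entry <= if (kstar == 0) -Inf else
      max(entry[ord[seq_len(kstar)]])
    nextr <- 1L
    if (any(in_rank1)) {
      rank[in_rank1] <- 1L
      nextr <- 2L
    }
    for (s in steps[sizes > kstar]) {
      idx <- which(entry == s & !in_rank1)
      if (length(idx)) {
        rank[idx] <- nextr
        nextr <- nextr + 1L
      }
    }
    if (any(!is.finite(entry))) rank[!is.finite(entry)] <- nextr
    prefix_scores <- stats::setNames(scores, cand_sizes)
  } else {
    sds <- apply(fm$x, 2, stats::sd)
    imp <- abs(as.numeric(stats::coef(cv, s = lam))[-1]) * sds
    rank <- integer(length(feats))
    nz <- imp > 0
    if (any(nz)) {
      r <- rank(-imp[nz], ties.method = "min")
      rank[nz] <- as.integer(match(r, sort(unique(r))))
    }
    if (any(!nz)) rank[!nz] <- max(rank[nz], 0L) + 1L
    prefix_scores <- NULL
  }
  out <- data.frame(feature = feats, rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("feature_ranking", "data.frame"),
            selected = feats[active], lambda = lam,
            rank1 = out$feature[out$rank == 1],
            prefix_scores = prefix_scores,
            lambda_rule = lambda_rule, ranker = ranker)
}

#' @export
#' @method print feature_ranking
print.feature_ranking <- function(x, ...) {
  cat("Lasso feature ranking (lambda =",
      format(attr(x, "lambda"), digits = 3), ",",
      attr(x, "lambda_rule"), "rule)\n")
  print.data.frame(x)
  invisible(x)
}

# fixed fold assignment used by subset_search
.make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Cross-validated subset search over candidate features
#'
#' Enumerates every non-empty subset of the candidate features
#' (optionally restricted to subsets containing at least one of
#' \code{must_include_any}) and scores each by k-fold cross-validated
#' out-of-fold R-squared. The adjusted score applies the adjusted-R2
#' penalty with the fold training size: 1 - (1 - R2)(n - 1)/(n - p - 1).
#' The comparison is sorted by mean adjusted score (descending), then
#' fewer features, then lexicographic feature names; the same fold
#' assignment is used for every subset so the ordering is invariant to
#' feature column order.
#'
#' @param data data.frame holding candidate columns and the target.
#' @param target response vector or column name.
#' @param candidates character vector of candidate feature names.
#' @param cv_folds folds (default 20).
#' @param seed integer seed for the fold assignment.
#' @param must_include_any optional character vector; subsets must
#'   contain at least one of these.
#' @return object of class \code{model_comparison}: data.frame
#'   \code{model_no, features, n_features, mean_cv_r2, mean_cv_adj_r2}.
#' @export
subset_search <- function(data, target, candidates, cv_folds = 20, seed,
                          must_include_any = NULL) {
  if (length(candidates) == 0) {
    stop("subset_search: empty candidate set", call. = FALSE)
  }
  .need_cols(data, candidates, "subset_search")
  y <- if (is.character(target) && length(target) == 1) data[[target]]
       else as.numeric(target)
  keep <- stats::complete.cases(data[candidates]) & is.finite(y)
  d <- data[keep, candidates, drop = FALSE]
  d <- as.data.frame(lapply(d, as.numeric))
  y <- y[keep]
  n <- nrow(d)
  if (n < cv_folds * 2) {
    stop("subset_search: too few complete rows for ", cv_folds, " folds",
         call. = FALSE)
  }
  cand <- sort(candidates)
  subsets <- unlist(lapply(seq_along(cand), function(k) {
    utils::combn(cand, k, simplify = FALSE)
  }), recursive = FALSE)
  if (!is.null(must_include_any)) {
    subsets <- Filter(function(s) length(intersect(s, must_include_any)) > 0,
                      subsets)
  }
  folds <- .make_folds(n, cv_folds, seed)
  score_subset <- function(feats) {
    r2 <- adj <- numeric(cv_folds)
    p <- length(feats)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      fit <- stats::lm.fit(cbind(1, as.matrix(d[tr, feats, drop = FALSE])),
                           y[tr])
      pred <- cbind(1, as.matrix(d[!tr, feats, drop = FALSE])) %*%
        fit$coefficients
      yt <- y[!tr]
      r2[k] <- 1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
      ntr <- sum(tr)
      adj[k] <- 1 - (1 - r2[k]) * (ntr - 1) / (ntr - p - 1)
    }
    c(mean(r2), mean(adj))
  }
  sc <- t(vapply(subsets, score_subset, numeric(2)))
  feats_str <- vapply(subsets, function(s) paste(s, collapse = ", "),
                      character(1))
  out <- data.frame(features = feats_str,
                    n_features = lengths(subsets),
                    mean_cv_r2 = sc[, 1],
                    mean_cv_adj_r2 = sc[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_cv_adj_r2, out$n_features, out$features), ]
  out <- cbind(model_no = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("model_comparison", "data.frame"),
            cv_folds = cv_folds, seed = seed)
}

#' @export
#' @method print model_comparison
print.model_comparison <- function(x, n = 10, ...) {
  cat("Cross-validated subset comparison (", attr(x, "cv_folds"),
      "-fold)\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more subsets\n")
  invisible(x)
}

#' Train/test split evaluation with CV-tuned Lasso
#'
#' Splits the data (default 80/20), tunes the Lasso penalty on the
#' training split by k-fold cross-validation, and reports the
#' cross-validated training R-squared (1 - CV MSE / Var(y_train)) and
#' the held-out test R-squared of the tuned model.
#'
#' @param data data.frame of features (+ target column).
#' @param target response vector or column name.
#' @param split training fraction (default 0.8).
#' @param cv_folds folds for lambda tuning (default 20).
#' @param seed integer seed (controls the split and the folds).
#' @param lambda_rule "min" or "1se".
#' @return list: \code{n_train, n_test, lambda, train_cv_r2, test_r2,
#'   nonzero} (features retained at the tuned lambda).
#' @export
train_test_split_eval <- function(data, target, split = 0.8, cv_folds = 20,
                                  seed, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  fm <- .feature_matrix(data, target)
  n <- nrow(fm$x)
  if (n < 25) stop("train_test_split_eval: need n >= 25", call. = FALSE)
  set.seed(seed)
  idx <- sample(n, floor(split * n))
  if (length(idx) < cv_folds * 2 || n - length(idx) < 2) {
    stop("train_test_split_eval: split too small for ", cv_folds, " folds",
         call. = FALSE)
  }
  xtr <- fm$x[idx, , drop = FALSE]; ytr <- fm$y[idx]
  xte <- fm$x[-idx, , drop = FALSE]; yte <- fm$y[-idx]
  cv <- glmnet::cv.glmnet(xtr, ytr, nfolds = cv_folds, nlambda = 100,
                          standardize = TRUE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cvm <- cv$cvm[cv$lambda == lam]
  train_cv_r2 <- 1 - cvm / mean((ytr - mean(ytr))^2)
  pred <- as.numeric(stats::predict(cv, newx = xte, s = lam))
  test_r2 <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  nz <- rownames(stats::coef(cv, s = lam))[-1][
    abs(as.numeric(stats::coef(cv, s = lam))[-1]) > 0]
  list(n_train = length(ytr), n_test = length(yte), lambda = lam,
       train_cv_r2 = train_cv_r2, test_r2 = test_r2, nonzero = nz)
}
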