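#' Assemble a subject x feature matrix from upstream tables
#'
#' Column-binds per-subject feature tables (long format: `id`, `feature`,
#' `value`) and keeps only the features named in `selection`. The
#' selection mask is produced upstream (e.g. features significantly
#' different between groups at both time points) — note this selection
#' happens outside the cross-validation loop and is a potential source of
#' optimistic bias; the returned object records the provenance so reports
#' can flag it.
#'
#' @param tables list of long-format data frames with columns `id`,
#'   `feature`, `value` (e.g. microstate parameters and mean FCSCC).
#' @param groups data frame with `id` and `group` for every subject.
#' @param selection character vector of feature names to retain.
#' @return object of class `feature_matrix`: `x` (subjects x features),
#'   `group` (factor), `selection`.
#' @export
assemble_features <- function(tables, groups, selection) {
  if (length(selection) == 0L)
    stop("empty selection mask: no features to assemble")
  long <- do.call(rbind, tables)
  stopifnot(all(c("id", "feature", "value") %in% names(long)))
  long <- long[long$feature %in% selection, , drop = FALSE]
  missing_feat <- setdiff(selection, unique(long$feature))
  if (length(missing_feat))
    stop("structural error: selected feature(s) absent: ",
         paste(missing_feat, collapse = ", "))
  ids <- groups$id
  x <- matrix(NA_real_, length(ids), length(selection),
              dimnames = list(ids, selection))
  long <- long[long$id %in% ids, , drop = FALSE]
  for (r in seq_len(nrow(long)))
    x[long$id[r], long$feature[r]] <- long$value[r]
  if (anyNA(x)) {
    bad <- rownames(x)[apply(is.na(x), 1L, any)]
    stop("structural error: missing values for subject(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(x = x, group = factor(groups$group),
                 selection = selection),
            class = "feature_matrix")
}

fit_svm <- function(x, g, kernel, cost, gamma) {
  e1071::svm(x, g, kernel = kernel, cost = cost,
             gamma = if (kernel == "radial") gamma else
               if (ncol(x) > 0) 1 / ncol(x) else 1,
             scale = FALSE)
}

decision_score <- function(model, newx, positive) {
  pr <- stats::predict(model, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients decision values toward the first class in the colname
  first <- sub("/.*", "", colnames(dv)[1L])
  s <- as.numeric(dv[, 1L])
  if (first == positive) s else -s
}

#' Nested leave-one-out cross-validated SVM
#'
#' Outer loop: leave one subject out. Per fold, preprocessing is fitted
#' on the training subjects only — standardise to zero mean / unit
#' variance, then PCA retaining `var_retain` of the variance — and the
#' inner leave-one-out loop grid-searches the SVM hyperparameters by
#' accuracy (ties break to the smaller cost, then the smaller gamma). The
#' winning model is refitted on the whole training fold and scored on the
#' held-out subject; pooled outer-fold decision scores give one ROC curve
#' and AUC.
#'
#' Each held-out decision score is centred by the mean decision score of
#' its own training fold before pooling. Pooled leave-one-out scores
#' carry a systematic offset between the classes (the training fold is
#' always depleted of the held-out subject's class, which shifts the
#' fitted boundary), biasing the null AUC well below 0.5; per-fold
#' centring removes that offset without touching the within-fold ranking.
#'
#' @param fm a [assemble_features()] `feature_matrix` (2 classes).
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost_grid,gamma_grid hyperparameter grids (gamma used for the
#'   RBF kernel only).
#' @param var_retain PCA variance fraction to retain.
#' @return list with `scores` (per-subject decision values, oriented so
#'   larger means the second factor level), `roc` (a `pROC::roc`), `auc`,
#'   `fold_means` (per-fold training means, for leakage audits), and the
#'   chosen hyperparameters per fold.
#' @export
nested_loocv_svm <- function(fm, kernel = c("linear", "rbf"),
                             cost_grid = 10^seq(-2, 2),
                             gamma_grid = 10^seq(-3, 1),
                             var_retain = 0.95) {
  kernel <- match.arg(kernel)
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"
  x <- fm$x
  g <- fm$group
  stopifnot(nlevels(g) == 2L, all(table(g) >= 2L))
  positive <- levels(g)[2L]
  n <- nrow(x)
  if (kernel == "linear") gamma_grid <- NA_real_
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  scores <- rep(NA_real_, n)
  chosen <- vector("list", n)
  fold_means <- matrix(NA_real_, n, ncol(x))
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    gtr <- droplevels(g[-i])
    if (nlevels(gtr) < 2L) {
      warning("class absent from training fold ", i, "; fold skipped")
      next
    }
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    fold_means[i, ] <- mu
    ztr <- scale(xtr, center = mu, scale = sdv)
    pc <- stats::prcomp(ztr, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1L, which(cum >= var_retain)[1L])
    ptr <- ztr %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
    # inner LOOCV accuracy per grid point
    acc <- vapply(seq_len(nrow(grid)), function(gi) {
      hits <- vapply(seq_len(nrow(ptr)), function(j) {
        gin <- droplevels(gtr[-j])
        if (nlevels(gin) < 2L) return(NA)
        m <- fit_svm(ptr[-j, , drop = FALSE], gin, svm_kernel,
                     grid$cost[gi], grid$gamma[gi])
        as.character(stats::predict(m, ptr[j, , drop = FALSE])) ==
          as.character(gtr[j])
      }, logical(1))
      mean(hits, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(acc)   # ties -> first = smallest cost, then gamma
    chosen[[i]] <- grid[best, ]
    model <- fit_svm(ptr, gtr, svm_kernel, grid$cost[best],
                     grid$gamma[best])
    zte <- scale(x[i, , drop = FALSE], center = mu, scale = sdv)
    pte <- zte %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
    scores[i] <- decision_score(model, pte, positive) -
      mean(decision_score(model, ptr, positive))
  }
  ok <- !is.na(scores)
  roc <- pROC::roc(response = g[ok], predictor = scores[ok],
                   levels = levels(g), direction = "<", quiet = TRUE)
  list(scores = scores, roc = roc, auc = as.numeric(pROC::auc(roc)),
       fold_means = fold_means, chosen = chosen, kernel = kernel)
}
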