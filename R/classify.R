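#' Two-sample t-test with pooled variance
#'
#' Two-sided test of equal means assuming a common variance (degrees of
#' freedom `n_a + n_b - 2`). Thin wrapper over `stats::t.test(var.equal =
#' TRUE)`; a zero pooled variance (both samples constant and equal) has no
#' defined statistic and yields `NA`.
#'
#' @param a,b numeric sample vectors of length >= 2 with finite values.
#' @return two-sided p-value, or `NA` when the pooled variance is zero.
#' @export
pooled_t_test <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "need >= 2 values per sample",
              class = "ehg_parameter_error")
  assert_that(all(is.finite(a)) && all(is.finite(b)), "samples must be finite",
              class = "ehg_parameter_error")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) return(1)
  out <- tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
  out
}

#' SMOTE minority over-sampling
#'
#' Balances two classes by synthesizing minority samples on the segments
#' between each randomly selected minority sample and one of its `k` nearest
#' minority neighbours (Euclidean metric), with a uniform interpolation
#' factor in `[0, 1]`. Oversampling stops when the minority class reaches
#' `target_n` rows (by default the majority count). Uses the current RNG
#' state; seed with `set.seed()` for reproducibility.
#'
#' @param x_minority,x_majority numeric matrices (rows = samples).
#' @param k number of nearest neighbours (default 5).
#' @param target_n minority size after balancing.
#' @return list with `x` (stacked matrix, minority rows first) and `y`
#'   (factor with levels `minority`, `majority`).
#' @export
smote_balance <- function(x_minority, x_majority, k = 5,
                          target_n = nrow(x_majority)) {
  x_minority <- as.matrix(x_minority); x_majority <- as.matrix(x_majority)
  n_min <- nrow(x_minority)
  assert_that(n_min >= k + 1, "minority class must have at least k + 1 samples",
              class = "ehg_parameter_error")
  n_new <- target_n - n_min
  assert_that(n_new >= 0, "target_n must be >= the minority count",
              class = "ehg_parameter_error")
  synth <- NULL
  if (n_new > 0) {
    d2 <- as.matrix(stats::dist(x_minority))^2
    diag(d2) <- Inf
    nn <- matrix(apply(d2, 1, function(row) order(row)[seq_len(k)]),
                 ncol = n_min)  # k x n_min
    base_idx <- sample.int(n_min, n_new, replace = n_new > n_min)
    synth <- matrix(NA_real_, n_new, ncol(x_minority))
    for (s in seq_len(n_new)) {
      i <- base_idx[s]
      j <- nn[sample.int(k, 1), i]
      u <- stats::runif(1)
      synth[s, ] <- x_minority[i, ] + u * (x_minority[j, ] - x_minority[i, ])
    }
  }
  x <- rbind(x_minority, synth, x_majority)
  y <- factor(rep(c("minority", "majority"), c(n_min + n_new, nrow(x_majority))),
              levels = c("minority", "majority"))
  list(x = x, y = y)
}

## ---- quadratic discriminant analysis ---------------------------------------

# Per-class Gaussian fit with equal priors; covariance regularized by eps * I
# when rank-deficient (eps defaults to 1e-6 * trace / dim).
qda_train <- function(x, y, reg_eps = NULL) {
  x <- as.matrix(x)
  lev <- levels(factor(y))
  assert_that(length(lev) == 2L, "QDA here is two-class",
              class = "ehg_parameter_error")
  fit_class <- function(lv) {
    xc <- x[y == lv, , drop = FALSE]
    mu <- colMeans(xc)
    S <- stats::cov(xc)
    eps <- reg_eps %||% (1e-6 * sum(diag(S)) / ncol(S))
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      S <- S + diag(eps, ncol(S))
      ch <- tryCatch(chol(S), error = function(e) NULL)
    }
    if (is.null(ch))
      stop_ehg("singular covariance after regularization for features: ",
               paste(colnames(x), collapse = ", "), class = "ehg_singular_error")
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))))
  }
  structure(list(classes = lev,
                 fits = stats::setNames(lapply(lev, fit_class), lev)),
            class = "ehg_qda")
}

# Continuous discriminant score: log-likelihood of the positive (first) class
# minus the negative class; > 0 classifies positive. Equal priors.
qda_score <- function(model, x) {
  x <- as.matrix(x)
  ll <- function(fit) {
    z <- forwardsolve(t(fit$chol), t(x) - fit$mu)
    -0.5 * colSums(z^2) - 0.5 * fit$logdet
  }
  ll(model$fits[[1]]) - ll(model$fits[[2]])
}

#' QDA with repeated stratified cross-validation
#'
#' The classification protocol: quadratic discriminant analysis (per-class
#' mean and covariance, equal priors, quadratic decision rule) evaluated by
#' stratified `n_folds`-fold cross-validation repeated `n_reps` times with
#' distinct fold shuffles. Class imbalance is handled by SMOTE; in the default
#' `"whole"` mode the complete sample is balanced before the folds are drawn
#' (the protocol used to produce the published tables), while `"folds"`
#' restricts SMOTE to each training fold for leakage-free generalization
#' estimates, and `"none"` disables it. Sensitivity, specificity and accuracy
#' are computed from the pooled confusion counts of each repetition; AUC is
#' the rank (Mann-Whitney) statistic of the continuous discriminant score.
#'
#' @param x numeric matrix of features (rows = intervals).
#' @param y two-level factor or character; `positive` names the positive
#'   (preterm) class.
#' @param positive level of `y` treated as positive (default the first level).
#' @param n_folds folds per repetition (default 10).
#' @param n_reps repetitions (default 30).
#' @param seed master seed; repetition seeds are fixed offsets from it.
#' @param smote_mode `"whole"`, `"folds"` or `"none"`.
#' @param k SMOTE neighbour count.
#' @param reg_eps optional covariance regularization.
#' @return object of class `ehg_cvreport` with fields `Se`, `Sp`, `CA`, `AUC`
#'   (percent, averaged over repetitions), `per_rep` (metric data frame),
#'   `confusion` (summed TP/FN/TN/FP), and the protocol settings.
#' @export
qda_cv <- function(x, y, positive = NULL, n_folds = 10, n_reps = 30,
                   seed = 1, smote_mode = c("whole", "folds", "none"),
                   k = 5, reg_eps = NULL) {
  smote_mode <- match.arg(smote_mode)
  x <- as.matrix(x)
  assert_that(all(is.finite(x)), "features must be finite",
              class = "ehg_parameter_error")
  y <- factor(y)
  assert_that(nlevels(y) == 2L, "y must have exactly two classes",
              class = "ehg_parameter_error")
  positive <- positive %||% levels(y)[1]
  y <- factor(y, levels = c(positive, setdiff(levels(y), positive)))
  assert_that(min(table(y)) >= n_folds,
              "need at least n_folds samples per class",
              class = "ehg_parameter_error")

  if (smote_mode == "whole") {
    set.seed(seed)
    tab <- table(y)
    minor <- names(tab)[which.min(tab)]
    major <- setdiff(levels(y), minor)
    bal <- smote_balance(x[y == minor, , drop = FALSE],
                         x[y == major, , drop = FALSE], k = k)
    x <- bal$x
    y <- factor(ifelse(bal$y == "minority", minor, major),
                levels = levels(y))
  }

  run_rep <- function(r) {
    set.seed(seed + r)
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    score <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
      if (smote_mode == "folds") {
        tab <- table(ytr)
        minor <- names(tab)[which.min(tab)]
        major <- setdiff(levels(y), minor)
        if (tab[minor] < tab[major]) {
          bal <- smote_balance(xtr[ytr == minor, , drop = FALSE],
                               xtr[ytr == major, , drop = FALSE], k = k)
          xtr <- bal$x
          ytr <- factor(ifelse(bal$y == "minority", minor, major),
                        levels = levels(y))
        }
      }
      model <- qda_train(xtr, ytr, reg_eps = reg_eps)
      score[fold == f] <- qda_score(model, x[fold == f, , drop = FALSE])
    }
    pos <- y == levels(y)[1]
    pred_pos <- score > 0
    tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
    tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
    sp <- score[pos]; sn <- score[!pos]
    auc <- mean(outer(sp, sn, function(u, v) (u > v) + 0.5 * (u == v)))
    c(TP = tp, FN = fn, TN = tn, FP = fp,
      Se = 100 * tp / (tp + fn), Sp = 100 * tn / (tn + fp),
      CA = 100 * (tp + tn) / (tp + fn + tn + fp), AUC = 100 * auc)
  }
  reps <- as.data.frame(t(vapply(seq_len(n_reps), run_rep, numeric(8))))
  structure(list(
    Se = mean(reps$Se), Sp = mean(reps$Sp), CA = mean(reps$CA),
    AUC = mean(reps$AUC), per_rep = reps,
    confusion = colSums(reps[, c("TP", "FN", "TN", "FP")]),
    n_folds = n_folds, n_reps = n_reps, seed = seed,
    smote_mode = smote_mode, positive = positive,
    features = colnames(x) %||% paste0("x", seq_len(ncol(x)))),
    class = "ehg_cvreport")
}

#' @export
print.ehg_cvreport <- function(x, ...) {
  cat(sprintf("<ehg_cvreport> QDA, %d-fold x %d reps (SMOTE: %s; positive: %s)\n",
              x$n_folds, x$n_reps, x$smote_mode, x$positive))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  Se = %.1f%%  Sp = %.1f%%  CA = %.1f%%  AUC = %.1f%%\n",
              x$Se, x$Sp, x$CA, x$AUC))
  invisible(x)
}

#' Classification experiment grid
#'
#' Evaluates the protocol of [qda_cv()] over every combination of band,
#' interval kind and feature subset, mirroring the published experiment
#' layout. Rows whose selected features contain undefined values are excluded
#' pairwise (per subset) and the exclusion count is reported; a subset left
#' with fewer samples per class than `n_folds` is skipped with a message.
#'
#' @param features feature table from [ehg_features()] with a `group` column
#'   containing `preterm` / `term`.
#' @param bands band names to evaluate.
#' @param interval_kinds interval kinds (default dummy and contraction).
#' @param subsets named list of character vectors of feature columns; the
#'   default is the published set: each single feature and the stated
#'   combinations.
#' @param ... passed to [qda_cv()] (`n_folds`, `n_reps`, `seed`,
#'   `smote_mode`, ...).
#' @return data frame with one row per report: `band`, `interval_kind`,
#'   `features`, `n_preterm`, `n_term`, `n_excluded`, `Se`, `Sp`, `CA`,
#'   `AUC`; the full `ehg_cvreport` objects are attached as the `reports`
#'   attribute.
#' @export
experiment_grid <- function(features,
                            bands = c("B0p", "Bb", "B1", "B2", "B3"),
                            interval_kinds = c("dummy", "contraction"),
                            subsets = default_subsets(), ...) {
  assert_that(all(c("group", "interval_kind", "band") %in% names(features)),
              "features must come from ehg_features()")
  rows <- list(); reports <- list()
  for (b in bands) for (kind in interval_kinds) for (sname in names(subsets)) {
    cols <- subsets[[sname]]
    sub <- features[features$band == b & features$interval_kind == kind &
                      features$group %in% c("preterm", "term"), ]
    keep <- stats::complete.cases(sub[, cols, drop = FALSE])
    n_excl <- sum(!keep)
    sub <- sub[keep, ]
    tab <- table(factor(sub$group, c("preterm", "term")))
    label <- paste(cols, collapse = ",")
    dots <- list(...)
    n_folds <- dots$n_folds %||% 10
    if (min(tab) < n_folds) {
      message(sprintf("skipping %s / %s / %s: %d preterm, %d term after exclusions",
                      b, kind, label, tab[["preterm"]], tab[["term"]]))
      next
    }
    rep <- qda_cv(as.matrix(sub[, cols, drop = FALSE]),
                  factor(sub$group, c("preterm", "term")),
                  positive = "preterm", ...)
    rows[[length(rows) + 1L]] <- data.frame(
      band = b, interval_kind = kind, features = label,
      n_preterm = tab[["preterm"]], n_term = tab[["term"]],
      n_excluded = n_excl, Se = rep$Se, Sp = rep$Sp, CA = rep$CA,
      AUC = rep$AUC, stringsAsFactors = FALSE)
    reports[[paste(b, kind, label, sep = "|")]] <- rep
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(band = character(), interval_kind = character(),
               features = character(), n_preterm = integer(),
               n_term = integer(), n_excluded = integer(), Se = numeric(),
               Sp = numeric(), CA = numeric(), AUC = numeric())
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' @rdname experiment_grid
#' @export
default_subsets <- function() {
  singles <- c("P_V", "P_H", "RP_VH", "Vbar_V", "Vbar_H", "RV_VH",
               "SE_S2", "SE_S3")
  out <- c(stats::setNames(as.list(singles), singles),
           list("P_V+P_H" = c("P_V", "P_H"),
                "Vbar_V+Vbar_H" = c("Vbar_V", "Vbar_H"),
                "RP_VH+SE_S2" = c("RP_VH", "SE_S2"),
                "RV_VH+SE_S2" = c("RV_VH", "SE_S2"),
                "P_V+P_H+SE_S2" = c("P_V", "P_H", "SE_S2"),
                "Vbar_V+Vbar_H+SE_S2" = c("Vbar_V", "Vbar_H", "SE_S2"),
                "P_H+Vbar_V+SE_S2" = c("P_H", "Vbar_V", "SE_S2"),
                "SE_S2+SE_S3" = c("SE_S2", "SE_S3")))
  out
}
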