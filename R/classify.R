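# Window-level logistic discrimination between conditions, evaluated with
# participant-wise k-fold cross-validation. All preprocessing inside CV
# (mean imputation and standardisation) uses training-fold statistics
# only, so no information from a held-out participant ever reaches the
# model that scores it.

#' Participant-wise fold assignment
#'
#' Participants (never windows) are shuffled within condition under the
#' seed, interleaved across conditions, and dealt to folds in contiguous
#' blocks, so fold sizes differ by at most one participant, folds mix
#' conditions wherever their size allows, and both conditions appear in
#' every training set.
#'
#' @param participants Data frame with `participant_id` and `condition`
#'   (one row per participant), or a feature matrix from which the pairs
#'   are taken.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return Named integer vector mapping participant_id to fold (0-based).
#' @export
assign_folds <- function(participants, k = 10, seed = 17) {
  df <- unique(participants[, c("participant_id", "condition")])
  if (k < 2) stop("k must be >= 2: cross-validation needs held-out data")
  if (nrow(df) < k) stop("more folds than participants")
  set.seed(as.integer(seed) %% 2147483647)
  by_cond <- split(df$participant_id, df$condition)
  shuffled <- lapply(by_cond, function(ids) sample(ids))
  # interleave conditions, then deal round-robin
  maxlen <- max(vapply(shuffled, length, integer(1)))
  order_ids <- unlist(lapply(seq_len(maxlen), function(i) {
    unlist(lapply(shuffled, function(ids) {
      if (i <= length(ids)) ids[i] else NULL
    }))
  }))
  # contiguous blocks over the interleaved order: fold sizes differ by at
  # most one and each fold mixes conditions wherever its size allows
  # (plain modulo dealing would hand alternating conditions to alternating
  # folds, making every fold single-condition when k is even)
  n <- length(order_ids)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  folds <- setNames(rep(seq_len(k) - 1L, times = sizes), order_ids)
  folds[df$participant_id]
}

impute_standardise <- function(train, test) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(train))) {
    train[is.na(train[, j]), j] <- mu[j]
    test[is.na(test[, j]), j] <- mu[j]
  }
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = scale(train, center = mu, scale = sdv),
       test = scale(test, center = mu, scale = sdv))
}

fit_predict_logistic <- function(xtr, ytr, xte) {
  if (ncol(xtr) == 1) {
    # single-feature models are fitted unpenalised
    dtr <- data.frame(y = ytr, x = xtr[, 1])
    fit <- suppressWarnings(glm(y ~ x, data = dtr, family = binomial()))
    p <- suppressWarnings(
      predict(fit, newdata = data.frame(x = xte[, 1]), type = "response"))
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                     lambda = 1 / length(ytr), standardize = FALSE))
    p <- as.numeric(predict(fit, newx = xte, type = "response"))
  }
  p
}

#' Participant-wise cross-validated logistic classification
#'
#' Per fold, features are mean-imputed and standardised with
#' training-fold statistics only, an L2-regularised (ridge) logistic
#' regression is fitted on the training windows, and the held-out windows
#' are scored. Accuracy is pooled over windows across folds. The ridge
#' penalty corresponds to unit L2 strength against the summed
#' log-likelihood (glmnet lambda = 1/n on standardised features);
#' single-feature models are fitted unpenalised.
#'
#' @param fm Window-level feature matrix.
#' @param features Character vector of feature columns to use.
#' @param folds Fold assignment from [assign_folds()].
#' @param name Label stored in the report.
#' @param seed Seed recorded in the report (provenance only).
#' @param return_predictions If `TRUE`, include per-window held-out
#'   probabilities in the report (`predictions`).
#' @return A `cv_report`: list with `feature_set`, `accuracy`,
#'   `per_fold` accuracies, `n_windows`, `n_features`, `seed`, and
#'   optionally `predictions`.
#' @export
cross_validate <- function(fm, features, folds, name = "custom",
                           seed = NA_integer_, return_predictions = FALSE) {
  if (length(features) == 0) stop("empty feature set")
  miss <- setdiff(features, names(fm))
  if (length(miss) > 0) {
    stop("features absent from matrix: ", paste(head(miss, 3), collapse = ", "))
  }
  y <- as.integer(fm$condition == "GamePlay")
  x <- as.matrix(fm[, features, drop = FALSE])
  pid <- fm$participant_id
  fold_of_row <- folds[pid]
  if (anyNA(fold_of_row)) stop("fold assignment missing some participants")
  correct <- 0L
  total <- 0L
  per_fold <- numeric(0)
  prob <- rep(NA_real_, nrow(fm))
  for (f in sort(unique(fold_of_row))) {
    te <- fold_of_row == f
    tr <- !te
    if (length(unique(y[tr])) < 2) stop("degenerate fold: one-class training set")
    if (min(table(y[tr])) < 2) {
      stop("degenerate fold: a class has fewer than 2 training windows")
    }
    xs <- impute_standardise(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    p <- fit_predict_logistic(xs$train, y[tr], xs$test)
    prob[te] <- p
    hit <- sum((p > 0.5) == (y[te] == 1))
    correct <- correct + hit
    total <- total + sum(te)
    per_fold <- c(per_fold, hit / sum(te))
  }
  rep <- structure(list(feature_set = name, accuracy = correct / total,
                        per_fold = per_fold, n_windows = total,
                        n_features = length(features), seed = seed),
                   class = "cv_report")
  if (return_predictions) {
    rep$predictions <- data.frame(participant_id = pid,
                                  fold = unname(fold_of_row),
                                  y = y, prob = prob)
  }
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: accuracy %.2f%% (%d windows, %d features)\n",
              x$feature_set, 100 * x$accuracy, x$n_windows, x$n_features))
  invisible(x)
}

#' Modality ablation suite
#'
#' Cross-validates the full 80-feature model, the model without EMG (63
#' features) and the model without EMG and EDA (51 features) on identical
#' folds.
#'
#' @inheritParams cross_validate
#' @return Named list of three `cv_report`s: `full`, `wo_emg`,
#'   `wo_emg_eda`.
#' @export
ablation_suite <- function(fm, folds, seed = NA_integer_) {
  sets <- c("full", "wo_emg", "wo_emg_eda")
  setNames(lapply(sets, function(s) {
    cross_validate(fm, feature_set(s), folds, name = s, seed = seed)
  }), sets)
}

#' Single-feature logistic screening
#'
#' For every feature: a full-data unpenalised logistic fit on the
#' standardised (mean-imputed) feature gives the coefficient `beta` and a
#' likelihood-ratio p-value, adjusted by Benjamini-Hochberg across the
#' screened features; cross-validation on the shared folds gives the
#' accuracy. Constant features are skipped with a flag.
#'
#' @inheritParams cross_validate
#' @param top_n Optionally return only the `top_n` most accurate features.
#' @return Data frame sorted by accuracy (descending): `feature`,
#'   `modality`, `beta`, `p`, `p_fdr`, `accuracy`, `flag`.
#' @export
single_feature_screen <- function(fm, folds, top_n = NULL,
                                  seed = NA_integer_) {
  feats <- intersect(feature_names(), names(fm))
  y <- as.integer(fm$condition == "GamePlay")
  rows <- lapply(feats, function(f) {
    v <- fm[[f]]
    out <- data.frame(feature = f,
                      modality = unname(feature_modalities()[f]),
                      beta = NA_real_, p = NA_real_, p_fdr = NA_real_,
                      accuracy = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    vv <- v
    vv[is.na(vv)] <- mean(vv, na.rm = TRUE)
    if (!any(is.finite(vv)) || sd(vv) == 0) {
      out$flag <- "constant"
      return(out)
    }
    z <- (vv - mean(vv)) / sd(vv)
    fit <- suppressWarnings(glm(y ~ z, family = binomial()))
    cf <- coef(fit)
    if ("z" %in% names(cf)) {
      out$beta <- unname(cf["z"])
      # likelihood-ratio p: unlike the Wald statistic it stays sharp when
      # a feature separates the classes almost perfectly
      out$p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                             lower.tail = FALSE)
    }
    out$accuracy <- cross_validate(fm, f, folds, name = f, seed = seed)$accuracy
    out
  })
  out <- do.call(rbind, rows)
  sel <- out$flag == ""
  out$p_fdr[sel] <- bh_fdr(out$p[sel])
  out <- out[order(-out$accuracy), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}
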