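# Event-level aggregation and group-comparison statistics with FDR control.

#' Aggregate window-level features to one value per participant
#'
#' Two-stage aggregation: window values are averaged within each event,
#' and the event-level means are then averaged per participant, so every
#' event contributes equally regardless of its length. Missing windows are
#' excluded pairwise; a feature missing in all of a participant's windows
#' stays missing.
#'
#' @param fm A window-level feature matrix (see
#'   [extract_feature_matrix()]).
#' @return Data frame with one row per participant: `participant_id`,
#'   `condition`, and one column per feature.
#' @export
aggregate_participant <- function(fm) {
  feats <- intersect(feature_names(), names(fm))
  if (nrow(fm) == 0) stop("empty feature matrix")
  dt <- data.table::as.data.table(fm)
  nanmean <- function(x) {
    v <- mean(x, na.rm = TRUE)
    if (is.nan(v)) NA_real_ else v
  }
  ev <- dt[, lapply(.SD, nanmean), .SDcols = feats,
           by = c("participant_id", "condition", "event_id")]
  pt <- ev[, lapply(.SD, nanmean), .SDcols = feats,
           by = c("participant_id", "condition")]
  data.table::setDF(pt)
  pt
}

#' Pooled-variance two-sample t-test with effect size
#'
#' Student's t with pooled variance (df = n_a + n_b - 2), Cohen's d from
#' the pooled SD, and the 95% confidence interval of the mean difference.
#'
#' @param a,b Numeric vectors (NAs dropped), each with >= 2 values.
#' @return List with `t`, `df`, `p`, `d`, `ci95` (length-2), `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
ttest_ind <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("degenerate groups: zero pooled variance")
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(a) - mean(b)) / sqrt(sp2),
       ci95 = unname(tt$conf.int),
       mean_a = mean(a), mean_b = mean(b),
       sd_a = sd(a), sd_b = sd(b),
       n_a = length(a), n_b = length(b))
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @return List with `U` (for the first sample), `Z` and the two-sided
#'   `p` from the tie-corrected normal approximation (no continuity
#'   correction, so swapping the samples exactly negates `Z`).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("each group needs >= 1 value")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, Z = 0, p = 1))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param items Numeric matrix or data.frame, respondents in rows and
#'   items in columns (>= 2 of each).
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 respondents and >= 2 items")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (clipped at 1).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs passed
#'   through).
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Group comparison over all features with FDR control
#'
#' Aggregates to participant level if given a window-level matrix, runs a
#' pooled t-test per feature between the two conditions, and adjusts
#' p-values within each declared family. Features constant in both groups
#' (or with too few non-missing participants) are flagged `degenerate` and
#' excluded from testing and adjustment.
#'
#' @param participant_tab Participant-level table from
#'   [aggregate_participant()] (window-level matrices are aggregated
#'   automatically).
#' @param families Named character vector mapping feature names to family
#'   labels; defaults to one `"physiology"` family for all features.
#' @return Data frame with one row per feature: `feature`, `modality`,
#'   `family`, group means/SDs, `t`, `p_raw`, `p_fdr`, `d`, `ci_low`,
#'   `ci_high`, `n_play`, `n_watch`, `flag`; sorted by modality then
#'   feature name.
#' @export
compare_groups <- function(participant_tab, families = NULL) {
  feats <- intersect(feature_names(), names(participant_tab))
  if (!"condition" %in% names(participant_tab) ||
      length(unique(participant_tab$condition)) != 2) {
    stop("need exactly two conditions")
  }
  if ("window_index" %in% names(participant_tab)) {
    participant_tab <- aggregate_participant(participant_tab)
  }
  grp <- participant_tab$condition
  lv <- c("GamePlay", "GameWatch")
  if (!all(grp %in% lv)) lv <- sort(unique(grp))
  if (min(table(grp)) < 2) stop("need >= 2 participants per group")
  if (is.null(families)) {
    families <- setNames(rep("physiology", length(feats)), feats)
  }
  mods <- feature_modalities()
  rows <- lapply(feats, function(f) {
    a <- participant_tab[[f]][grp == lv[1]]
    b <- participant_tab[[f]][grp == lv[2]]
    base <- data.frame(feature = f, modality = unname(mods[f]),
                       family = unname(families[f]),
                       mean_play = mean(a, na.rm = TRUE),
                       sd_play = sd(a[!is.na(a)]),
                       mean_watch = mean(b, na.rm = TRUE),
                       sd_watch = sd(b[!is.na(b)]),
                       t = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                       d = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       n_play = sum(!is.na(a)), n_watch = sum(!is.na(b)),
                       flag = "", stringsAsFactors = FALSE)
    res <- tryCatch(ttest_ind(a, b), error = function(e) NULL)
    if (is.null(res)) {
      base$flag <- "degenerate"
    } else {
      base$t <- res$t
      base$p_raw <- res$p
      base$d <- res$d
      base$ci_low <- res$ci95[1]
      base$ci_high <- res$ci95[2]
    }
    base
  })
  out <- do.call(rbind, rows)
  for (fam in unique(out$family)) {
    sel <- out$family == fam & out$flag == ""
    out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
  }
  out[order(out$modality, out$feature), ]
}
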