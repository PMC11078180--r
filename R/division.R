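# Division-pattern analysis: pairing daughters to micropattern sites,
# delta-MOB mixture classification into metabolically symmetric vs
# asymmetric divisions, parent-daughter inheritance, post-division score
# dynamics, and condition screening.

#' Pair parent cells with their daughters by micropattern site
#'
#' Assigns every cell at both timepoints to its nearest micropattern site
#' (within \code{site_radius}); sites holding one cell before division and
#' exactly two after become parent/paired-daughter records. Sites with more
#' than two post-division cells (a second division) are flagged and
#' excluded.
#'
#' @param pre data.frame of pre-division cells: \code{x}, \code{y},
#'   \code{score}.
#' @param post data.frame of post-division cells: same columns.
#' @param sites data.frame of site positions: \code{site}, \code{x}, \code{y}.
#' @param site_radius maximum cell-to-site distance.
#' @return list with \code{records} (data.frame: pair_id, site,
#'   parent_score, daughter1, daughter2, delta_mob) and \code{flagged}
#'   (sites excluded, with reason).
#' @export
pair_daughters <- function(pre, post, sites, site_radius = 15) {
  assign_site <- function(df) {
    if (!nrow(df)) return(integer(0))
    d2 <- outer(df$x, sites$x, "-")^2 + outer(df$y, sites$y, "-")^2
    nearest <- max.col(-d2)
    ok <- d2[cbind(seq_len(nrow(df)), nearest)] <= site_radius^2
    ifelse(ok, sites$site[nearest], NA_integer_)
  }
  pre_site <- assign_site(pre)
  post_site <- assign_site(post)
  records <- list(); flagged <- list()
  for (s in sites$site) {
    np_pre <- which(pre_site == s)
    np_post <- which(post_site == s)
    if (length(np_pre) != 1) next
    if (length(np_post) > 2) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(site = s, reason = "more than 2 post-division cells")
      next
    }
    if (length(np_post) != 2) next   # no division (or lost cell)
    d <- post$score[np_post]
    records[[length(records) + 1L]] <- data.frame(
      pair_id = length(records) + 1L, site = s,
      parent_score = pre$score[np_pre],
      daughter1 = d[1], daughter2 = d[2], delta_mob = abs(d[1] - d[2]))
  }
  list(records = if (length(records)) do.call(rbind, records) else
         data.frame(pair_id = integer(), site = integer(),
                    parent_score = numeric(), daughter1 = numeric(),
                    daughter2 = numeric(), delta_mob = numeric()),
       flagged = if (length(flagged)) do.call(rbind, flagged) else
         data.frame(site = integer(), reason = character()))
}

#' Classify divisions by the delta-MOB double-Gaussian threshold
#'
#' Fits a two-component Gaussian mixture to the |delta-MOB| values (absolute
#' daughter score differences) and places the threshold at the component
#' density intersection between the means: divisions above it are
#' metabolically asymmetric (M-asymmetric), below it M-symmetric. When the
#' components collapse no threshold exists and pairs stay unclassified.
#'
#' @param delta_mob numeric |delta-MOB| values (n >= 20).
#' @param ... passed to \code{\link{fit_gauss2}}.
#' @return list with the mixture parameters, \code{threshold}, and
#'   \code{pattern} (factor per input value, NA when collapsed).
#' @export
fit_delta_mixture <- function(delta_mob, ...) {
  if (length(delta_mob) < 20)
    warning("fewer than 20 divisions; mixture threshold may be unstable")
  fit <- fit_gauss2(delta_mob, ...)
  pattern <- if (fit$collapsed) factor(rep(NA_character_, length(delta_mob)),
                                       levels = c("M-symmetric", "M-asymmetric"))
  else factor(ifelse(delta_mob > fit$threshold, "M-asymmetric", "M-symmetric"),
              levels = c("M-symmetric", "M-asymmetric"))
  list(means = fit$means, sds = fit$sds, weights = fit$weights,
       threshold = fit$threshold, collapsed = fit$collapsed,
       pattern = pattern, fit = fit)
}

#' Parent-daughter inheritance correlation
#'
#' Pearson correlation between parent scores and daughter scores (the
#' daughter-pair mean by default, or each daughter separately), with the
#' zero-slope p-value; computed overall and per division pattern when
#' patterns are available.
#'
#' @param records data.frame with \code{parent_score}, \code{daughter1},
#'   \code{daughter2}, and optionally \code{pattern}.
#' @param daughter "mean" (default), "each" (both daughters stacked).
#' @return data.frame: group, n, r, p.
#' @export
inheritance_correlation <- function(records, daughter = c("mean", "each")) {
  daughter <- match.arg(daughter)
  vals <- function(df) {
    if (daughter == "mean")
      list(p = df$parent_score, d = (df$daughter1 + df$daughter2) / 2)
    else list(p = rep(df$parent_score, 2), d = c(df$daughter1, df$daughter2))
  }
  one <- function(df, group) {
    v <- vals(df)
    if (length(v$p) < 3 || sd(v$p) == 0 || sd(v$d) == 0)
      return(data.frame(group = group, n = nrow(df), r = NA_real_,
                        p = NA_real_))
    ct <- cor.test(v$p, v$d, method = "pearson")
    data.frame(group = group, n = nrow(df), r = unname(ct$estimate),
               p = ct$p.value)
  }
  out <- one(records, "all")
  if ("pattern" %in% names(records)) {
    for (g in levels(factor(records$pattern))) {
      out <- rbind(out, one(records[records$pattern %in% g, , drop = FALSE], g))
    }
  }
  out
}

#' Post-division score dynamics per division pattern
#'
#' Mean daughter-score trajectories per pattern over follow-up timepoints,
#' the fraction of daughters above the stemness threshold at each timepoint,
#' and a rank-based (Mann-Whitney) two-group comparison of patterns at each
#' timepoint.
#'
#' @param scores long data.frame: \code{pair_id}, \code{pattern},
#'   \code{timepoint}, \code{score} (one row per daughter per timepoint).
#' @param threshold stemness threshold on the score scale.
#' @return list with \code{trajectories} (pattern x timepoint means, n,
#'   fraction above threshold) and \code{tests} (per-timepoint Mann-Whitney
#'   p between the two patterns, when both present).
#' @export
score_dynamics <- function(scores, threshold) {
  stopifnot(all(c("pattern", "timepoint", "score") %in% names(scores)))
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(scores, list(scores$pattern,
                                                  scores$timepoint),
                                     drop = TRUE), function(df) {
    data.frame(pattern = df$pattern[1], timepoint = df$timepoint[1],
               n = nrow(df), mean_score = mean(df$score),
               fraction_above = mean(df$score > threshold))
  }))
  rownames(agg) <- NULL
  tests <- NULL
  pats <- unique(scores$pattern)
  if (length(pats) == 2) {
    tests <- do.call(rbind, lapply(split(scores, scores$timepoint),
                                   function(df) {
      a <- df$score[df$pattern == pats[1]]
      b <- df$score[df$pattern == pats[2]]
      p <- if (length(a) >= 2 && length(b) >= 2)
        suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
      data.frame(timepoint = df$timepoint[1], n1 = length(a),
                 n2 = length(b), p = p)
    }))
    rownames(tests) <- NULL
  }
  list(trajectories = agg[order(agg$pattern, agg$timepoint), ], tests = tests)
}

#' Screen conditions for induced division asymmetry
#'
#' Per-condition delta-MOB summaries, the asymmetric-division fraction
#' (against a shared or per-condition mixture threshold), per-pattern mean
#' daughter scores, and a one-way ANOVA across conditions on delta-MOB.
#'
#' @param records data.frame with \code{condition}, \code{delta_mob},
#'   \code{daughter1}, \code{daughter2}.
#' @param threshold delta-MOB classification threshold shared across
#'   conditions; NULL fits one mixture to the pooled delta-MOB values.
#' @param min_n conditions with fewer records are excluded (warning).
#' @return list with \code{summary} (per condition: n, mean/median delta,
#'   asymmetric fraction, per-pattern mean daughter score), \code{threshold},
#'   and \code{anova_p} (NA with a single condition).
#' @export
condition_screen <- function(records, threshold = NULL, min_n = 3L) {
  stopifnot(all(c("condition", "delta_mob") %in% names(records)))
  cnt <- table(records$condition)
  drop <- names(cnt)[cnt < min_n]
  if (length(drop)) {
    warning("excluding condition(s) with n < ", min_n, ": ",
            paste(drop, collapse = ", "))
    records <- records[!records$condition %in% drop, , drop = FALSE]
  }
  if (!nrow(records)) stop("no conditions left to screen")
  if (is.null(threshold)) {
    mix <- fit_delta_mixture(records$delta_mob)
    threshold <- mix$threshold
  }
  records$pattern <- if (is.na(threshold)) NA_character_ else
    ifelse(records$delta_mob > threshold, "M-asymmetric", "M-symmetric")
  summ <- do.call(rbind, lapply(split(records, records$condition),
                                function(df) {
    dmean <- if (all(c("daughter1", "daughter2") %in% names(df)))
      (df$daughter1 + df$daughter2) / 2 else rep(NA_real_, nrow(df))
    data.frame(condition = df$condition[1], n = nrow(df),
               mean_delta = mean(df$delta_mob),
               median_delta = median(df$delta_mob),
               asym_fraction = mean(df$pattern == "M-asymmetric"),
               mean_daughter_sym = mean(dmean[df$pattern == "M-symmetric"]),
               mean_daughter_asym = mean(dmean[df$pattern == "M-asymmetric"]))
  }))
  rownames(summ) <- NULL
  anova_p <- NA_real_
  if (length(unique(records$condition)) >= 2) {
    fit <- aov(delta_mob ~ factor(condition), data = records)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  list(summary = summ, threshold = threshold, anova_p = anova_p,
       records = records)
}
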