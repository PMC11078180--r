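# Informative-feature selection: per-feature logistic F1 gate, trending
# index across differentiation stages, conjunction across two datasets, and
# knowledge-graph reduction to representative features; SVM ROC evaluation.

#' F1 score from confusion counts
#'
#' \code{F1 = 2 * precision * recall / (precision + recall)} with the stem
#' (positive) class convention: precision is the fraction of predicted
#' positives that are true positives, recall the fraction of actual positives
#' recovered. Returns 0 when there are no true positives (but some
#' prediction/positive exists), NA when all counts are zero.
#'
#' @param tp,fp,fn nonnegative confusion counts.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) return(NA_real_)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# stratified train/test split: returns logical train indicator
.stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, round(train_frac * length(idx)))
    train[sample(idx, k)] <- TRUE
  }
  train
}

#' Held-out F1 of a single feature via logistic regression
#'
#' Trains a one-covariate logistic model on a stratified 60% split and
#' scores the held-out 40% at probability threshold 0.5, with the positive
#' class being the stem label.
#'
#' @param values numeric feature vector.
#' @param labels vector coercible to character; \code{positive} marks the
#'   stem class.
#' @param positive positive-class label, default "HSC".
#' @param train_frac training fraction, default 0.6.
#' @param seed split seed.
#' @return list with \code{f1}, and \code{degenerate = TRUE} when the feature
#'   is constant (the model reduces to the majority-class rule).
#' @export
evaluate_feature <- function(values, labels, positive = "HSC",
                             train_frac = 0.6, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels), positive %in% labels,
            length(unique(labels)) >= 2)
  y <- as.integer(labels == positive)
  train <- .stratified_split(y, train_frac, seed)
  degenerate <- sd(values[train]) == 0 || anyNA(values)
  if (degenerate) {
    pred <- rep(as.integer(mean(y[train]) > 0.5), sum(!train))
  } else {
    fit <- suppressWarnings(
      glm(y ~ x, data = data.frame(y = y[train], x = values[train]),
          family = binomial()))
    p <- predict(fit, newdata = data.frame(x = values[!train]),
                 type = "response")
    pred <- as.integer(p > 0.5)
  }
  yt <- y[!train]
  f1 <- f1_score(tp = sum(pred == 1 & yt == 1),
                 fp = sum(pred == 1 & yt == 0),
                 fn = sum(pred == 0 & yt == 1))
  list(f1 = f1, degenerate = degenerate)
}

#' Trending index of a feature across ordered differentiation stages
#'
#' \code{TI = sum(diff(means)) / sum(abs(diff(means)))} over population-level
#' stage averages ordered by stage. TI is 1 for continuously increasing and
#' -1 for continuously decreasing features; |TI| < 0.5 marks a fluctuating
#' (non-monotonous) feature.
#'
#' @param stage_means numeric vector of stage means in stage order (stem
#'   first).
#' @return TI in [-1, 1]; NA when all stage means are equal (0/0).
#' @export
trending_index <- function(stage_means) {
  stopifnot(length(stage_means) >= 2)
  d <- diff(stage_means)
  den <- sum(abs(d))
  if (den == 0) return(NA_real_)
  sum(d) / den
}

#' Select informative features across two differentiation datasets
#'
#' A feature is selected iff (i) its held-out logistic F1 exceeds
#' \code{f1_cut} in both datasets and (ii) its trending index is beyond
#' \code{+/- ti_cut} in both datasets (by default additionally with the same
#' sign in both, so "informative" means consistently up or consistently down).
#'
#' @param table_a,table_b feature tables: data.frames with \code{stage}
#'   (ordered integer stages, stem = 0), \code{label} (stem label vs rest)
#'   and feature columns.
#' @param features feature column names to evaluate (default: all columns
#'   other than stage/label/metadata).
#' @param f1_cut,ti_cut strict thresholds, defaults 0.6 and 0.5.
#' @param positive stem label, default "HSC".
#' @param require_sign_agreement require matching TI sign across datasets
#'   (default TRUE); FALSE gives the literal two-criteria rule.
#' @param seed split seed.
#' @return a \code{selection_result} data.frame: per feature F1 and TI in
#'   both datasets, the gate booleans, and \code{selected}.
#' @export
select_features <- function(table_a, table_b, features = NULL, f1_cut = 0.6,
                            ti_cut = 0.5, positive = "HSC",
                            require_sign_agreement = TRUE, seed = 1L) {
  if (is.null(features)) {
    drop <- c("stage", "label", "cell_id", "dataset", "timepoint",
              "centroid_row", "centroid_col", "area_px", "flag_split")
    features <- setdiff(intersect(names(table_a), names(table_b)), drop)
  }
  for (tb in list(table_a, table_b)) {
    cnt <- table(tb$stage)
    if (any(cnt == 0)) stop("a stage has zero cells")
  }
  res <- data.frame(feature_id = features, F1_a = NA_real_, F1_b = NA_real_,
                    TI_a = NA_real_, TI_b = NA_real_)
  for (k in seq_along(features)) {
    f <- features[k]
    res$F1_a[k] <- evaluate_feature(table_a[[f]], table_a$label, positive,
                                    seed = seed)$f1
    res$F1_b[k] <- evaluate_feature(table_b[[f]], table_b$label, positive,
                                    seed = seed)$f1
    ma <- tapply(table_a[[f]], table_a$stage, mean)
    mb <- tapply(table_b[[f]], table_b$stage, mean)
    res$TI_a[k] <- trending_index(ma[order(as.numeric(names(ma)))])
    res$TI_b[k] <- trending_index(mb[order(as.numeric(names(mb)))])
  }
  res$pass_f1 <- res$F1_a > f1_cut & res$F1_b > f1_cut
  res$pass_ti <- abs(res$TI_a) > ti_cut & abs(res$TI_b) > ti_cut
  if (require_sign_agreement)
    res$pass_ti <- res$pass_ti & sign(res$TI_a) == sign(res$TI_b)
  res$pass_f1[is.na(res$pass_f1)] <- FALSE
  res$pass_ti[is.na(res$pass_ti)] <- FALSE
  res$selected <- res$pass_f1 & res$pass_ti
  attr(res, "thresholds") <- list(f1_cut = f1_cut, ti_cut = ti_cut,
                                  require_sign_agreement = require_sign_agreement,
                                  seed = seed)
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Build a knowledge graph over the feature registry
#'
#' Groups registry features into leaf nodes by (stem category, region,
#' channel, statistic family): e.g. all signal-strength statistics of
#' mitochondrial NAD(P)H intensity form one node. Every registry feature
#' belongs to exactly one node.
#'
#' @param registry a \code{\link{mob_registry}} table.
#' @return a \code{knowledge_graph}: named list of nodes, each with
#'   \code{members} (feature ids) and \code{stem} (top-level category).
#' @export
knowledge_graph <- function(registry = mob_registry()) {
  stem <- ifelse(registry$channel == "morphology", "morphology",
          ifelse(registry$region == "compartmentalization", "compartmentalization",
          ifelse(registry$region == "mito", "mitochondria", "cytoplasm_nucleus")))
  key <- paste(stem, registry$channel, registry$family, sep = ".")
  nodes <- split(registry$feature_id, key)
  g <- lapply(names(nodes), function(k) {
    list(node = k, stem = strsplit(k, ".", fixed = TRUE)[[1]][1],
         members = nodes[[k]])
  })
  names(g) <- names(nodes)
  structure(g, class = "knowledge_graph")
}

#' Reduce a selection to representative features via the knowledge graph
#'
#' A node is retained when the fraction of its members passing selection
#' reaches \code{node_fraction_cut}; a retained node emits one canonical
#' representative by statistic priority (average > median > variance >
#' first member).
#'
#' @param selection a \code{\link{select_features}} result.
#' @param graph a \code{\link{knowledge_graph}}.
#' @param node_fraction_cut minimum selected fraction, default 0.5.
#' @param priority statistic-name priority for the canonical member.
#' @return data.frame of retained nodes: node, selected fraction,
#'   representative feature id.
#' @export
representatives <- function(selection, graph,
                            node_fraction_cut = 0.5,
                            priority = c("average", "median", "variance")) {
  sel_ids <- selection$feature_id[selection$selected]
  all_members <- unlist(lapply(graph, `[[`, "members"))
  missing <- setdiff(sel_ids, all_members)
  if (length(missing))
    stop("selected feature(s) not covered by the knowledge graph: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (nd in graph) {
    evaluated <- intersect(nd$members, selection$feature_id)
    if (!length(evaluated)) next
    frac <- mean(evaluated %in% sel_ids)
    if (frac < node_fraction_cut || frac == 0) next
    sel_members <- intersect(evaluated, sel_ids)
    stat_of <- sub(".*_", "", sel_members)
    rep_id <- sel_members[1]
    for (p in priority) {
      hit <- sel_members[endsWith(sel_members, paste0("_", p))]
      if (length(hit)) { rep_id <- hit[1]; break }
    }
    out[[length(out) + 1L]] <- data.frame(node = nd$node, stem = nd$stem,
                                          n_members = length(evaluated),
                                          selected_fraction = frac,
                                          representative = rep_id)
  }
  if (!length(out))
    return(data.frame(node = character(), stem = character(),
                      n_members = integer(), selected_fraction = numeric(),
                      representative = character()))
  do.call(rbind, out)
}

#' SVM ROC evaluation of a feature subset
#'
#' Trains a margin classifier (radial-kernel SVM) on a stratified 70% split
#' and computes the ROC and trapezoid-rule AUC of its decision values on the
#' held-out 30%.
#'
#' @param x numeric matrix/data.frame of features (rows = cells).
#' @param labels class labels; \code{positive} is the stem class.
#' @param positive positive-class label.
#' @param train_frac training fraction, default 0.7.
#' @param seed split seed.
#' @return list with \code{auc}, \code{roc} (data.frame fpr/tpr), and the
#'   held-out size \code{n_test}.
#' @export
classifier_roc <- function(x, labels, positive = "HSC", train_frac = 0.7,
                           seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.integer(as.character(labels) == positive), levels = c(0, 1))
  train <- .stratified_split(as.integer(as.character(y)), train_frac, seed)
  if (length(unique(y[train])) < 2 || length(unique(y[!train])) < 2)
    stop("both classes must be present in both splits")
  fit <- e1071::svm(x[train, , drop = FALSE], y[train], kernel = "radial",
                    scale = TRUE)
  dv <- attr(predict(fit, x[!train, , drop = FALSE], decision.values = TRUE),
             "decision.values")[, 1]
  # orient decision values so larger means more likely positive
  yt <- as.integer(as.character(y[!train]))
  if (cor(dv, yt) < 0) dv <- -dv
  ord <- order(dv, decreasing = TRUE)
  tpr <- cumsum(yt[ord] == 1) / sum(yt == 1)
  fpr <- cumsum(yt[ord] == 0) / sum(yt == 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(auc = auc, roc = roc, n_test = sum(!train))
}
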