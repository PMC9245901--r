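#' Decode behavioral labels from latent factors, against dummy baselines
#'
#' Supervised sanity check on the latent representation: a random forest
#' (library defaults) decodes the per-bin behavioral label under
#' trial-wise cross-validation (whole trials are never split across
#' train and test). Two dummy baselines are scored on the same folds:
#' "stratified" draws each test label from the training label
#' distribution, "most frequent" always predicts the training majority
#' class. The classifier is compared to each baseline with a one-sided
#' Wilcoxon signed-rank test across folds (zero differences dropped);
#' the reported p is the larger of the two.
#'
#' @param features `bins x features` matrix (GPFA factors by default in
#'   the pipeline; binned counts work too).
#' @param labels per-bin behavioral labels.
#' @param trial_ids per-bin trial identifiers.
#' @param folds number of trial-wise folds (default 10).
#' @param seed RNG seed (fold assignment, forest, stratified draws).
#' @return list: `accuracy` (per fold), `accuracy_stratified`,
#'   `accuracy_majority`, `p_stratified`, `p_majority`, `p` (max),
#'   `rf_params`.
#' @export
decode_vs_baselines <- function(features, labels, trial_ids, folds = 10,
                                seed = 1) {
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(trial_ids))
  trials <- unique(trial_ids)
  if (folds > length(trials))
    stop(errorCondition("more folds than trials",
                        class = c("neuroethogram_validation_error", "error")))
  labels <- factor(labels)
  set.seed(seed)
  fold_of_trial <- stats::setNames(
    sample(rep(seq_len(folds), length.out = length(trials))), trials)
  fold <- fold_of_trial[trial_ids]
  acc <- accs <- accm <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    ytr <- droplevels(labels[tr])
    if (nlevels(ytr) < 2) {
      # degenerate training fold: constant classifier
      pred <- factor(rep(levels(ytr)[1], sum(te)), levels = levels(labels))
    } else {
      rf <- randomForest::randomForest(
        x = features[tr, , drop = FALSE], y = ytr)
      pred <- stats::predict(rf, features[te, , drop = FALSE])
    }
    acc[f] <- mean(as.character(pred) == as.character(labels[te]))
    p_train <- table(labels[tr]) / sum(tr)
    draw <- sample(names(p_train), sum(te), replace = TRUE,
                   prob = as.numeric(p_train))
    accs[f] <- mean(draw == as.character(labels[te]))
    maj <- names(p_train)[which.max(p_train)]
    accm[f] <- mean(as.character(labels[te]) == maj)
  }
  one_sided <- function(a, b) {
    if (all(a == b)) return(1)
    tryCatch(
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          alternative = "greater")$p.value),
      error = function(e) 1)
  }
  p_s <- one_sided(acc, accs)
  p_m <- one_sided(acc, accm)
  list(accuracy = acc, accuracy_stratified = accs, accuracy_majority = accm,
       p_stratified = p_s, p_majority = p_m, p = max(p_s, p_m),
       rf_params = list(ntree = 500, mtry = "floor(sqrt(p))",
                        nodesize = 1))
}
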