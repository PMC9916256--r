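# Ranking metrics for positive-unlabeled interaction prediction, seeded
# cross-validation, and the top-k% unlabeled-pair labeling curve.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with ties counted 1/2.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_roc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)) # 0.75
auc_roc <- function(scores, labels) {
  check_scored(scores, labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores) # midranks handle ties at 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: precision accumulated at each positive in
#' the score-descending ranking (stepwise sum of precision times recall
#' increments). Ties are broken by original position, matching the stable
#' ordering used everywhere else in the package.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector of the same length.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  check_scored(scores, labels)
  ord <- order(-scores) # stable: ties keep input order
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab == 1]) / sum(lab)
}

check_scored <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_input("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop_input("labels must be 0/1")
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    stop_input("both classes must be present to compute a ranking metric")
  }
  invisible(TRUE)
}

#' Top-k% labeling of unlabeled pairs
#'
#' Ranks unlabeled pairs by predicted score, keeps the top `ceiling(k% * n)`,
#' and counts how many of those score at least `theta` — the number of
#' unlabeled pairs the model would newly label as interacting at that depth.
#' Ties are broken by stable original order.
#'
#' @param unlabeled_scores Numeric scores of the unlabeled pairs.
#' @param k_percent Depth of the ranking to inspect, in `(0, 100]`.
#' @param theta Labeling threshold in `[0, 1]`. Default 0.5.
#' @return List with `n_considered` and `n_labeled`.
#' @export
topk_labeling <- function(unlabeled_scores, k_percent, theta = 0.5) {
  if (length(unlabeled_scores) == 0L) stop_input("empty score list")
  if (!(k_percent > 0 && k_percent <= 100)) {
    stop_input("k_percent must lie in (0, 100]")
  }
  if (!(theta >= 0 && theta <= 1)) stop_input("theta must lie in [0, 1]")
  n <- length(unlabeled_scores)
  n_considered <- ceiling(k_percent / 100 * n)
  top <- utils::head(order(-unlabeled_scores), n_considered)
  list(n_considered = n_considered,
       n_labeled = sum(unlabeled_scores[top] >= theta))
}

#' Top-k% labeling curve over a grid of depths
#'
#' @param unlabeled_scores Numeric scores of unlabeled pairs.
#' @param k_grid Vector of depths (percent). Default `seq(10, 100, 10)`.
#' @param theta Labeling threshold. Default 0.5.
#' @return Data frame with columns `top_k`, `unlabeled` (pairs considered) and
#'   `labeled` (pairs called positive); both counts are non-decreasing in `k`.
#' @export
topk_curve <- function(unlabeled_scores, k_grid = seq(10, 100, 10),
                       theta = 0.5) {
  rows <- lapply(k_grid, function(k) {
    r <- topk_labeling(unlabeled_scores, k, theta)
    data.frame(top_k = k, unlabeled = r$n_considered, labeled = r$n_labeled)
  })
  do.call(rbind, rows)
}

#' Seeded cross-validated AUC/AUPR on an interaction dataset
#'
#' For each CV seed, the known interacting pairs are split into `n_folds`
#' folds and an equal-sized negative sample is drawn (per fold, disjointly)
#' from the non-interacting pairs — the positive-unlabeled convention of
#' treating unknown pairs as sampled negatives. A model is trained on each
#' training fold-set and scores its held-out fold; the pooled held-out scores
#' give one AUC and one AUPR per seed, reported as percentages to two
#' decimals. The seed controls fold assignment, negative sampling, and weight
#' initialisation, so identical seeds reproduce identical rows.
#'
#' @param dataset A feature-bearing interaction dataset
#'   ([generate_synthetic_dti()] or [read_interaction_matrix()] +
#'   [profile_features()]).
#' @param cv_seeds Integer vector of CV repetition seeds.
#' @param hyper [mlstm_control()] list used for every training (when `sso` is
#'   `NULL`).
#' @param n_folds Number of folds. Default 5.
#' @param sso Optional list with elements `np`, `t_max` (and optionally `box`,
#'   `epochs`): tune hyperparameters once per seed on the first fold's
#'   training pairs before cross-validating.
#' @param quiet Suppress progress messages. Default `TRUE`.
#' @return Data frame with one row per seed: `cv_seed`, `auc`, `aupr`
#'   (percent).
#' @export
cv_evaluate <- function(dataset, cv_seeds, hyper = mlstm_control(),
                        n_folds = 5L, sso = NULL, quiet = TRUE) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (length(cv_seeds) == 0L) stop_input("cv_seeds must be non-empty")
  A <- dataset$interactions
  pos <- which(A == 1, arr.ind = TRUE)
  neg_pool <- which(A == 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop_input("dataset has no positive interactions")
  rows <- lapply(cv_seeds, function(sd) {
    folds_p <- with_seed(derive_seed(sd, "folds"),
                         sample(rep_len(seq_len(n_folds), nrow(pos))))
    neg_idx <- with_seed(derive_seed(sd, "negatives"),
                         sample.int(nrow(neg_pool), min(nrow(pos),
                                                        nrow(neg_pool))))
    neg <- neg_pool[neg_idx, , drop = FALSE]
    folds_n <- with_seed(derive_seed(sd, "negfolds"),
                         sample(rep_len(seq_len(n_folds), nrow(neg))))
    hp <- hyper
    scores <- numeric(0); labels <- numeric(0)
    for (fold in seq_len(n_folds)) {
      tr_pairs <- rbind(pos[folds_p != fold, , drop = FALSE],
                        neg[folds_n != fold, , drop = FALSE])
      te_pairs <- rbind(pos[folds_p == fold, , drop = FALSE],
                        neg[folds_n == fold, , drop = FALSE])
      tr_lab <- c(rep(1, sum(folds_p != fold)), rep(0, sum(folds_n != fold)))
      te_lab <- c(rep(1, sum(folds_p == fold)), rep(0, sum(folds_n == fold)))
      if (sum(te_lab) == 0L || sum(te_lab == 0) == 0L) {
        warning("degenerate fold ", fold, " for seed ", sd, "; re-split",
                call. = FALSE)
        next
      }
      xtr <- pair_sequences(dataset, tr_pairs)
      ytr <- label_matrix(tr_lab, dataset$spec$C)
      if (fold == 1L && !is.null(sso)) {
        tuned <- tune_mlstm(xtr, ytr,
                            box = sso$box %||% default_hyper_box(),
                            np = sso$np %||% 10L, t_max = sso$t_max %||% 20L,
                            seed = derive_seed(sd, "tune"),
                            epochs = sso$epochs %||% 6L)
        hp <- mlstm_control(hidden = tuned$hyper$hidden,
                            lr = tuned$hyper$lr,
                            epochs = hyper$epochs,
                            batch_size = tuned$hyper$batch_size,
                            gamma = tuned$hyper$gamma,
                            dropout = tuned$hyper$dropout %||% 0,
                            val_frac = hyper$val_frac)
      }
      fit <- mlstm_train(xtr, ytr, hp, seed = derive_seed(sd, paste0("f", fold)))
      xte <- pair_sequences(dataset, te_pairs)
      p <- predict_scores(fit, xte)
      scores <- c(scores, p[, 1L])
      labels <- c(labels, te_lab)
      if (!quiet) message("seed ", sd, " fold ", fold, " done")
    }
    data.frame(cv_seed = sd,
               auc = round(auc_roc(scores, labels) * 100, 2),
               aupr = round(aupr(scores, labels) * 100, 2))
  })
  do.call(rbind, rows)
}

# Binary fold labels -> N x C multilabel matrix matching the generator's
# layout: column 1 = interacting, column 2 = non-interacting, extra type
# columns zero for sampled pairs.
label_matrix <- function(lab, C) {
  y <- matrix(0, length(lab), C)
  y[, 1L] <- lab
  y[, 2L] <- 1 - lab
  y
}
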