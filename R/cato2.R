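# Two-stage logistic scoring of regulatory variants: a global
# genomic-annotation model, per-TF motif-disruption models gated by
# cell-type enrichment, and a lasso-penalized combiner over per-TF-cluster
# scores. Squared terms in the model formulas are realized as additional
# squared columns of the (standardized) annotation values.

#' @importFrom stats glm binomial coef fitted
#' @importFrom glmnet cv.glmnet
NULL

.quant_cols <- c("mcv", "dist_tss", "dhs_strength", "dhs_width",
                 "n_nearby_sites", "conservation")

#' Standardize genomic annotations against a reference cohort
#'
#' Two steps: (1) each quantitative column of `a` is multiplied by the ratio
#' of the reference cohort's mean to `a`'s mean (cross-cohort scale
#' matching); (2) columns are z-scored using the pooled training set's mean
#' and SD. The parameters are stored and must be reused verbatim when
#' scoring new data (pass them back via `params`).
#'
#' Distance-to-TSS and DHS width are log-transformed (`log(x + 1)`, guarding
#' zeros for SNVs inside a TSS-overlapping DHS) before scaling.
#'
#' @param a Annotation data.frame (`snv_id`, `mcv`, `intron`, `intergenic`,
#'   `dist_tss`, `dhs_strength`, `dhs_width`, `footprint`,
#'   `n_nearby_sites`, `conservation`).
#' @param b Optional reference cohort with the same columns; `NULL` means no
#'   cross-cohort scaling (factors 1).
#' @param params Stored parameters from a previous call; when supplied, `b`
#'   is ignored and the stored transform is applied.
#' @param quantitative Columns receiving the mean-ratio scaling.
#' @return List: `a` (standardized annotations), `b` (standardized reference
#'   cohort, when given), `params` (`scale`, `center`, `sd`).
#' @export
standardize_annotations <- function(a, b = NULL, params = NULL,
                                    quantitative = .quant_cols) {
  transform_logs <- function(x) {
    x$dist_tss <- log(x$dist_tss + 1)
    x$dhs_width <- log(x$dhs_width + 1)
    x
  }
  a <- transform_logs(a)
  if (!is.null(b)) b <- transform_logs(b)
  num_cols <- setdiff(names(a), "snv_id")
  if (is.null(params)) {
    scale_f <- setNames(rep(1, length(quantitative)), quantitative)
    if (!is.null(b)) {
      for (cl in quantitative) {
        ma <- mean(a[[cl]])
        if (ma == 0) stop("zero mean in cohort A for column '", cl,
                          "'; cannot scale")
        scale_f[cl] <- mean(b[[cl]]) / ma
      }
    }
    for (cl in quantitative) a[[cl]] <- a[[cl]] * scale_f[cl]
    pooled <- if (is.null(b)) a else rbind(a[num_cols], b[num_cols])
    center <- vapply(pooled[num_cols], mean, numeric(1))
    sdv <- vapply(pooled[num_cols], sd, numeric(1))
    sdv[sdv == 0] <- 1
    params <- list(scale = scale_f, center = center, sd = sdv)
  } else {
    for (cl in quantitative) a[[cl]] <- a[[cl]] * params$scale[cl]
  }
  z <- function(x) {
    for (cl in num_cols) x[[cl]] <- (x[[cl]] - params$center[cl]) /
        params$sd[cl]
    x
  }
  out <- list(a = z(a), params = params)
  if (!is.null(b)) out$b <- z(b[c("snv_id", num_cols)])
  out
}

# Global-model design matrix: linear terms for every annotation plus squared
# columns for MCV, log distance-to-TSS, DHS strength and nearby-site count.
global_design <- function(ann) {
  data.frame(
    mcv = ann$mcv, mcv_sq = ann$mcv^2,
    intron = ann$intron, intergenic = ann$intergenic,
    log_dist_tss = ann$dist_tss, log_dist_tss_sq = ann$dist_tss^2,
    dhs_strength = ann$dhs_strength, dhs_strength_sq = ann$dhs_strength^2,
    log_dhs_width = ann$dhs_width,
    footprint = ann$footprint,
    n_nearby = ann$n_nearby_sites, n_nearby_sq = ann$n_nearby_sites^2,
    conservation = ann$conservation)
}

#' Fit the global genomic-annotation logistic model
#'
#' Logistic regression of imbalance labels on the standardized annotation
#' set, with squared terms for cell-type activity (MCV), log distance to
#' TSS, DHS strength and nearby-binding-site count.
#'
#' @param ann Standardized annotations (output of
#'   [standardize_annotations()], already log-transformed and z-scored).
#' @param labels Logical/0-1 vector of imbalance labels aligned with `ann`.
#' @return List of class `cato2_global`: `model` (a `glm`), `fitted`
#'   (per-SNV probabilities), `snv_id`.
#' @export
fit_global_model <- function(ann, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("global model requires both label classes")
  }
  X <- global_design(ann)
  fit <- glm(labels ~ ., data = cbind(labels = labels, X),
             family = binomial())
  if (!fit$converged) stop("global model failed to converge; check ",
                           "annotation scaling and label balance")
  res <- list(model = fit, fitted = as.numeric(fitted(fit)),
              snv_id = ann$snv_id)
  class(res) <- "cato2_global"
  res
}

#' Fit a per-TF motif-disruption logistic model
#'
#' Logistic model over SNVs overlapping one motif: the global-model fitted
#' probability, the log motif match score (linear and squared), the
#' ref-vs-alt log-odds difference, and per-position indicator covariates for
#' motif positions with enough data (at least `min_pos_count` rows).
#' Constant columns are dropped with a warning. Training rows should come
#' from gated cell types only (the caller restricts rows; see
#' [celltype_enrichment()]).
#'
#' @param motif_id Motif identifier (metadata).
#' @param feats data.frame per (SNV, motif) row: `snv_id`, `global_fit`,
#'   `score` (match score, positive), `logodds_diff`, `position` (0-based
#'   position of the SNV in the motif).
#' @param labels Logical/0-1 labels aligned with `feats`.
#' @param min_rows Minimum training rows; below it the TF is skipped
#'   (returns `NULL`) with a message.
#' @param min_pos_count Minimum rows for a position indicator (default 7).
#' @return List of class `cato2_tf` (`model`, `motif_id`, `positions`,
#'   `dropped`), or `NULL` when skipped.
#' @export
fit_tf_model <- function(motif_id, feats, labels, min_rows = 50,
                         min_pos_count = 7) {
  labels <- as.integer(labels)
  if (nrow(feats) < min_rows || length(unique(labels)) < 2L) {
    message("TF ", motif_id, " skipped: ", nrow(feats), " rows")
    return(NULL)
  }
  X <- data.frame(global_fit = feats$global_fit,
                  log_score = log(feats$score),
                  log_score_sq = log(feats$score)^2,
                  logodds_diff = feats$logodds_diff)
  pos_tab <- table(feats$position)
  keep_pos <- as.integer(names(pos_tab)[pos_tab >= min_pos_count])
  if (length(keep_pos)) {
    keep_pos <- setdiff(keep_pos, min(keep_pos))  # reference position
  }
  for (p in keep_pos) X[[paste0("pos_", p)]] <- as.integer(feats$position == p)
  const <- vapply(X, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) {
    warning("TF ", motif_id, ": constant column(s) dropped: ",
            paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  fit <- suppressWarnings(glm(labels ~ ., data = cbind(labels = labels, X),
                              family = binomial()))
  res <- list(model = fit, motif_id = motif_id, positions = keep_pos,
              dropped = names(const)[const], columns = names(X))
  class(res) <- "cato2_tf"
  res
}

# Score one TF model on new feature rows, rebuilding its design columns.
predict_tf_model <- function(tf, feats) {
  X <- data.frame(global_fit = feats$global_fit,
                  log_score = log(feats$score),
                  log_score_sq = log(feats$score)^2,
                  logodds_diff = feats$logodds_diff)
  for (p in tf$positions) X[[paste0("pos_", p)]] <-
      as.integer(feats$position == p)
  X <- X[intersect(tf$columns, names(X))]
  for (cl in setdiff(tf$columns, names(X))) X[[cl]] <- 0
  as.numeric(predict(tf$model, newdata = X, type = "response"))
}

#' Fit the sparse lasso combiner over per-TF-cluster scores
#'
#' Lasso-penalized logistic regression combining the best per-TF-cluster
#' model scores at each SNV (plus the global-model probability as its own
#' column, which also provides the fallback pathway for SNVs with no motif
#' overlap). The penalty is chosen by cross-validated AUC at its maximum
#' (`lambda.min`); folds are assigned by seeded permutation stratified by
#' label.
#'
#' @param scores Numeric matrix (SNVs x feature columns); zero where a SNV
#'   has no overlap with a cluster's motifs. Column names required.
#' @param labels Logical/0-1 labels.
#' @param nfolds Cross-validation folds (default 50); reduced with a warning
#'   when `nfolds > n/2`.
#' @param seed Seed for fold assignment.
#' @return List of class `cato2_combiner`: `fit` (cv.glmnet), `lambda`,
#'   `n_nonzero` (non-zero feature coefficients at the selected penalty),
#'   `cv_auc`.
#' @export
fit_combiner <- function(scores, labels, nfolds = 50, seed = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (nfolds > n / 2) {
    warning("nfolds reduced from ", nfolds, " to ", max(3L, floor(n / 10)))
    nfolds <- max(3L, floor(n / 10))
  }
  if (ncol(scores) < 2L) {
    # lasso solver requires >= 2 columns; pad with an all-zero feature
    # whose coefficient is structurally zero
    scores <- cbind(scores, .zero_pad = 0)
  }
  set.seed(seed)
  foldid <- integer(n)
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    foldid[i] <- sample(rep_len(seq_len(nfolds), length(i)))
  }
  fit <- glmnet::cv.glmnet(scores, labels, family = "binomial",
                           type.measure = "auc", alpha = 1, foldid = foldid)
  cf <- coef(fit, s = "lambda.min")
  nz <- sum(cf[-1, 1] != 0)
  res <- list(fit = fit, lambda = fit$lambda.min, n_nonzero = nz,
              cv_auc = max(fit$cvm))
  class(res) <- "cato2_combiner"
  res
}

#' Train the full two-stage scoring bundle
#'
#' Convenience wrapper: standardizes annotations, fits the global model,
#' fits gated per-TF models, arranges best-per-cluster scores and fits the
#' combiner.
#'
#' @param ann Raw annotations.
#' @param labels Per-SNV imbalance labels aligned with `ann` (aggregate or
#'   cell-type-specific, the caller's choice).
#' @param tf_feats Named list (by motif_id) of per-TF feature frames (see
#'   [fit_tf_model()]); the caller restricts rows to gated cell types'
#'   SNVs.
#' @param tf_labels Named list of label vectors aligned with `tf_feats`.
#' @param cluster_map data.frame (`motif_id`, `cluster_id`); motifs absent
#'   from the map form singleton clusters.
#' @param reference_cohort Optional second cohort for annotation scaling.
#' @param nfolds,seed Combiner settings.
#' @param min_rows Per-TF minimum training rows.
#' @return List of class `cato2_bundle`: `params`, `global`, `tf_models`,
#'   `combiner`, `cluster_map`, `feature_names`.
#' @export
train_cato2 <- function(ann, labels, tf_feats, tf_labels, cluster_map = NULL,
                        reference_cohort = NULL, nfolds = 50, seed = 1,
                        min_rows = 50) {
  std <- standardize_annotations(ann, b = reference_cohort)
  global <- fit_global_model(std$a, labels)
  gf <- setNames(global$fitted, std$a$snv_id)
  tf_models <- list()
  for (mid in names(tf_feats)) {
    ft <- tf_feats[[mid]]
    ft$global_fit <- gf[ft$snv_id]
    m <- fit_tf_model(mid, ft, tf_labels[[mid]], min_rows = min_rows)
    if (!is.null(m)) tf_models[[mid]] <- m
  }
  feat <- combiner_features(std$a$snv_id, gf, tf_models, tf_feats,
                            cluster_map)
  combiner <- fit_combiner(feat, labels, nfolds = nfolds, seed = seed)
  res <- list(params = std$params, global = global, tf_models = tf_models,
              combiner = combiner, cluster_map = cluster_map,
              feature_names = colnames(feat))
  class(res) <- "cato2_bundle"
  res
}

# Best per-cluster TF-model score per SNV, plus the global probability
# column; zero where a SNV overlaps no motif of a cluster.
combiner_features <- function(snv_ids, global_fit, tf_models, tf_feats,
                              cluster_map) {
  cluster_of <- function(mid) {
    if (is.null(cluster_map)) return(mid)
    i <- match(mid, cluster_map$motif_id)
    if (is.na(i)) mid else cluster_map$cluster_id[i]
  }
  clusters <- unique(vapply(names(tf_models), cluster_of, character(1)))
  feat <- matrix(0, length(snv_ids), 1L + length(clusters),
                 dimnames = list(snv_ids, c("global", clusters)))
  feat[, "global"] <- global_fit[snv_ids]
  for (mid in names(tf_models)) {
    ft <- tf_feats[[mid]]
    ft$global_fit <- global_fit[ft$snv_id]
    sc <- predict_tf_model(tf_models[[mid]], ft)
    cl <- cluster_of(mid)
    i <- match(ft$snv_id, snv_ids)
    ok <- !is.na(i)
    cur <- feat[i[ok], cl]
    feat[i[ok], cl] <- pmax(cur, sc[ok])
  }
  feat
}

#' Score variants with a trained bundle
#'
#' Pure function of (bundle, inputs): standardizes the annotations with the
#' bundle's stored parameters, computes the global probability, per-TF model
#' scores for SNVs overlapping each motif, arranges best-per-cluster
#' features and returns the combiner response in `[0, 1]`. SNVs with no
#' motif overlap are scored through the global column and the combiner
#' intercept alone.
#'
#' @param bundle A `cato2_bundle`.
#' @param ann Raw annotations for the SNVs to score.
#' @param tf_feats Named list of per-TF feature frames for the new SNVs
#'   (`snv_id`, `score`, `logodds_diff`, `position`); may be empty.
#' @return data.frame (`snv_id`, `score`).
#' @export
score_variants <- function(bundle, ann, tf_feats = list()) {
  need <- c("snv_id", .quant_cols, "intron", "intergenic", "footprint")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation columns missing: ",
                         paste(miss, collapse = ", "))
  std <- standardize_annotations(ann, params = bundle$params)
  X <- global_design(std$a)
  gp <- as.numeric(predict(bundle$global$model, newdata = X,
                           type = "response"))
  gf <- setNames(gp, std$a$snv_id)
  feat <- combiner_features(std$a$snv_id, gf,
                            bundle$tf_models[
                              intersect(names(bundle$tf_models),
                                        names(tf_feats))],
                            tf_feats, bundle$cluster_map)
  # align columns with the combiner's training-time feature set (including
  # any structural zero pad)
  train_cols <- rownames(coef(bundle$combiner$fit, s = "lambda.min"))[-1]
  full <- matrix(0, nrow(feat), length(train_cols),
                 dimnames = list(rownames(feat), train_cols))
  common <- intersect(colnames(feat), train_cols)
  full[, common] <- feat[, common]
  sc <- as.numeric(predict(bundle$combiner$fit, newx = full,
                           s = "lambda.min", type = "response"))
  data.frame(snv_id = std$a$snv_id, score = sc, stringsAsFactors = FALSE)
}

#' Precision-recall curve and area
#'
#' Curve over all score thresholds (descending unique scores); area by
#' trapezoid on the recall grid; the positive-class prevalence is reported
#' as the chance baseline.
#'
#' @param scores Numeric scores.
#' @param labels Logical/0-1 labels; both classes must be present.
#' @return List: `curve` (data.frame `threshold`, `recall`, `precision`),
#'   `auprc`, `baseline`.
#' @export
precision_recall <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both label classes required")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  # evaluate at the last index of each unique score (threshold = that score)
  last <- !duplicated(sc, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- sc[last]
  npos <- sum(lab)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  r <- c(0, recall); p <- c(precision[1], precision)
  auprc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  list(curve = data.frame(threshold = thr, recall = recall,
                          precision = precision),
       auprc = auprc, baseline = npos / length(labels))
}
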