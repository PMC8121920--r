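mk_ann <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    snv_id = sprintf("s%05d", seq_len(n)),
    mcv = runif(n),
    intron = as.integer(runif(n) < 0.4),
    intergenic = as.integer(runif(n) < 0.3),
    dist_tss = as.integer(round(rlnorm(n, log(20000), 1.2))),
    dhs_strength = rgamma(n, 2, 0.5),
    dhs_width = as.integer(round(runif(n, 150, 500))),
    footprint = as.integer(runif(n) < 0.3),
    n_nearby_sites = rpois(n, 2),
    conservation = runif(n),
    stringsAsFactors = FALSE)
}

test_that("annotation standardization scales, centers and is reusable", {
  a <- mk_ann(500, seed = 1)
  b <- mk_ann(500, seed = 2)
  b$mcv <- b$mcv * 2  # cohort B twice the mean -> scale factor ~2 applied to A
  std <- standardize_annotations(a, b)
  expect_equal(unname(std$params$scale["mcv"]),
               mean(b$mcv) / mean(a$mcv))
  num <- setdiff(names(std$a), "snv_id")
  pooled <- rbind(std$a[num], std$b[num])
  expect_true(all(abs(colMeans(pooled)) < 1e-10))
  expect_true(all(abs(apply(pooled, 2, sd) - 1) < 1e-10))
  # self-standardization: factors 1, unit-variance columns
  std_self <- standardize_annotations(a)
  expect_true(all(std_self$params$scale == 1))
  expect_true(all(abs(colMeans(std_self$a[num])) < 1e-10))
  # parameter reuse contract: applying stored params reproduces the output
  again <- standardize_annotations(a, params = std$params)
  expect_equal(again$a, std$a)
  # zero-mean scaled column is an error
  a0 <- a; a0$mcv <- 0
  expect_error(standardize_annotations(a0, b), "mcv")
})

test_that("global model: no-signal null AUC ~ 0.5 and recovery of a known model", {
  set.seed(30)
  n <- 6000
  a <- mk_ann(n, seed = 3)
  std <- standardize_annotations(a)
  # labels independent of annotations
  lab0 <- runif(n) < 0.2
  g0 <- fit_global_model(std$a, lab0)
  pr <- precision_recall(g0$fitted, lab0)
  expect_lt(abs(pr$auprc - pr$baseline), 0.05)
  # labels generated from a known logistic model on the same features
  eta <- -2 + 1.5 * std$a$mcv + 1.0 * std$a$footprint -
    0.8 * std$a$dist_tss
  lab1 <- runif(n) < plogis(eta)
  g1 <- fit_global_model(std$a, lab1)
  cf <- coef(g1$model)
  se <- sqrt(diag(vcov(g1$model)))
  expect_lt(abs(cf["mcv"] - 1.5), 2.5 * se["mcv"] + 0.15)
  expect_lt(abs(cf["footprint"] - 1.0), 2.5 * se["footprint"] + 0.15)
  expect_error(fit_global_model(std$a, rep(TRUE, n)), "both label classes")
})

test_that("per-TF model puts largest positive weights on causal positions", {
  set.seed(31)
  n <- 3000
  feats <- data.frame(snv_id = sprintf("s%d", 1:n),
                      global_fit = runif(n, 0.05, 0.3),
                      score = exp(runif(n, 1, 3)),
                      logodds_diff = rnorm(n),
                      position = sample(0:9, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  causal_pos <- feats$position %in% c(3, 4)
  labels <- runif(n) < ifelse(causal_pos, 0.6, 0.05)
  tf <- fit_tf_model("TFX", feats, labels)
  cf <- coef(tf$model)
  pos_cf <- cf[grep("^pos_", names(cf))]
  top2 <- names(sort(pos_cf, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("pos_3", "pos_4"))
  # too few rows -> skipped
  expect_message(r <- fit_tf_model("TFY", feats[1:10, ], labels[1:10]),
                 "skipped")
  expect_null(r)
  # constant column dropped with a warning
  f2 <- feats; f2$logodds_diff <- 0
  expect_warning(tf2 <- fit_tf_model("TFZ", f2, labels), "constant")
  expect_false("logodds_diff" %in% tf2$columns)
})

test_that("lasso combiner recovers sparse signal and reports CV-AUC", {
  set.seed(32)
  n <- 1200; p_noise <- 30
  informative <- rnorm(n)
  labels <- runif(n) < plogis(-1 + 2 * informative)
  X <- cbind(informative = informative,
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, sprintf("noise%02d", 1:p_noise))))
  cb <- fit_combiner(X, labels, nfolds = 10, seed = 5)
  cf <- coef(cb$fit, s = "lambda.min")[-1, 1]
  expect_true(cf["informative"] != 0)
  expect_gte(mean(cf[grep("noise", names(cf))] == 0), 0.9)
  expect_gt(cb$cv_auc, 0.8)
  # all-noise features: CV-AUC near chance
  Xn <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("n", 1:10)))
  cbn <- fit_combiner(Xn, labels, nfolds = 10, seed = 6)
  expect_lte(cbn$cv_auc, 0.58)
  # folds > n/2 reduced with warning
  expect_warning(fit_combiner(X[1:40, ], labels[1:40], nfolds = 50,
                              seed = 7), "nfolds reduced")
})

test_that("duplicated feature columns leave combiner predictions unchanged", {
  set.seed(33)
  n <- 600
  x <- rnorm(n)
  labels <- runif(n) < plogis(2 * x)
  X1 <- cbind(a = x, b = rnorm(n))
  X2 <- cbind(a = x, a2 = x, b = X1[, "b"])
  cb1 <- fit_combiner(X1, labels, nfolds = 10, seed = 8)
  cb2 <- fit_combiner(X2, labels, nfolds = 10, seed = 8)
  p1 <- predict(cb1$fit, newx = X1, s = "lambda.min", type = "response")
  p2 <- predict(cb2$fit, newx = X2, s = "lambda.min", type = "response")
  expect_lt(max(abs(p1 - p2)), 0.05)
})

test_that("precision-recall matches a brute-force threshold sweep", {
  set.seed(34)
  n <- 1000
  scores <- runif(n)
  labels <- runif(n) < plogis(3 * (scores - 0.5))
  pr <- precision_recall(scores, labels)
  # brute force over every unique threshold
  brute <- t(vapply(sort(unique(scores), decreasing = TRUE), function(t) {
    sel <- scores >= t
    c(recall = sum(labels & sel) / sum(labels),
      precision = sum(labels & sel) / sum(sel))
  }, numeric(2)))
  r <- c(0, brute[, "recall"]); p <- c(brute[1, "precision"],
                                       brute[, "precision"])
  auc_brute <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  expect_lt(abs(pr$auprc - auc_brute), 1e-9)
  # perfect separation
  expect_equal(precision_recall(labels * 1.0, labels)$auprc, 1)
  # random scores: AUPR ~ prevalence
  pr_rand <- precision_recall(runif(n), labels)
  expect_lt(abs(pr_rand$auprc - pr_rand$baseline), 0.1)
  expect_error(precision_recall(scores, rep(1, n)), "both label classes")
})

test_that("end-to-end scoring: bounded, pure, and beats the prevalence baseline", {
  set.seed(35)
  ch <- simulate_cohort(sim_config(n_snvs = 4000, fraction_causal = 0.1,
                                   p_shared = 1, depth_mu = 100, seed = 51))
  pooled <- pool_counts(ch$counts, ch$scheme, "aggregate")
  nulls <- fit_nulls(pooled)
  calls <- call_imbalance(pooled, nulls, level = "aggregate")
  status <- merge(calls[c("snv_id", "imbalanced")],
                  ch$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")
  ann <- ch$annotations[match(status$snv_id, ch$annotations$snv_id), ]
  labels <- status$imbalanced
  tf <- ascap:::build_tf_features(ch, status)
  bundle <- train_cato2(ann, labels, tf$feats, tf$labels, nfolds = 10,
                        seed = 52, min_rows = 10)
  sc <- score_variants(bundle, ann, tf$feats)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # purity: identical inputs give identical scores
  sc2 <- score_variants(bundle, ann, tf$feats)
  expect_identical(sc, sc2)
  pr <- precision_recall(sc$score[match(status$snv_id, sc$snv_id)], labels)
  expect_gt(pr$auprc, 2 * pr$baseline)
  # missing annotation columns are named in the error
  expect_error(score_variants(bundle, ann[setdiff(names(ann), "mcv")],
                              tf$feats), "mcv")
})

test_that("cell-type-specific models beat the aggregate model on cell-type-specific architectures", {
  # sign test over 10 seeds: a bundle trained on per-cell-type labels
  # (matched cell type) vs one trained on aggregate labels, both scored
  # against the cell type's truth
  auprs <- function(sd_i) {
    set.seed(1000 + sd_i)
    ch <- simulate_cohort(sim_config(n_snvs = 2500, fraction_causal = 0.12,
                                     p_shared = 0, depth_mu = 80,
                                     cell_types = c("liver", "kidney"),
                                     seed = 1000 + sd_i))
    calls_for <- function(level) {
      pooled <- pool_counts(ch$counts, ch$scheme, level)
      call_imbalance(pooled, fit_nulls(pooled), level = level)
    }
    liver <- calls_for("cell_type")
    liver <- liver[liver$group_id == "liver", ]
    agg <- calls_for("aggregate")
    common <- intersect(liver$snv_id, agg$snv_id)
    te <- ch$true_effects[ch$true_effects$cell_type == "liver", ]
    truth <- te$theta[match(common, te$snv_id)] != 0.5
    if (sum(truth) < 5) return(NULL)
    train_eval <- function(calls) {
      status <- merge(calls[c("snv_id", "imbalanced")],
                      ch$snvs[c("snv_id", "chrom", "pos")], by = "snv_id")
      ann <- ch$annotations[match(status$snv_id, ch$annotations$snv_id), ]
      tf <- ascap:::build_tf_features(ch, status)
      bundle <- train_cato2(ann, status$imbalanced, tf$feats, tf$labels,
                            nfolds = 5, seed = sd_i, min_rows = 10)
      sc <- score_variants(bundle, ann, tf$feats)
      precision_recall(sc$score[match(common, sc$snv_id)], truth)$auprc
    }
    c(ct = train_eval(liver), agg = train_eval(agg))
  }
  wins <- 0; total <- 0
  for (sd_i in 1:10) {
    a <- auprs(sd_i)
    if (is.null(a)) next
    total <- total + 1
    if (a["ct"] > a["agg"]) wins <- wins + 1
  }
  # one-sided binomial sign test at alpha = 0.05
  expect_lt(binom.test(wins, total, alternative = "greater")$p.value, 0.05)
})
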