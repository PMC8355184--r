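#' Feature groupings for the evaluation harness
#'
#' Named models mirroring how related metrics are combined in a single
#' regression: enhancer (sharing + total), TF (shared + total), CTCF
#' (total + inverted), expression (level + CV differences), eQTL sharing
#' (sharing + co-expressed eGenes), distance, Hi-C, GO, LD, and a combined
#' model over all features.
#'
#' @param columns available feature columns (models are restricted to
#'   these); defaults to the full set.
#' @return Named list of character vectors of feature columns.
#' @export
model_specs <- function(columns = feature_columns) {
  specs <- list(
    distance = "tss_distance",
    ctcf = c("total_ctcf", "inverted_ctcf"),
    hic = "hic_contact",
    enhancer = c("enh_sharing", "enh_total"),
    tf = c("tf_shared", "tfbs_total"),
    expression = c("diff_expr_level", "diff_coef_var"),
    go = "go_sharing",
    ld = "ld_proxy",
    eqtl_sharing = c("eqtl_sharing", "coexp_egenes"))
  specs <- lapply(specs, intersect, columns)
  specs <- specs[lengths(specs) > 0]
  specs$combined <- setdiff(unique(unlist(specs)), "tss_distance")
  specs
}

# rank-free AUC via pROC with fixed direction so no-signal features sit at 0.5
roc_auc <- function(labels, scores) {
  if (length(unique(scores)) < 2) return(0.5)
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("0", "1"),
                                 direction = "<", quiet = TRUE)))
}

#' Evaluate a feature model by repeated split logistic regression
#'
#' Per repetition: stratified 80/20 train/test split preserving the class
#' balance, features standardized with training-fold statistics, plain
#' logistic regression with intercept fitted on the training pairs, ROC
#' AUC measured on the held-out pairs. Split seeds derive from
#' `(seed, rep)` so individual repetitions are reproducible.
#'
#' @param table feature table with a 0/1 `label` column (see
#'   [assemble_features()]).
#' @param features character vector of feature columns for this model.
#' @param reps number of randomisations (default 50).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return A `locop_auc` list: `model` features, `auc` (per-rep vector),
#'   `mean_auc`, `seed`.
#' @export
evaluate_model <- function(table, features, reps = 50, train_frac = 0.8,
                           seed = 1) {
  stopifnot(all(features %in% names(table)), "label" %in% names(table),
            all(table$label %in% c(0, 1)), train_frac > 0, train_frac < 1)
  if (length(unique(table$label)) < 2) stop("need both labels present")
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$label
  if (sum(apply(X, 2, function(c) length(unique(c))) >= 2) == 0) {
    warning("fewer than 2 distinct feature values; AUC 0.5")
    return(structure(list(model = features, auc = rep(0.5, reps),
                          mean_auc = 0.5, seed = seed), class = "locop_auc"))
  }
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  aucs <- numeric(reps)
  for (rep_i in seq_len(reps)) {
    set.seed(derive_seed(seed, paste0("rep:", rep_i)))
    tr1 <- sample(idx1, round(train_frac * length(idx1)))
    tr0 <- sample(idx0, round(train_frac * length(idx0)))
    tr <- c(tr1, tr0)
    te <- setdiff(seq_along(y), tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
    dtr <- data.frame(Z[tr, , drop = FALSE], .y = y[tr], check.names = FALSE)
    fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
    scores <- suppressWarnings(
      predict(fit, newdata = data.frame(Z[te, , drop = FALSE],
                                        check.names = FALSE)))
    aucs[rep_i] <- roc_auc(y[te], scores)
  }
  structure(list(model = features, auc = aucs, mean_auc = mean(aucs),
                 seed = seed), class = "locop_auc")
}

#' @export
print.locop_auc <- function(x, ...) {
  cat(sprintf("<locop_auc> %s: mean AUC %.3f over %d reps\n",
              paste(x$model, collapse = "+"), x$mean_auc, length(x$auc)))
  invisible(x)
}

#' Evaluate every named model on a feature table
#'
#' @param table feature table with `label`.
#' @param specs named list of feature groupings (default [model_specs()]
#'   restricted to the table's columns).
#' @param reps,train_frac,seed passed to [evaluate_model()].
#' @return data.frame `model`, `mean_auc` plus a `results` attribute with
#'   the full `locop_auc` objects.
#' @export
evaluate_all_models <- function(table, specs = NULL, reps = 50,
                                train_frac = 0.8, seed = 1) {
  if (is.null(specs)) specs <- model_specs(intersect(feature_columns,
                                                     names(table)))
  res <- lapply(specs, function(f)
    evaluate_model(table, f, reps = reps, train_frac = train_frac,
                   seed = seed))
  out <- data.frame(model = names(specs),
                    mean_auc = vapply(res, `[[`, numeric(1), "mean_auc"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}
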