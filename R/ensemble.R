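#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' of an ordinary least-squares regression (with intercept) of covariate j on
#' all other covariates. Computed as the diagonal of the inverse correlation
#' matrix, with a per-variable least-squares fallback when the correlation
#' matrix is (numerically) singular; a perfectly collinear variable reports
#' `Inf`.
#'
#' @param covs data.frame or matrix of covariate values (rows > columns >= 2).
#' @param cap values above this are reported as `Inf`.
#' @return named vector of VIFs.
#' @export
vif <- function(covs, cap = 1e12) {
  X <- as.matrix(covs)
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X), all(is.finite(X)))
  R <- stats::cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v)) || any(v < 1 - 1e-8)) {
    v <- vapply(seq_len(ncol(X)), function(j) {
      y <- X[, j]
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  v[v > cap] <- Inf
  names(v) <- colnames(X)
  v
}

#' Iterative VIF-based covariate filtering
#'
#' Repeatedly drops the covariate with the highest VIF above the threshold and
#' recomputes, until all remaining VIFs are at or below the threshold. Ties
#' are broken deterministically by variable-name order.
#'
#' @param covs data.frame of covariate values with column names.
#' @param threshold VIF threshold (default 10).
#' @return list with `retained` (character vector of surviving names) and
#'   `removed` (data.frame of dropped variables and their VIF at removal).
#' @export
vif_filter <- function(covs, threshold = 10) {
  current <- as.data.frame(covs)
  removed <- data.frame(variable = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    if (ncol(current) < 2) break
    v <- vif(current)
    vmax <- max(v)
    if (vmax <= threshold) break
    ties <- names(v)[v >= vmax - 1e-9 | (is.infinite(vmax) & is.infinite(v))]
    drop <- sort(ties)[1]
    removed <- rbind(removed,
                     data.frame(variable = drop, vif = unname(v[drop]),
                                stringsAsFactors = FALSE))
    current <- current[, setdiff(names(current), drop), drop = FALSE]
  }
  list(retained = names(current), removed = removed)
}

#' Modelling hyperparameters
#'
#' Fixed stand-ins for the ensemble platform defaults the workflow relies on:
#' GLM with linear plus quadratic terms and no stepwise selection; GAM with a
#' modest spline basis per covariate (logit link, REML smoothing); BRT as
#' gradient-boosted trees with logistic loss (2500 trees, learning rate 0.001,
#' interaction depth 7, bag fraction 0.5). All are exposed here so desk-scale
#' runs can trade tree count for speed.
#'
#' @param gam_k spline basis dimension per covariate.
#' @param brt_n_trees,brt_learning_rate,brt_max_depth,brt_bag_fraction boosted
#'   regression tree settings.
#' @return a `sdm_hyper` list.
#' @export
sdm_hyperparameters <- function(gam_k = 4, brt_n_trees = 2500,
                                brt_learning_rate = 0.001, brt_max_depth = 7,
                                brt_bag_fraction = 0.5) {
  structure(list(gam_k = gam_k, brt_n_trees = brt_n_trees,
                 brt_learning_rate = brt_learning_rate,
                 brt_max_depth = brt_max_depth,
                 brt_bag_fraction = brt_bag_fraction),
            class = "sdm_hyper")
}

#' Fit one modelling technique
#'
#' GLM: binomial-logit regression with linear and quadratic terms per
#' covariate. GAM: binomial-logit with a smooth spline per covariate
#' (basis dimension `gam_k`, REML smoothing selection). BRT: gradient-boosted
#' trees with logistic loss. GLM and GAM covariates are z-scored from the
#' calibration data; BRT sees raw values (trees are scale-invariant).
#'
#' @param technique `"GLM"`, `"GAM"` or `"BRT"`.
#' @param covs calibration covariate data.frame.
#' @param labels 0/1 presence labels.
#' @param hyper a [sdm_hyperparameters()] list.
#' @param seed integer seed (BRT subsampling).
#' @return an `sdm_fit` with a `predict` method returning probabilities of
#'   occurrence in \[0, 1\]; `$converged` reports fitting health.
#' @export
fit_technique <- function(technique = c("GLM", "GAM", "BRT"), covs, labels,
                          hyper = sdm_hyperparameters(), seed = 1) {
  technique <- match.arg(technique)
  stopifnot(nrow(covs) == length(labels), all(labels %in% c(0, 1)))
  vars <- names(covs)
  fit <- list(technique = technique, vars = vars, converged = TRUE)

  if (technique %in% c("GLM", "GAM")) {
    ctr <- vapply(covs, mean, 0)
    scl <- vapply(covs, stats::sd, 0)
    scl[scl == 0] <- 1
    Z <- as.data.frame(scale(covs, ctr, scl))
    Z$.y <- labels
    fit$center <- ctr; fit$scale <- scl
    # degenerate covariates (few unique values, e.g. a binary flag) enter as
    # plain linear terms: a quadratic duplicates them and mgcv rejects a
    # smooth with more basis functions than unique values
    nuniq <- vapply(covs, function(x) length(unique(x)), 0L)
    if (technique == "GLM") {
      terms <- paste(ifelse(nuniq >= 3, sprintf("%s + I(%s^2)", vars, vars),
                            vars), collapse = " + ")
      f <- stats::as.formula(paste(".y ~", terms))
      m <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = Z))
      fit$converged <- isTRUE(m$converged)
      fit$model <- m
    } else {
      terms <- paste(ifelse(nuniq > hyper$gam_k + 1,
                            sprintf("s(%s, k = %d)", vars, hyper$gam_k), vars),
                     collapse = " + ")
      f <- stats::as.formula(paste(".y ~", terms))
      m <- tryCatch(
        mgcv::gam(f, family = stats::binomial(), data = Z, method = "REML"),
        error = function(e) e
      )
      if (inherits(m, "error")) {
        fit$converged <- FALSE
      } else {
        fit$converged <- isTRUE(m$converged)
        fit$model <- m
      }
    }
  } else {
    d <- xgboost::xgb.DMatrix(as.matrix(covs), label = labels)
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = hyper$brt_learning_rate,
                    max_depth = hyper$brt_max_depth,
                    subsample = hyper$brt_bag_fraction,
                    nthread = 1, seed = seed),
      data = d, nrounds = hyper$brt_n_trees, verbose = 0
    )
    fit$model <- m
  }
  structure(fit, class = "sdm_fit")
}

#' Predict occurrence probabilities from a fitted technique
#'
#' @param object an `sdm_fit`.
#' @param newdata data.frame containing the model's covariates.
#' @param ... unused.
#' @return probabilities of occurrence, clipped to \[0, 1\].
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  newdata <- newdata[, object$vars, drop = FALSE]
  if (is.null(object$model)) stop("technique did not converge; no model")
  p <- if (object$technique == "BRT") {
    stats::predict(object$model, as.matrix(newdata))
  } else {
    Z <- as.data.frame(scale(newdata, object$center, object$scale))
    as.vector(stats::predict(object$model, Z, type = "response"))
  }
  pmin(pmax(as.vector(p), 0), 1)
}

#' Threshold-based and threshold-free evaluation of predictions
#'
#' AUC via the rank (Mann-Whitney) statistic with ties counted one half. TSS
#' is maximised over a fixed threshold grid (0 to 1 in steps of 0.001); among
#' tied maxima the smallest threshold is chosen, and the sensitivity and
#' specificity at that threshold are reported (a prediction equal to the
#' threshold counts as presence).
#'
#' @param predictions probability-of-occurrence vector.
#' @param labels 0/1 vector; both classes must be present.
#' @param thresholds threshold grid.
#' @return an `sdm_metrics` list: `auc`, `tss`, `best_threshold`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_predictions <- function(predictions, labels,
                                 thresholds = seq(0, 1, by = 0.001)) {
  stopifnot(length(predictions) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to evaluate")
  r <- rank(predictions)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pos <- predictions[labels == 1]; neg <- predictions[labels == 0]
  sens <- vapply(thresholds, function(t) sum(pos >= t), 0) / n1
  spec <- vapply(thresholds, function(t) sum(neg < t), 0) / n0
  tss <- sens + spec - 1
  best <- which.max(tss)  # first maximum = smallest threshold
  structure(list(auc = auc, tss = tss[best], best_threshold = thresholds[best],
                 sensitivity = sens[best], specificity = spec[best]),
            class = "sdm_metrics")
}

#' Ensemble weights from cross-validated TSS
#'
#' Negative TSS values are clipped to zero before normalising (a
#' worse-than-random member should not vote); if all members clip to zero the
#' weights fall back to equal.
#'
#' @param tss_values numeric vector of member cross-validated TSS.
#' @return non-negative weights summing to one.
#' @export
weights_from_tss <- function(tss_values) {
  w <- pmax(tss_values, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w / sum(w)
}

#' Weighted-mean ensemble prediction
#'
#' @param members list of `sdm_fit` models.
#' @param weights non-negative weights summing to one.
#' @param newdata covariate data.frame.
#' @return ensemble probabilities of occurrence.
#' @export
ensemble_predict <- function(members, weights, newdata) {
  stopifnot(length(members) == length(weights),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0))
  preds <- vapply(members, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  if (any(preds < 0 | preds > 1)) stop("member prediction outside [0, 1]")
  as.vector(preds %*% weights)
}

#' Species retention rule
#'
#' A species' ensemble model is retained when its cross-validated TSS is at
#' least `tss_min` and its cross-validated AUC at least `auc_min` (both
#' inclusive).
#'
#' @param metrics an `sdm_metrics` (cross-validated, from the evaluation set).
#' @param tss_min,auc_min retention thresholds (defaults 0.3 and 0.7).
#' @return logical.
#' @export
retain_species <- function(metrics, tss_min = 0.3, auc_min = 0.7) {
  metrics$tss >= tss_min && metrics$auc >= auc_min
}

#' Permutation variable importance for one fitted technique
#'
#' For each variable, its column is shuffled and the importance is
#' `1 - cor(predictions_original, predictions_shuffled)`, averaged over
#' `n_perm` shuffles, floored at 0 and capped at 1. An undefined correlation
#' (constant predictions) is treated as 1, giving importance 0.
#'
#' @param model an `sdm_fit`.
#' @param covs covariate data.frame.
#' @param n_perm number of permutations (default 3).
#' @param seed integer seed.
#' @return named importance vector in \[0, 1\].
#' @export
permutation_importance <- function(model, covs, n_perm = 3, seed = 1) {
  p0 <- predict(model, covs)
  with_seed(seed, {
    out <- vapply(names(covs), function(v) {
      vals <- vapply(seq_len(n_perm), function(i) {
        shuffled <- covs
        shuffled[[v]] <- shuffled[[v]][sample.int(nrow(covs))]
        p1 <- predict(model, shuffled)
        r <- suppressWarnings(stats::cor(p0, p1))
        if (is.na(r)) r <- 1
        1 - r
      }, 0)
      mean(vals)
    }, 0)
    pmin(pmax(out, 0), 1)
  })
}

#' TSS-weighted ensemble variable importance
#'
#' @param member_importance matrix (variables x members) of per-technique
#'   importances.
#' @param weights ensemble weights.
#' @return named weighted-mean importance vector.
#' @export
ensemble_importance <- function(member_importance, weights) {
  stopifnot(ncol(member_importance) == length(weights))
  out <- as.vector(member_importance %*% weights)
  names(out) <- rownames(member_importance)
  out
}

#' Fit the full three-technique ensemble for one species
#'
#' Fits GLM and GAM on the calibration portion of the presence plus large
#' absence sample and BRT on the presence plus small absence sample, evaluates
#' every member and the TSS-weighted ensemble on the held-out evaluation set
#' (presences plus large-sample absences), applies the retention rule, then
#' refits all members on 100% of the data for prediction, response curves and
#' permutation importance.
#'
#' @param ds a `species_dataset` from [prepare_species_data()].
#' @param hyper a [sdm_hyperparameters()] list.
#' @param seed integer seed.
#' @param tss_min,auc_min retention thresholds.
#' @param n_perm permutations for variable importance.
#' @return an `sdm_ensemble` list: final `members`, `weights`,
#'   `member_metrics`, `ensemble_metrics` (cross-validated), `threshold`
#'   (maxTSS), `retained`, `converged`, `importance`,
#'   `member_importance`.
#' @export
fit_ensemble <- function(ds, hyper = sdm_hyperparameters(), seed = 1,
                         tss_min = 0.3, auc_min = 0.7, n_perm = 3) {
  stopifnot(inherits(ds, "species_dataset"))
  techs <- c("GLM", "GAM", "BRT")

  cal_data <- function(tech) {
    if (tech == "BRT") {
      list(covs = rbind(ds$pres_covs[ds$cal_pres, , drop = FALSE],
                        ds$abs_small_covs[ds$cal_abs_small, , drop = FALSE]),
           y = c(rep(1, sum(ds$cal_pres)), rep(0, sum(ds$cal_abs_small))))
    } else {
      list(covs = rbind(ds$pres_covs[ds$cal_pres, , drop = FALSE],
                        ds$abs_large_covs[ds$cal_abs_large, , drop = FALSE]),
           y = c(rep(1, sum(ds$cal_pres)), rep(0, sum(ds$cal_abs_large))))
    }
  }
  full_data <- function(tech) {
    if (tech == "BRT") {
      list(covs = rbind(ds$pres_covs, ds$abs_small_covs),
           y = c(rep(1, nrow(ds$pres_covs)), rep(0, nrow(ds$abs_small_covs))))
    } else {
      list(covs = rbind(ds$pres_covs, ds$abs_large_covs),
           y = c(rep(1, nrow(ds$pres_covs)), rep(0, nrow(ds$abs_large_covs))))
    }
  }

  cv_members <- lapply(seq_along(techs), function(i) {
    d <- cal_data(techs[i])
    fit_technique(techs[i], d$covs, d$y, hyper, child_seed(seed, 20 + i))
  })
  names(cv_members) <- techs
  converged <- all(vapply(cv_members, `[[`, TRUE, "converged"))

  eval_covs <- rbind(ds$pres_covs[!ds$cal_pres, , drop = FALSE],
                     ds$abs_large_covs[!ds$cal_abs_large, , drop = FALSE])
  y_eval <- c(rep(1, sum(!ds$cal_pres)), rep(0, sum(!ds$cal_abs_large)))

  member_metrics <- NULL; weights <- rep(1 / 3, 3)
  ensemble_metrics <- NULL; retained <- FALSE
  if (converged) {
    member_metrics <- lapply(cv_members, function(m) {
      evaluate_predictions(predict(m, eval_covs), y_eval)
    })
    weights <- weights_from_tss(vapply(member_metrics, `[[`, 0, "tss"))
    p_ens <- ensemble_predict(cv_members, weights, eval_covs)
    ensemble_metrics <- evaluate_predictions(p_ens, y_eval)
    retained <- retain_species(ensemble_metrics, tss_min, auc_min)
  }

  # final models: refit on 100% of the data (weights stay cross-validated)
  members <- lapply(seq_along(techs), function(i) {
    d <- full_data(techs[i])
    fit_technique(techs[i], d$covs, d$y, hyper, child_seed(seed, 30 + i))
  })
  names(members) <- techs
  converged <- converged && all(vapply(members, `[[`, TRUE, "converged"))

  importance <- NULL; member_importance <- NULL
  if (converged) {
    imp_covs <- rbind(ds$pres_covs, ds$abs_large_covs)
    member_importance <- vapply(seq_along(members), function(i) {
      permutation_importance(members[[i]], imp_covs, n_perm,
                             child_seed(seed, 40 + i))
    }, numeric(ncol(imp_covs)))
    member_importance <- matrix(member_importance, ncol = length(members),
                                dimnames = list(names(imp_covs), techs))
    importance <- ensemble_importance(member_importance, weights)
  }

  structure(list(species_id = ds$species_id, members = members,
                 cv_members = cv_members, weights = weights,
                 member_metrics = member_metrics,
                 ensemble_metrics = ensemble_metrics,
                 threshold = if (!is.null(ensemble_metrics))
                   ensemble_metrics$best_threshold else NA_real_,
                 retained = retained, converged = converged,
                 importance = importance,
                 member_importance = member_importance),
            class = "sdm_ensemble")
}
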