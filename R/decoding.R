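# Linear maximum-margin decoding of trial labels with leave-one-session-out
# outer cross-validation, nested leave-one-trial-out selection of the
# regularization hyperparameter C, and condition-split analysis (one
# independent decoding per threat stratum, subject value = mean of the two
# stratum accuracies). Everything that does not depend on the labels
# (scaling, Gram matrices, the fold structure) is precomputed once per
# subject so that permutation inference can re-run the label-dependent part
# of the identical pipeline thousands of times.

#' Decoding configuration
#'
#' @param C_grid candidate values of the SVM regularization hyperparameter C
#'   (positive; sorted ascending internally; ties in the nested selection
#'   resolve to the smallest C).
#' @param scaling `"fold"` (default): voxel standardization is fit on the
#'   training rows of each cross-validation fold, keeping the analysis
#'   non-circular. `"global"`: fit once on all trials before
#'   cross-validation, replicating pre-CV standardization.
#' @param eps SMO convergence tolerance.
#' @param max_iter SMO iteration cap.
#' @param seed seed recorded for run manifests (the decoder itself is
#'   deterministic; only permutation schemes draw random numbers).
#' @return An object of class `decoding_config`.
#' @export
decoding_config <- function(C_grid = 10^(-3:3), scaling = c("fold", "global"),
                            eps = 1e-6, max_iter = 200000L, seed = NULL) {
  if (!length(C_grid) || any(C_grid <= 0))
    stop("C_grid must be nonempty and strictly positive")
  structure(list(C_grid = sort(unique(as.numeric(C_grid))),
                 scaling = match.arg(scaling), eps = eps,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "decoding_config")
}

#' Leave-one-session-out folds
#'
#' @param sessions per-trial session index (>= 2 distinct sessions).
#' @return List of S folds, each `list(train_sessions, test_session)`; every
#'   session is tested exactly once.
#' @export
loso_folds <- function(sessions) {
  us <- sort(unique(sessions))
  if (length(us) < 2) stop("leave-one-session-out needs >= 2 sessions")
  lapply(us, function(s) list(train_sessions = setdiff(us, s),
                              test_session = s))
}

#' Train a linear soft-margin classifier
#'
#' C-SVC with hinge loss and l2 penalty (dual SMO on the precomputed Gram
#' matrix); deterministic given its inputs. The per-feature weights `w` are
#' exposed for weight-map inference.
#'
#' @param x trials-by-features matrix.
#' @param y labels (`pain`/`no_pain` or -1/+1); both classes required.
#' @param C regularization hyperparameter (> 0).
#' @param eps,max_iter solver controls.
#' @return Object of class `linear_margin`: `w`, `b`, `alpha`, `C`.
#' @export
train_linear_margin <- function(x, y, C = 1, eps = 1e-6, max_iter = 200000L) {
  yy <- to_pm1(y)
  if (length(unique(yy)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be > 0")
  fit <- .cpp_smo(tcrossprod(x), yy, C, eps, as.integer(max_iter))
  w <- drop(crossprod(x, fit$alpha * yy))
  structure(list(w = w, b = -fit$rho, alpha = fit$alpha, y = yy, C = C,
                 converged = fit$converged),
            class = "linear_margin")
}

#' @export
predict.linear_margin <- function(object, newdata,
                                  type = c("class", "decision"), ...) {
  type <- match.arg(type)
  f <- drop(newdata %*% object$w + object$b)
  if (type == "decision") f else pm1_to_label(ifelse(f > 0, 1L, -1L))
}

#' Nested selection of the regularization hyperparameter
#'
#' Leave-one-trial-out cross-validation on the training set for every
#' candidate C; returns the accuracy maximizer, with ties resolved to the
#' smallest C. Inner folds whose remaining trials contain a single class are
#' skipped.
#'
#' @param x training trials-by-features matrix.
#' @param y training labels (>= 2 per class recommended).
#' @param C_grid candidate values (nonempty, positive).
#' @param eps,max_iter solver controls.
#' @return List with `C` (chosen value) and `inner_accuracy` (named vector
#'   of inner accuracies per candidate).
#' @export
nested_select_C <- function(x, y, C_grid = 10^(-3:3), eps = 1e-6,
                            max_iter = 200000L) {
  if (!length(C_grid) || any(C_grid <= 0))
    stop("C_grid must be nonempty and strictly positive")
  yy <- to_pm1(y)
  if (length(unique(yy)) < 2) stop("both classes must be present")
  grid <- sort(unique(as.numeric(C_grid)))
  acc <- .cpp_inner_loto(tcrossprod(x), yy, grid, eps, as.integer(max_iter))
  names(acc) <- format(grid, trim = TRUE)
  best <- if (all(is.na(acc))) 1L else which.max(acc)  # which.max: first max
  list(C = grid[best], inner_accuracy = acc)
}

# l2 scaling that tolerates all-zero rows (leaves them at zero); used inside
# permutation loops where an occasional information-free trial pattern must
# not abort the run
l2_safe <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' Build a reusable per-subject decoder
#'
#' Precomputes everything label-independent about the decoding analysis of
#' one subject (feature extraction, scaling, fold structure, Gram matrices)
#' and returns a function of the label vector that runs the label-dependent
#' remainder (voxel ranking where applicable, nested C selection, training,
#' testing). Calling it with the observed labels reproduces
#' [decode_subject()]; permutation inference calls it with shuffled labels.
#'
#' @inheritParams decode_subject
#' @param details also return per-fold weight vectors and scaling
#'   parameters (slower; keeps feature matrices in memory).
#' @return A function `f(labels)` returning a list with `mean_accuracy`,
#'   per-stratum accuracies and fold information.
#' @export
make_subject_decoder <- function(beta, phase = c("stimulation", "anticipation"),
                                 features = feature_spec("whole_brain"),
                                 config = decoding_config(),
                                 details = FALSE) {
  stopifnot(inherits(beta, "beta_series"), inherits(config, "decoding_config"))
  phase <- match.arg(phase)
  X <- beta$patterns[[phase]]
  meta <- beta$meta
  cols <- feature_columns(features, beta$atlas, ncol(X))
  Xc <- X[, cols, drop = FALSE]
  ranking_mode <- features$type == "top_voxels"
  k_top <- features$k
  sessions <- meta$session
  strata <- sort(unique(meta$threat))

  if (config$scaling == "global") {
    st_g <- standardize_voxels(Xc)
    Xg <- st_g$values
  }

  prep <- lapply(strata, function(lev) {
    rows <- which(meta$threat == lev)
    sess <- sessions[rows]
    folds <- loso_folds(sess)
    fold_prep <- lapply(folds, function(f) {
      train <- which(sess != f$test_session)
      test <- which(sess == f$test_session)
      if (config$scaling == "global") {
        Z <- Xg[rows, , drop = FALSE]
        sc <- if (details) list(center = st_g$center, scale = st_g$scale)
      } else {
        st <- standardize_voxels(Xc[rows, , drop = FALSE], fit_rows = train)
        Z <- st$values
        sc <- if (details) list(center = st$center, scale = st$scale)
      }
      if (ranking_mode) {
        list(train = train, test = test, Z = Z, K = NULL, scaling = sc,
             test_session = f$test_session)
      } else {
        Zl <- l2_safe(Z)
        list(train = train, test = test,
             Z = if (details) Zl, K = tcrossprod(Zl), scaling = sc,
             test_session = f$test_session)
      }
    })
    list(rows = rows, folds = fold_prep)
  })

  grid <- config$C_grid
  eps <- config$eps
  max_iter <- config$max_iter

  function(labels) {
    y_all <- to_pm1(labels)
    strat_res <- lapply(seq_along(strata), function(si) {
      p <- prep[[si]]
      y <- y_all[p$rows]
      nf <- length(p$folds)
      if (ranking_mode) {
        Ks <- vector("list", nf)
        sel_list <- vector("list", nf)
        for (fi in seq_len(nf)) {
          f <- p$folds[[fi]]
          ytr <- y[f$train]
          if (length(unique(ytr)) < 2) {   # fold will be skipped by the solver
            Ks[[fi]] <- matrix(0, length(y), length(y))
            next
          }
          rk <- rank_voxels_tcontrast(f$Z[f$train, , drop = FALSE], ytr)
          sel <- rk$voxel[seq_len(min(k_top, nrow(rk)))]
          sel_list[[fi]] <- sel
          Ks[[fi]] <- tcrossprod(l2_safe(f$Z[, sel, drop = FALSE]))
        }
      } else {
        Ks <- lapply(p$folds, `[[`, "K")
        sel_list <- NULL
      }
      res <- .cpp_decode_stratum(Ks,
                                 lapply(p$folds, `[[`, "train"),
                                 lapply(p$folds, `[[`, "test"),
                                 y, grid, eps, max_iter, details)
      predicted <- !is.na(res$pred)
      acc <- if (any(predicted)) mean(res$pred[predicted] == y[predicted]) else NA_real_
      fold_acc <- vapply(seq_len(nf), function(fi) {
        te <- p$folds[[fi]]$test
        te <- te[!is.na(res$pred[te])]
        if (length(te)) mean(res$pred[te] == y[te]) else NA_real_
      }, numeric(1))
      out <- list(stratum = strata[si], accuracy = acc,
                  accuracy_fold_mean = mean(fold_acc, na.rm = TRUE),
                  n_trials = length(y), n_predicted = sum(predicted),
                  chosen_C = res$chosen_C, skipped = res$skipped,
                  fold_accuracy = fold_acc,
                  test_session = vapply(p$folds, `[[`, numeric(1), "test_session"),
                  pred = res$pred, decision = res$decision, y = y,
                  rows = p$rows)
      if (details) {
        out$fold_details <- lapply(seq_len(nf), function(fi) {
          f <- p$folds[[fi]]
          if (res$skipped[fi]) return(NULL)
          fit <- res$fold_fits[[fi]]
          Ztr <- if (ranking_mode)
            l2_safe(f$Z[, sel_list[[fi]], drop = FALSE])[f$train, , drop = FALSE]
          else f$Z[f$train, , drop = FALSE]
          list(chosen_C = res$chosen_C[fi],
               w = drop(crossprod(Ztr, fit$alpha * y[f$train])),
               b = -fit$rho, alpha = fit$alpha, scaling = f$scaling,
               selected_voxels = if (ranking_mode) sel_list[[fi]])
        })
      }
      out
    })
    acc <- vapply(strat_res, `[[`, numeric(1), "accuracy")
    list(mean_accuracy = mean(acc),   # NA if any stratum undecodable
         stratum_accuracy = stats::setNames(acc, strata),
         strata = strat_res)
  }
}

#' Decode pain perception for one subject
#'
#' Runs, independently within each threat stratum, leave-one-session-out
#' cross-validation with fold-wise feature scaling (and fold-wise voxel
#' ranking for `top_voxels` feature specs) and nested leave-one-trial-out
#' selection of C on the training data only. The stratum accuracy is the
#' pooled proportion of correctly predicted test trials across folds (the
#' mean of per-fold accuracies is reported alongside); the subject value is
#' the mean of the two stratum accuracies. Training folds containing a
#' single class are skipped with a warning and the accuracy pooled over the
#' remaining folds.
#'
#' @param beta a `beta_series`.
#' @param phase `"stimulation"` or `"anticipation"`.
#' @param features a [feature_spec()].
#' @param config a [decoding_config()].
#' @param details keep per-fold weights and scaling parameters.
#' @param undecodable what to do when every fold of a stratum is skipped:
#'   `"error"` (default) or `"na"` (stratum and subject accuracy become NA).
#' @param quiet suppress skipped-fold warnings.
#' @return Object of class `subject_decoding`: `mean_accuracy`,
#'   `stratum_accuracy`, per-fold table `folds`, per-trial `predictions`,
#'   and (with `details`) per-fold fits.
#' @export
decode_subject <- function(beta, phase = c("stimulation", "anticipation"),
                           features = feature_spec("whole_brain"),
                           config = decoding_config(), details = FALSE,
                           undecodable = c("error", "na"), quiet = FALSE) {
  phase <- match.arg(phase)
  undecodable <- match.arg(undecodable)
  decoder <- make_subject_decoder(beta, phase, features, config, details)
  res <- decoder(beta$meta$label)

  folds <- do.call(rbind, lapply(res$strata, function(s)
    data.frame(threat = s$stratum, test_session = s$test_session,
               chosen_C = s$chosen_C, skipped = s$skipped,
               fold_accuracy = s$fold_accuracy)))
  n_skipped <- sum(folds$skipped)
  if (n_skipped > 0 && !quiet)
    warning(sprintf("%d training fold(s) contained a single class and were skipped",
                    n_skipped))
  for (s in res$strata) {
    if (is.na(s$accuracy)) {
      msg <- sprintf("stratum '%s' is undecodable (all folds skipped)", s$stratum)
      if (undecodable == "error") stop(msg) else if (!quiet) warning(msg)
    }
  }
  predictions <- do.call(rbind, lapply(res$strata, function(s)
    data.frame(row = s$rows, threat = s$stratum,
               true = pm1_to_label(s$y), pred = pm1_to_label(s$pred),
               decision = s$decision)))
  predictions <- predictions[order(predictions$row), ]
  rownames(predictions) <- NULL

  structure(list(mean_accuracy = res$mean_accuracy,
                 stratum_accuracy = res$stratum_accuracy,
                 folds = folds, predictions = predictions,
                 phase = phase, features = format(features), config = config,
                 details = if (details) lapply(res$strata, `[[`, "fold_details"),
                 subject_id = beta$subject_id),
            class = "subject_decoding")
}

#' @export
print.subject_decoding <- function(x, ...) {
  cat("<subject_decoding>", x$subject_id %||% "", x$phase, x$features, "\n")
  cat("  mean accuracy:", format(x$mean_accuracy, digits = 4), "\n")
  cat("  per stratum:",
      paste(sprintf("%s=%.3f", names(x$stratum_accuracy), x$stratum_accuracy),
            collapse = "  "), "\n")
  invisible(x)
}

#' Aggregate subject accuracies into a group result
#'
#' @param accuracies numeric vector of per-subject mean accuracies, or a
#'   list of `subject_decoding` objects.
#' @param p optional permutation p-value to attach (see
#'   [group_accuracy_null()] / [perm_pvalue()]).
#' @return Object of class `group_decoding`: `subject_accuracies`,
#'   `mean_accuracy` (arithmetic mean), `sem`, `n`, `p`.
#' @export
group_accuracy <- function(accuracies, p = NA_real_) {
  if (is.list(accuracies))
    accuracies <- vapply(accuracies, function(a)
      if (inherits(a, "subject_decoding")) a$mean_accuracy else as.numeric(a),
      numeric(1))
  if (length(accuracies) < 2) stop("need >= 2 subjects")
  ok <- !is.na(accuracies)
  structure(list(subject_accuracies = accuracies,
                 mean_accuracy = mean(accuracies[ok]),
                 sem = stats::sd(accuracies[ok]) / sqrt(sum(ok)),
                 n = sum(ok), p = p),
            class = "group_decoding")
}

#' @export
print.group_decoding <- function(x, ...) {
  cat(sprintf("<group_decoding> n=%d  mean accuracy %.3f +/- %.3f (SEM)",
              x$n, x$mean_accuracy, x$sem))
  if (!is.na(x$p)) cat(sprintf("  p=%.4g", x$p))
  cat("\n")
  invisible(x)
}

#' Decode a group of subjects
#'
#' Runs [decode_subject()] for every subject and aggregates; optionally
#' attaches a group-level permutation p-value obtained by independently
#' permuting every subject's labels within sessions and recomputing the
#' group mean `N_perm` times.
#'
#' @param betas list of `beta_series` (one per subject).
#' @param phase,features,config as in [decode_subject()].
#' @param N_perm number of group permutations (0 = no p-value).
#' @param seed seed for the permutation scheme.
#' @param undecodable passed through; for group runs the default is `"na"`
#'   so that a rare degenerate stratum drops that subject from the mean
#'   rather than aborting the analysis.
#' @return A `group_decoding`; per-subject results in
#'   `attr(, "subject_results")`, the permutation null in `attr(, "null")`.
#' @export
decode_group <- function(betas, phase = c("stimulation", "anticipation"),
                         features = feature_spec("whole_brain"),
                         config = decoding_config(), N_perm = 0, seed = NULL,
                         undecodable = "na") {
  phase <- match.arg(phase)
  decoders <- lapply(betas, make_subject_decoder, phase = phase,
                     features = features, config = config)
  obs <- vapply(seq_along(betas), function(i)
    decoders[[i]](betas[[i]]$meta$label)$mean_accuracy, numeric(1))
  if (undecodable == "error" && anyNA(obs))
    stop("undecodable stratum in subject(s): ",
         paste(which(is.na(obs)), collapse = ", "))
  res <- group_accuracy(obs)
  if (N_perm > 0) {
    labels <- lapply(betas, function(b) b$meta$label)
    sessions <- lapply(betas, function(b) b$meta$session)
    null <- group_accuracy_null(decoders, labels, sessions, N_perm, seed)
    res$p <- perm_pvalue(res$mean_accuracy, null)
    attr(res, "null") <- null
  }
  attr(res, "phase") <- phase
  attr(res, "features") <- format(features)
  res
}
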