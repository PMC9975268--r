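# Load-state classification ----------------------------------------------
#
# One (delta PEP, delta HR) point per subject and load state, expressed as
# the deviation of the state mean from the subject's single rest-calibration
# measurement.  Classified with k-nearest neighbours under subject-wise
# cross-validation: all of a subject's points sit in the same fold, so no
# subject leaks between training and test.

#' Build per-subject load-state features
#'
#' For every subject with a baseline rest calibration and at least one valid
#' measurement in each load state, computes the state-mean PEP and heart
#' rate as deltas to the calibration measurement.  The rest-state mean uses
#' the recovered late-break rest measurements, not the calibration itself,
#' so rest features scatter around the origin with genuine within-subject
#' noise.
#'
#' @param measurements measurement table.
#' @return Data frame with columns `subject_id`, `state` (factor
#'   rest/mental/physical), `d_pep`, `d_hr`; subjects missing a state are
#'   excluded with a message.
#' @export
build_features <- function(measurements) {
  m <- .valid_meas(measurements)
  ref <- .rest_reference(m)

  rows <- lapply(split(m, m$subject_id), function(d) {
    id <- d$subject_id[1]
    r <- ref[ref$subject_id == id, ]
    if (nrow(r) == 0L) return(NULL)
    noncal <- d[!(d$phase == "rest"), ]
    out <- lapply(c("rest", "mental", "physical"), function(st) {
      dd <- noncal[noncal$state == st, ]
      if (nrow(dd) == 0L) return(NULL)
      data.frame(subject_id = id, state = st,
                 d_pep = mean(dd$pep) - r$pep_rest,
                 d_hr = mean(dd$hr) - r$hr_rest,
                 stringsAsFactors = FALSE)
    })
    if (any(vapply(out, is.null, logical(1)))) return(NULL)
    do.call(rbind, out)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " subject(s) lacked a calibration or a complete set of states")
  feats <- do.call(rbind, rows)
  if (is.null(feats) || nrow(feats) == 0L)
    stop("no subject has a complete feature set", call. = FALSE)
  rownames(feats) <- NULL
  feats$state <- factor(feats$state, levels = c("rest", "mental", "physical"))
  feats
}

# deterministic k-NN: neighbours are the k smallest distances (ties at the
# boundary are all included), majority vote, ties broken by the smaller
# summed neighbour distance, then by fixed class order.  Invariant to the
# ordering of the training points.
.knn_predict <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (k >= nrow(train_x))
    stop("k must be smaller than the training-set size", call. = FALSE)
  classes <- levels(train_y)
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    kth <- sort(d2, partial = k)[k]
    nb <- which(d2 <= kth + 1e-12)
    votes <- tapply(rep(1L, length(nb)), train_y[nb], sum, default = 0L)
    sums <- tapply(sqrt(d2[nb]), train_y[nb], sum, default = Inf)
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1L) {
      best <- best[order(sums[best], match(best, classes))][1]
    }
    out[i] <- best
  }
  factor(out, levels = classes)
}

.fold_assign <- function(subjects, folds) {
  n <- length(subjects)
  shuffled <- sample(subjects)
  split(shuffled, rep_len(seq_len(folds), n))
}

#' Evaluate the k-NN load-state classifier
#'
#' Subject-wise k-fold cross-validation (default fivefold, i.e. an 80/20
#' split), repeated with reshuffled fold assignments to stabilise the
#' estimate.  Features are z-scored with statistics fitted on the training
#' folds only.  Positive predictive value and sensitivity are computed per
#' class from each repeat's pooled confusion matrix, macro-averaged over the
#' three states and then averaged over repeats.
#'
#' @param features output of [build_features()].
#' @param k neighbours (default 13).
#' @param folds number of folds (default 5).
#' @param repeats repeated cross-validation runs (default 20).
#' @param seed seed for the fold assignments.
#' @param standardize z-score features on training statistics (default TRUE).
#' @return Object of class `knn_report`: confusion matrix (summed over all
#'   repeats), per-class and macro PPV and sensitivity, and the settings.
#' @export
evaluate_knn <- function(features, k = 13, folds = 5, repeats = 20,
                         seed = 1, standardize = TRUE) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "state", "d_pep", "d_hr") %in% names(features)))
  if (!is.factor(features$state))
    features$state <- factor(features$state,
                             levels = c("rest", "mental", "physical"))
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)

  classes <- levels(features$state)
  subjects <- unique(features$subject_id)
  conf_total <- matrix(0L, 3, 3, dimnames = list(truth = classes,
                                                 predicted = classes))
  ppv_rep <- sens_rep <- matrix(NA_real_, repeats, 3,
                                dimnames = list(NULL, classes))
  fold_log <- vector("list", repeats)

  for (r in seq_len(repeats)) {
    assign <- .fold_assign(subjects, folds)
    fold_log[[r]] <- assign
    conf <- matrix(0L, 3, 3, dimnames = dimnames(conf_total))
    for (f in seq_len(folds)) {
      test_ids <- assign[[f]]
      tr <- features[!features$subject_id %in% test_ids, ]
      te <- features[features$subject_id %in% test_ids, ]
      if (nrow(te) == 0L) next
      x_tr <- as.matrix(tr[, c("d_pep", "d_hr")])
      x_te <- as.matrix(te[, c("d_pep", "d_hr")])
      if (standardize) {
        mu <- colMeans(x_tr); sg <- apply(x_tr, 2, stats::sd)
        sg[sg == 0] <- 1
        x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
        x_te <- sweep(sweep(x_te, 2, mu), 2, sg, "/")
      }
      pred <- .knn_predict(x_tr, tr$state, x_te, k)
      tt <- table(factor(te$state, classes), factor(pred, classes))
      conf <- conf + matrix(as.integer(tt), 3, 3)
    }
    conf_total <- conf_total + conf
    ppv_rep[r, ] <- diag(conf) / pmax(colSums(conf), 1)
    sens_rep[r, ] <- diag(conf) / pmax(rowSums(conf), 1)
  }

  structure(list(
    confusion = conf_total,
    ppv = colMeans(ppv_rep), sensitivity = colMeans(sens_rep),
    ppv_macro = mean(ppv_rep), sensitivity_macro = mean(sens_rep),
    k = k, folds = folds, repeats = repeats, n_subjects = length(subjects),
    fold_assignments = fold_log
  ), class = "knn_report")
}

#' @export
print.knn_report <- function(x, ...) {
  cat("<knn_report> k =", x$k, "|", x$folds, "folds x", x$repeats,
      "repeats |", x$n_subjects, "subjects\n")
  cat(sprintf("  macro PPV: %.3f | macro sensitivity: %.3f\n",
              x$ppv_macro, x$sensitivity_macro))
  print(x$confusion)
  invisible(x)
}

#' Predicted load state over a (delta HR, delta PEP) grid
#'
#' Trains the k-NN on all features and predicts the class over a regular
#' grid, for visualising decision regions.
#'
#' @param features output of [build_features()].
#' @param k neighbours (default 13).
#' @param d_hr_range,d_pep_range grid extents; defaults cover the features
#'   with a 10% margin.
#' @param n grid points per axis (default 61).
#' @param standardize z-score with full-data statistics (default TRUE).
#' @return Data frame `d_hr`, `d_pep`, `state`.
#' @export
decision_map <- function(features, k = 13, d_hr_range = NULL,
                         d_pep_range = NULL, n = 61, standardize = TRUE) {
  stopifnot(is.data.frame(features))
  if (!is.numeric(n) || n < 2) stop("grid must have at least 2 points per axis",
                                    call. = FALSE)
  if (!is.factor(features$state))
    features$state <- factor(features$state,
                             levels = c("rest", "mental", "physical"))
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  if (is.null(d_hr_range)) d_hr_range <- pad(range(features$d_hr))
  if (is.null(d_pep_range)) d_pep_range <- pad(range(features$d_pep))
  grid <- expand.grid(d_hr = seq(d_hr_range[1], d_hr_range[2], length.out = n),
                      d_pep = seq(d_pep_range[1], d_pep_range[2], length.out = n))
  x_tr <- as.matrix(features[, c("d_pep", "d_hr")])
  x_te <- as.matrix(grid[, c("d_pep", "d_hr")])
  if (standardize) {
    mu <- colMeans(x_tr); sg <- apply(x_tr, 2, stats::sd); sg[sg == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sg, "/")
  }
  grid$state <- .knn_predict(x_tr, features$state, x_te, k)
  grid
}
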