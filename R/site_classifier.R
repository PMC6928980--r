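# Traffic-flow-based prediction of cluster membership: the scalar
# predictor x (sum of squared log10 hourly flows over the three most
# discriminating hours), a binomial logistic fit by IRLS, confusion
# metrics on a held-out split, and analytic / empirical x thresholds.

#' Traffic-flow parameter x
#'
#' `x = sum over the three chosen hours of [log10(F_h)]^2`, with F_h the
#' hourly traffic flow (veh/h). Defaults to hours 15, 13 and 11 (the
#' intervals 15-16 h, 13-14 h, 11-12 h). Flows below `flow_floor` are
#' floored with a warning (log10 of the floor 1 veh/h contributes 0);
#' negative flows are an error.
#'
#' @param flows data frame with columns `site_id`, `hour` (0-23),
#'   `veh_per_h`.
#' @param hours three hour-of-day labels.
#' @param flow_floor minimum flow before the log (default 1 veh/h).
#' @return data frame `site_id`, `x`, with the hours used as attribute
#'   `hours`.
#' @export
traffic_x <- function(flows, hours = c(15, 13, 11), flow_floor = 1) {
  stopifnot(all(c("site_id", "hour", "veh_per_h") %in% names(flows)),
            length(hours) == 3, all(hours %in% 0:23))
  f <- flows[flows$hour %in% hours, ]
  if (any(f$veh_per_h < 0)) stop("negative traffic flow")
  if (any(f$veh_per_h < flow_floor))
    warning(sum(f$veh_per_h < flow_floor),
            " flow value(s) below the floor of ", flow_floor,
            " veh/h were floored")
  f$veh_per_h <- pmax(f$veh_per_h, flow_floor)
  x <- tapply(log10(f$veh_per_h)^2, f$site_id, sum)
  ids <- names(x)
  if (any(tapply(f$hour, f$site_id, length) != 3))
    stop("every site needs flows for all three hours")
  structure(data.frame(site_id = ids, x = as.numeric(x)), hours = hours)
}

#' Seeded random train/test split keeping both classes in training
#'
#' @param sites data frame with a `cluster` column (two classes).
#' @param ratio training fraction (0 < ratio < 1, default 0.7).
#' @param seed integer seed; same seed, same split.
#' @return list with `train` and `test` data frames; the training size is
#'   `round(ratio * n)`. If a class is missing from the training part the
#'   split is redrawn (logged via `message`).
#' @export
split_train_test <- function(sites, ratio = 0.7, seed = 1) {
  stopifnot(ratio > 0, ratio < 1, "cluster" %in% names(sites))
  n <- nrow(sites)
  n_train <- round(ratio * n)
  with_seed(seed, {
    repeat {
      idx <- sample.int(n, n_train)
      if (length(unique(sites$cluster[idx])) ==
          length(unique(sites$cluster))) break
      message("redrawing split: a class was absent from the training set")
    }
    list(train = sites[idx, , drop = FALSE],
         test = sites[-idx, , drop = FALSE])
  })
}

#' Binomial logistic fit of cluster membership on x
#'
#' Maximum-likelihood fit of P(cluster 2 | x) by iteratively reweighted
#' least squares (convergence when the log-likelihood changes by less
#' than 1e-8, at most 100 iterations, ridge fallback of 1e-8 on the
#' normal-equation diagonal near separation). Coefficients are stored in
#' the exponent convention `P = 1 / (1 + exp(intercept_term +
#' slope_term * x))`, so the analytic decision threshold (P = 0.5) is
#' `x* = -intercept_term / slope_term`. Complete separation is detected
#' and flagged; the threshold is then the separating midpoint.
#'
#' @param x numeric predictor per site.
#' @param y class per site: cluster ids in \{1, 2\} (2 is the modelled
#'   "positive" outcome) or already-binary 0/1.
#' @return An object of class `logistic_fit`: `intercept_term`,
#'   `slope_term`, `analytic_threshold`, `converged`, `iterations`,
#'   `separation`, `loglik`, `n`.
#' @export
fit_logistic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (all(y %in% c(1, 2))) y <- as.integer(y == 2)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("need both classes to fit")
  if (sd(x) == 0) stop("x is constant; the model is unidentifiable")

  X <- cbind(1, x)
  beta <- c(0, 0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(100)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    xtw <- t(X * w)
    A <- xtw %*% X
    beta_new <- tryCatch(drop(solve(A, xtw %*% z)), error = function(e) NULL)
    if (is.null(beta_new))
      beta_new <- drop(solve(A + diag(1e-8, 2), xtw %*% z))
    beta <- beta_new
    ll <- sum(y * log(pmax(plogis(drop(X %*% beta)), 1e-300)) +
                (1 - y) * log(pmax(1 - plogis(drop(X %*% beta)), 1e-300)))
    if (is.finite(ll) && abs(ll - ll_old) < 1e-8) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  p_fit <- plogis(drop(X %*% beta))
  separation <- all(p_fit[y == 1] > 1 - 1e-6) && all(p_fit[y == 0] < 1e-6)
  # exponent convention: P = 1/(1 + exp(ic + sc * x)) with eta = -(ic + sc x)
  intercept_term <- -beta[1]
  slope_term <- -beta[2]
  threshold <- if (separation) {
    lo <- max(x[p_fit < 0.5]); hi <- min(x[p_fit > 0.5])
    (lo + hi) / 2
  } else if (slope_term != 0) -intercept_term / slope_term else NA_real_
  structure(
    list(intercept_term = unname(intercept_term),
         slope_term = unname(slope_term),
         analytic_threshold = unname(threshold),
         converged = converged, iterations = iter,
         separation = separation, loglik = ll_old, n = length(y)),
    class = "logistic_fit"
  )
}

#' Construct a logistic fit from known exponent-convention coefficients
#'
#' Useful to evaluate a published model `P = 1/(1 + exp(a + b x))`.
#'
#' @param intercept_term a, @param slope_term b in the exponent.
#' @return a `logistic_fit`.
#' @export
logistic_fit_from_terms <- function(intercept_term, slope_term) {
  stopifnot(is.finite(intercept_term), is.finite(slope_term), slope_term != 0)
  structure(
    list(intercept_term = intercept_term, slope_term = slope_term,
         analytic_threshold = -intercept_term / slope_term,
         converged = NA, iterations = 0L, separation = FALSE,
         loglik = NA_real_, n = 0L),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> P(cluster 2) = 1/(1 + exp(%.4g + %.4g x)); x* = %.4g%s\n",
              x$intercept_term, x$slope_term, x$analytic_threshold,
              if (isTRUE(x$separation)) " [complete separation]" else ""))
  invisible(x)
}

#' Predict cluster membership from x
#'
#' @param fit a `logistic_fit`.
#' @param x numeric vector of predictor values.
#' @return data frame `x`, `probability` (of cluster 2), `cluster`
#'   (2 iff probability > 0.5, else 1).
#' @export
predict_membership <- function(fit, x) {
  stopifnot(inherits(fit, "logistic_fit"), all(is.finite(x)))
  p <- 1 / (1 + exp(fit$intercept_term + fit$slope_term * x))
  data.frame(x = x, probability = p, cluster = ifelse(p > 0.5, 2L, 1L))
}

#' Confusion matrix and derived rates
#'
#' Counts the 2x2 predicted x actual table and reports accuracy,
#' precision, recall (= sensitivity), specificity, detection rate,
#' balanced accuracy and Cohen's kappa for the given positive class.
#' Because the choice of positive class changes precision/recall and
#' sensitivity/specificity, [confusion_both()] reports both conventions.
#'
#' @param predicted,actual equal-length binary label vectors (same two
#'   values, e.g. cluster ids 1/2).
#' @param positive_class which label counts as positive.
#' @return An object of class `confusion_summary`: list with `table`,
#'   `positive_class`, `accuracy`, `precision`, `recall`, `sensitivity`,
#'   `specificity`, `detection_rate`, `balanced_accuracy`, `kappa`.
#'   Degenerate marginals give NA rates; kappa is 0 when expected
#'   agreement is 1.
#' @export
confusion_metrics <- function(predicted, actual, positive_class) {
  stopifnot(length(predicted) == length(actual), length(actual) > 0)
  lv <- sort(unique(c(predicted, actual)))
  stopifnot(length(lv) <= 2, positive_class %in% lv)
  neg <- setdiff(lv, positive_class)
  if (length(neg) == 0) neg <- NA
  n <- length(actual)
  tp <- sum(predicted == positive_class & actual == positive_class)
  fp <- sum(predicted == positive_class & actual != positive_class)
  fn <- sum(predicted != positive_class & actual == positive_class)
  tn <- n - tp - fp - fn
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) 0 else (p_o - p_e) / (1 - p_e)
  tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(predicted = c(positive_class, neg),
                                actual = c(positive_class, neg)))
  structure(
    list(table = tab, positive_class = positive_class,
         accuracy = p_o, precision = rate(tp, tp + fp),
         recall = sens, sensitivity = sens, specificity = spec,
         detection_rate = tp / n,
         balanced_accuracy = balanced_accuracy(sens, spec),
         kappa = kappa),
    class = "confusion_summary"
  )
}

#' Balanced accuracy from sensitivity and specificity
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return their mean.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Confusion metrics under both positive-class conventions
#'
#' @inheritParams confusion_metrics
#' @return named list of two `confusion_summary` objects, one per class.
#' @export
confusion_both <- function(predicted, actual) {
  lv <- sort(unique(c(predicted, actual)))
  out <- lapply(lv, function(cl) confusion_metrics(predicted, actual, cl))
  names(out) <- paste0("positive_", lv)
  out
}

#' Empirical x threshold between two clusters
#'
#' Scans all midpoints between consecutive sorted distinct x values (in
#' the direction that puts the higher-x cluster on the high side) and
#' returns the cut minimizing the training misclassification count; ties
#' resolve to the midpoint of the tied cut range. With indistinguishable
#' x distributions (no cut beats any other) the threshold is undefined
#' (NA).
#'
#' @param x numeric predictor per site.
#' @param labels cluster ids (two groups, both present).
#' @return list with `threshold`, `misclassified`, `error_rate`,
#'   `high_side` (the cluster predicted above the threshold).
#' @export
empirical_threshold <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  lv <- sort(unique(labels))
  stopifnot(length(lv) == 2)
  med1 <- median(x[labels == lv[1]])
  med2 <- median(x[labels == lv[2]])
  high <- if (med2 >= med1) lv[2] else lv[1]
  low <- setdiff(lv, high)
  xs <- sort(unique(x))
  if (length(xs) < 2)
    return(list(threshold = NA_real_, misclassified = NA_integer_,
                error_rate = NA_real_, high_side = high))
  cuts <- (head(xs, -1) + tail(xs, -1)) / 2
  err <- vapply(cuts, function(cut) {
    pred <- ifelse(x > cut, high, low)
    sum(pred != labels)
  }, numeric(1))
  # no cut beats the trivial majority assignment: the x distributions do
  # not discriminate and the threshold is undefined
  if (min(err) >= min(table(labels))) {
    return(list(threshold = NA_real_, misclassified = NA_integer_,
                error_rate = NA_real_, high_side = high))
  }
  best <- which(err == min(err))
  thr <- (min(cuts[best]) + max(cuts[best])) / 2
  list(threshold = thr, misclassified = as.integer(min(err)),
       error_rate = min(err) / length(x), high_side = high)
}
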