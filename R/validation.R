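#' Construct a prediction table
#'
#' Observed/predicted activity pairs with train/test roles — the input of
#' the whole external-validation battery.
#'
#' @param id compound labels.
#' @param y_obs observed pIC50.
#' @param y_pred predicted pIC50.
#' @param role "train" or "test" per row.
#' @return data.frame of class `qsar_prediction_table`.
#' @export
prediction_table <- function(id, y_obs, y_pred, role) {
  stopifnot(length(id) == length(y_obs), length(y_obs) == length(y_pred),
            length(role) == length(y_obs))
  if (anyDuplicated(id)) stop("duplicate ids in prediction table")
  role <- match.arg(role, c("train", "test"), several.ok = TRUE)
  d <- data.frame(id = as.character(id), y_obs = as.numeric(y_obs),
                  y_pred = as.numeric(y_pred), role = role,
                  stringsAsFactors = FALSE)
  class(d) <- c("qsar_prediction_table", class(d))
  d
}

#' Read a prediction table from delimited text
#'
#' Header `id,y_obs,y_pred,role`; comma or tab separated.
#' @param path file path.
#' @return `qsar_prediction_table`.
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("id", "y_obs", "y_pred", "role")
  if (!all(need %in% names(d)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "))
  prediction_table(d$id, d$y_obs, d$y_pred, d$role)
}

split_table <- function(table) {
  tr <- table[table$role == "train", , drop = FALSE]
  te <- table[table$role == "test", , drop = FALSE]
  list(train = tr, test = te)
}

training_range <- function(table) {
  tr <- table[table$role == "train", , drop = FALSE]
  if (!nrow(tr)) stop("training range undefined: no training rows")
  diff(range(tr$y_obs))
}

#' External predictive r2 (r2pred)
#'
#' `r2pred = (SD - PRESS) / SD` where SD is the sum of squared deviations
#' of the test-set observed activities from the training-set mean
#' activity, and PRESS the sum of squared test residuals.
#'
#' @param table `qsar_prediction_table` with train and test rows.
#' @return numeric r2pred.
#' @export
r2pred <- function(table) {
  s <- split_table(table)
  if (!nrow(s$test)) stop("no test rows")
  if (!nrow(s$train)) stop("no training rows")
  sd_ <- sum((s$test$y_obs - mean(s$train$y_obs))^2)
  if (sd_ <= 0) stop("degenerate test set: zero SD about the training mean")
  press <- sum((s$test$y_obs - s$test$y_pred)^2)
  (sd_ - press) / sd_
}

#' Through-origin regression statistics (Golbraikh-Tropsha inputs)
#'
#' Computes, over the test rows: the squared Pearson correlation R2test
#' (with intercept), the through-origin slopes `k = sum(Yobs*Ypred) /
#' sum(Ypred^2)` and `k' = sum(Yobs*Ypred) / sum(Yobs^2)`, and the
#' origin-constrained determination coefficients R02/R'02.
#'
#' Two conventions are supported.  The default (`standard = FALSE`)
#' follows the as-printed forms
#' `R02 = 1 - sum((Ypred - k*Ypred)^2) / sum((Ypred - mean(Ypred))^2)`
#' (and the primed analogue on Yobs with k'), which is what the reference
#' results arithmetically require.  `standard = TRUE` computes the
#' conventional Golbraikh-Tropsha definitions
#' `r02 = 1 - sum((Yobs - k*Ypred)^2) / sum((Yobs - mean(Yobs))^2)` and
#' the primed analogue with observed and predicted exchanged.
#'
#' @param table `qsar_prediction_table` (>= 3 test rows).
#' @param standard use the literature definitions instead of the
#'   as-printed ones.
#' @return list(R2test, k, k_prime, R02, R02_prime).
#' @export
origin_regression <- function(table, standard = FALSE) {
  te <- split_table(table)$test
  if (nrow(te) < 3) stop("need at least 3 test rows")
  yo <- te$y_obs; yp <- te$y_pred
  if (sum(yp^2) == 0 || sum(yo^2) == 0)
    stop("zero denominator in through-origin slope")
  if (stats::sd(yo) == 0 || stats::sd(yp) == 0)
    stop("zero variance in test activities")
  r2 <- stats::cor(yo, yp)^2
  k <- sum(yo * yp) / sum(yp^2)
  kp <- sum(yo * yp) / sum(yo^2)
  if (standard) {
    r02  <- 1 - sum((yo - k  * yp)^2) / sum((yo - mean(yo))^2)
    r02p <- 1 - sum((yp - kp * yo)^2) / sum((yp - mean(yp))^2)
  } else {
    r02  <- 1 - sum((yp - k  * yp)^2) / sum((yp - mean(yp))^2)
    r02p <- 1 - sum((yo - kp * yo)^2) / sum((yo - mean(yo))^2)
  }
  list(R2test = r2, k = k, k_prime = kp, R02 = r02, R02_prime = r02p)
}

#' rm2 metrics
#'
#' `rm2 = R2test * (1 - sqrt(|R2test - R02|))`, the primed variant with
#' R'02, their average and absolute difference.
#'
#' @param R2test,R02,R02_prime inputs, e.g. from [origin_regression()].
#' @return list(rm2, rm2_prime, rm2_avg, delta_rm2).
#' @export
rm2_metrics <- function(R2test, R02, R02_prime) {
  rm2 <- R2test * (1 - sqrt(abs(R2test - R02)))
  rm2p <- R2test * (1 - sqrt(abs(R2test - R02_prime)))
  list(rm2 = rm2, rm2_prime = rm2p,
       rm2_avg = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p))
}

#' MAE-based criteria
#'
#' For each role: MAE = mean absolute residual and sigma = population
#' standard deviation (divisor n) of the absolute residuals.  The rules
#' `MAE <= 0.1 * training range` and `MAE + 3*sigma <= 0.2 * training
#' range` are evaluated against the training-set observed range.
#'
#' @param table `qsar_prediction_table`.
#' @return list per role ("test", "train"): list(MAE, sigma, pass_mae,
#'   pass_mae3s) plus `training_range`.
#' @export
mae_criteria <- function(table) {
  rng <- training_range(table)
  out <- list(training_range = rng)
  for (role in c("test", "train")) {
    d <- table[table$role == role, , drop = FALSE]
    if (nrow(d) < 2) stop("need at least 2 rows in the ", role, " set")
    ae <- abs(d$y_obs - d$y_pred)
    mae <- mean(ae)
    sigma <- sqrt(mean((ae - mae)^2))    # population divisor n
    out[[role]] <- list(
      MAE = mae, sigma = sigma,
      pass_mae = mae <= 0.1 * rng,
      pass_mae3s = mae + 3 * sigma <= 0.2 * rng)
  }
  out
}

#' Golbraikh-Tropsha criteria checklist
#'
#' Evaluates the six published inequalities: q2 > 0.5, R2test > 0.6,
#' (R2test - R02)/R2test < 0.1, (R2test - R'02)/R2test < 0.1,
#' 0.85 <= k <= 1.15 and 0.85 <= k' <= 1.15.
#'
#' @param reg list from [origin_regression()].
#' @param q2 cross-validated q2 of the model.
#' @return named logical vector of the six conditions plus `overall`.
#' @export
gt_criteria <- function(reg, q2) {
  checks <- c(
    q2_gt_0.5        = q2 > 0.5,
    R2test_gt_0.6    = reg$R2test > 0.6,
    rel_R02_lt_0.1   = (reg$R2test - reg$R02) / reg$R2test < 0.1,
    rel_R02p_lt_0.1  = (reg$R2test - reg$R02_prime) / reg$R2test < 0.1,
    k_in_band        = reg$k >= 0.85 & reg$k <= 1.15,
    k_prime_in_band  = reg$k_prime >= 0.85 & reg$k_prime <= 1.15)
  c(checks, overall = all(checks))
}

#' Overall rm2 battery on the union of LOO-train and test predictions
#'
#' Concatenates the training rows (carrying LOO-predicted activities) and
#' the test rows (model-predicted), then runs [origin_regression()] and
#' [rm2_metrics()] on the union treated as one evaluation set.
#'
#' @param loo_train_table `qsar_prediction_table` of training rows with
#'   LOO predictions.
#' @param test_table `qsar_prediction_table` of test rows.
#' @param standard passed to [origin_regression()].
#' @return list(rm2, rm2_prime, rm2_avg, delta_rm2).
#' @export
rm2_overall <- function(loo_train_table, test_table, standard = FALSE) {
  if (!nrow(loo_train_table)) stop("empty LOO training table")
  if (!nrow(test_table)) stop("empty test table")
  if (length(intersect(loo_train_table$id, test_table$id)))
    stop("id collision between training and test tables")
  u <- prediction_table(c(loo_train_table$id, test_table$id),
                        c(loo_train_table$y_obs, test_table$y_obs),
                        c(loo_train_table$y_pred, test_table$y_pred),
                        rep("test", nrow(loo_train_table) + nrow(test_table)))
  reg <- origin_regression(u, standard = standard)
  rm2_metrics(reg$R2test, reg$R02, reg$R02_prime)
}

#' Full validation report
#'
#' Computes the complete external-validation statistic set over a
#' prediction table: r2pred, R2test, R02/R'02 and their relative gaps,
#' k/k', MAE and sigma for both sets, the rm2 battery, and the
#' Golbraikh-Tropsha, MAE and rm2-guideline pass flags.
#'
#' @param table `qsar_prediction_table` with train and test rows.
#' @param q2 optional LOO q2 of the model (needed for the GT checklist).
#' @param standard use conventional instead of as-printed R02 forms.
#' @return list of class `qsar_validation_report`.
#' @export
validation_report <- function(table, q2 = NA_real_, standard = FALSE) {
  reg <- origin_regression(table, standard = standard)
  rm2 <- rm2_metrics(reg$R2test, reg$R02, reg$R02_prime)
  mae <- mae_criteria(table)
  rep_ <- list(
    r2pred = r2pred(table),
    R2test = reg$R2test,
    R02 = reg$R02, R02_prime = reg$R02_prime,
    rel_R02 = (reg$R2test - reg$R02) / reg$R2test,
    rel_R02_prime = (reg$R2test - reg$R02_prime) / reg$R2test,
    k = reg$k, k_prime = reg$k_prime,
    MAE_test = mae$test$MAE, MAE_train = mae$train$MAE,
    sigma_test = mae$test$sigma, sigma_train = mae$train$sigma,
    rm2 = rm2$rm2, rm2_prime = rm2$rm2_prime,
    rm2_avg = rm2$rm2_avg, delta_rm2 = rm2$delta_rm2,
    training_range = mae$training_range,
    q2 = q2,
    mae_pass = list(test = c(mae$test$pass_mae, mae$test$pass_mae3s),
                    train = c(mae$train$pass_mae, mae$train$pass_mae3s)),
    rm2_guideline = rm2$rm2_avg > 0.5 & rm2$delta_rm2 < 0.2,
    gt = if (!is.na(q2)) gt_criteria(reg, q2) else NULL)
  class(rep_) <- "qsar_validation_report"
  rep_
}

#' @export
print.qsar_validation_report <- function(x, digits = 3, ...) {
  keys <- c("r2pred", "R2test", "R02", "R02_prime", "rel_R02",
            "rel_R02_prime", "k", "k_prime", "MAE_test", "MAE_train",
            "sigma_test", "sigma_train", "rm2", "rm2_prime", "rm2_avg",
            "delta_rm2")
  for (k in keys)
    cat(sprintf("%-14s %s\n", k, format(round_half_up(x[[k]], digits),
                                        nsmall = digits)))
  cat(sprintf("%-14s %s\n", "rm2 guideline",
              ifelse(x$rm2_guideline, "pass", "FAIL")))
  if (!is.null(x$gt))
    cat(sprintf("%-14s %s\n", "GT overall",
                ifelse(x$gt["overall"], "pass", "FAIL")))
  invisible(x)
}

# half-up rounding at `digits` decimals, as used for report display
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pareto ranking of candidate models
#'
#' Non-dominated sorting over (q2, r2, F) maximised and SEE minimised.
#' Front 0 is the non-dominated set; within a front, models are ordered by
#' q2 descending (ties by row order).
#'
#' @param models data.frame with columns `q2`, `r2`, `SEE`, `F`.
#' @return the data.frame with an added integer `front` column, reordered
#'   by front then q2.
#' @export
pareto_rank <- function(models) {
  stopifnot(nrow(models) >= 1,
            all(c("q2", "r2", "SEE", "F") %in% names(models)))
  n <- nrow(models)
  dominates <- function(i, j) {
    ge <- models$q2[i] >= models$q2[j] && models$r2[i] >= models$r2[j] &&
      models$F[i] >= models$F[j] && models$SEE[i] <= models$SEE[j]
    gt <- models$q2[i] > models$q2[j] || models$r2[i] > models$r2[j] ||
      models$F[i] > models$F[j] || models$SEE[i] < models$SEE[j]
    ge && gt
  }
  front <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) j != i && dominates(j, i),
                  logical(1))), logical(1))]
    front[nd] <- level
    remaining <- setdiff(remaining, nd)
    level <- level + 1L
  }
  models$front <- front
  models[order(models$front, -models$q2), , drop = FALSE]
}

#' Progressive y-scrambling
#'
#' Robustness check: the response is sorted, cut into bins, and scrambled
#' within bins — coarse structure is preserved while fine structure is
#' destroyed.  For each bin count and repetition, the correlation
#' `r2yy' = cor(y, y_scrambled)^2` and the cross-validated `q2'` of a
#' model refit on the scrambled response are recorded.  A quadratic of
#' q2' against r2yy' is fitted; the reported Q2 is its value at the
#' critical point r2yy' = 0.85 and the slope is its derivative there.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param c component count for the refits.
#' @param n_bins_list bin counts defining the scrambling schedule
#'   (default 2:8; fewer bins = stronger scrambling).
#' @param reps repetitions per level (>= 10).
#' @param seed RNG seed (fully determines the output).
#' @param critical r2yy' evaluation point (default 0.85).
#' @return list of class `qsar_scrambling`: Q2, slope, levels data.frame
#'   (r2yy, q2) sorted by r2yy, and the unscrambled q2.
#' @export
progressive_scrambling <- function(X, y, c, n_bins_list = 2:8, reps = 20,
                                   seed = 1, critical = 0.85) {
  if (reps < 10) stop("reps must be >= 10")
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(unique(y)) < max(n_bins_list))
    stop("too few distinct y values for ", max(n_bins_list), " bins")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ord <- order(y)
  r2yy <- numeric(); q2s <- numeric()
  for (nb in n_bins_list) {
    bins <- cut(seq_along(y), breaks = nb, labels = FALSE)
    for (r in seq_len(reps)) {
      ys <- y
      for (b in seq_len(nb)) {
        idx <- ord[bins == b]
        if (length(idx) > 1) ys[idx] <- y[idx][sample.int(length(idx))]
      }
      r2yy <- c(r2yy, stats::cor(y, ys)^2)
      q2c <- loo_q2(X, ys, c)
      q2s <- c(q2s, q2c[c])
    }
  }
  base_q2 <- loo_q2(X, y, c)[c]
  lev <- data.frame(r2yy = r2yy, q2 = q2s)
  lev <- lev[order(lev$r2yy), , drop = FALSE]
  fit <- stats::lm(q2 ~ r2yy + I(r2yy^2),
                   data = rbind(lev, data.frame(r2yy = 1, q2 = base_q2)))
  co <- stats::coef(fit)
  structure(list(
    Q2 = as.numeric(co[1] + co[2] * critical + co[3] * critical^2),
    slope = as.numeric(co[2] + 2 * co[3] * critical),
    levels = lev, q2_unscrambled = base_q2, critical = critical),
    class = "qsar_scrambling")
}

#' @export
print.qsar_scrambling <- function(x, ...) {
  cat(sprintf("<qsar_scrambling: Q2(%.2f) = %.3f, slope = %.3f, %d levels>\n",
              x$critical, x$Q2, x$slope, nrow(x$levels)))
  invisible(x)
}
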