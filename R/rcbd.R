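# Pen-level randomized-complete-block analysis.  Fits go through the
# standard model machinery (stats::lm, lmerTest::lmer, stats::glm);
# least-squares means, their standard errors and unadjusted pairwise
# t-tests are obtained by contrast algebra on the fitted model, exactly
# as mixed-model LSMEANS are defined (treatment prediction averaged over
# block levels).

.rcbd_frame <- function(data, response, treatment, block) {
  .check_cols(data, c(response, treatment, block), "data")
  df <- data.frame(
    .y = data[[response]],
    .trt = factor(data[[treatment]], levels = unique(data[[treatment]])),
    .blk = factor(data[[block]])
  )
  if (nlevels(df$.trt) < 2) stop("need at least 2 treatments")
  if (nlevels(df$.blk) < 2) stop("need at least 2 blocks")
  df
}

# Treatment LS-mean contrast matrix for a fit on .trt + .blk: one row
# per treatment, averaging the design row over all block levels.
.lsmean_contrasts <- function(fit, df, with_block = TRUE) {
  grid <- expand.grid(.trt = levels(df$.trt), .blk = levels(df$.blk))
  form <- if (with_block) ~ .trt + .blk else ~ .trt
  X <- stats::model.matrix(form, grid)
  L <- t(vapply(levels(df$.trt), function(tr) {
    colMeans(X[grid$.trt == tr, , drop = FALSE])
  }, numeric(ncol(X))))
  rownames(L) <- levels(df$.trt)
  L
}

.pairwise_t <- function(L, beta, V, ddf) {
  trt <- rownames(L)
  pairs <- utils::combn(trt, 2)
  est <- se <- pv <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    d <- L[pairs[1, k], ] - L[pairs[2, k], ]
    est[k] <- sum(d * beta)
    se[k] <- sqrt(drop(t(d) %*% V %*% d))
    tval <- est[k] / se[k]
    pv[k] <- 2 * stats::pt(-abs(tval), ddf)
  }
  data.frame(a = pairs[1, ], b = pairs[2, ], estimate = est, se = se,
             df = ddf, p_value = pv, stringsAsFactors = FALSE)
}

#' Classify a treatment P-value
#'
#' `p <= 0.05` is significant; `0.05 < p <= 0.10` is a tendency;
#' anything larger (or undefined) is non-significant.
#'
#' @param p P-value(s) in `[0, 1]` (NA tolerated).
#' @param alpha Significance threshold (default 0.05).
#' @param alpha_tendency Tendency threshold (default 0.10).
#' @return Character vector: `"significant"`, `"tendency"` or `"ns"`.
#' @examples
#' classify_significance(c(0.04, 0.08, 0.29))
#' @export
classify_significance <- function(p, alpha = 0.05, alpha_tendency = 0.10) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p <= alpha_tendency] <- "tendency"
  out[!is.na(p) & p <= alpha] <- "significant"
  out
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb algorithm: treatments not significantly different
#' at `alpha` share at least one letter; significantly different
#' treatments share none.  Letters are assigned in decreasing order of
#' the means.
#'
#' @param ls_means Named numeric vector of treatment means.
#' @param pairwise Data.frame with columns `a`, `b`, `p_value` (one row
#'   per unordered treatment pair).
#' @param alpha Threshold for declaring a pair different (default 0.10).
#' @param labels Pool of letters to draw from.
#' @return Named character vector of letter groups per treatment; all
#'   empty strings when no pair differs is avoided by assigning a single
#'   shared letter.
#' @examples
#' letter_grouping(c(A = 3, B = 2, C = 1),
#'                 data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
#'                            p_value = c(0.5, 0.01, 0.5)))
#' @export
letter_grouping <- function(ls_means, pairwise, alpha = 0.10,
                            labels = letters) {
  trt <- names(sort(ls_means, decreasing = TRUE))
  sets <- list(trt)
  sig <- pairwise[!is.na(pairwise$p_value) & pairwise$p_value <= alpha, ,
                  drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    a <- sig$a[k]; b <- sig$b[k]
    new_sets <- list()
    for (S in sets) {
      if (all(c(a, b) %in% S)) {
        new_sets <- c(new_sets, list(setdiff(S, a)), list(setdiff(S, b)))
      } else {
        new_sets <- c(new_sets, list(S))
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  # order letters by the best-ranked member of each set
  rank_of <- function(S) min(match(S, trt))
  sets <- sets[order(vapply(sets, rank_of, numeric(1)))]
  out <- stats::setNames(rep("", length(trt)), trt)
  for (i in seq_along(sets)) {
    for (tr in sets[[i]]) out[tr] <- paste0(out[tr], labels[i])
  }
  out[names(ls_means)]
}

#' Fit a pen-level randomized-complete-block model
#'
#' Additive two-factor model (treatment + block, no interaction) on one
#' response per pen, with pen as the experimental unit.  Block enters as
#' a fixed effect by default; a random-block (REML) variant is provided
#' because intercept-only block variance leaves the balanced treatment
#' F-test unchanged.  Letters are assigned from unadjusted pairwise
#' t-tests at the tendency threshold.
#'
#' @param data Data.frame with one row per pen.
#' @param response Name of the response column.
#' @param treatment,block Names of the design columns.
#' @param block_effect `"fixed"` (default) or `"random"`.
#' @param alpha,alpha_tendency Significance and tendency thresholds.
#' @param pairwise Compute pairwise comparisons and letters (default
#'   TRUE; skip for speed in simulation loops).
#' @return An object of class `rcbd_fit`: list with `response`,
#'   `ls_means`, `se` (per-treatment SE), `sem` (average SE of a
#'   treatment mean), `p_value`, `classification`, `letter_groups`,
#'   `pairwise`, `block_effect`, `fit`.
#' @export
fit_rcbd <- function(data, response, treatment = "treatment",
                     block = "block", block_effect = c("fixed", "random"),
                     alpha = 0.05, alpha_tendency = 0.10, pairwise = TRUE) {
  block_effect <- match.arg(block_effect)
  df <- .rcbd_frame(data, response, treatment, block)
  if (block_effect == "fixed") {
    fit <- stats::lm(.y ~ .trt + .blk, data = df)
    an <- stats::drop1(fit, scope = ~ .trt + .blk, test = "F")
    p <- an[".trt", "Pr(>F)"]
    if (stats::sigma(fit)^2 < 1e-20) {
      # exact fit: means either coincide (no evidence, p = 1) or differ
      # deterministically
      tm <- tapply(df$.y, df$.trt, mean)
      p <- if (max(tm) - min(tm) < 1e-12) 1 else 0
    }
    L <- .lsmean_contrasts(fit, df)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    ddf <- fit$df.residual
  } else {
    fit <- lmerTest::lmer(.y ~ .trt + (1 | .blk), data = df)
    an <- suppressMessages(stats::anova(fit))  # Satterthwaite F
    p <- an[".trt", "Pr(>F)"]
    grid <- data.frame(.trt = levels(df$.trt))
    L <- stats::model.matrix(~ .trt, grid)
    rownames(L) <- levels(df$.trt)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ddf <- an[".trt", "DenDF"]
  }
  if (is.na(p) || is.nan(p)) p <- 1  # zero-variance convention
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  pw <- if (pairwise) .pairwise_t(L, beta, V, ddf) else NULL
  lg <- if (pairwise && p <= alpha_tendency) {
    letter_grouping(est, pw, alpha = alpha_tendency)
  } else {
    stats::setNames(rep("", length(est)), names(est))
  }
  structure(list(
    response = response, ls_means = est, se = se, sem = mean(se),
    p_value = p, classification = classify_significance(p, alpha,
                                                        alpha_tendency),
    letter_groups = lg, pairwise = pw, block_effect = block_effect,
    fit = fit
  ), class = "rcbd_fit")
}

#' Binomial grade-distribution analysis at the pen level
#'
#' Logit-link binomial GLM on per-pen counts with fixed block and
#' treatment effects; treatment means are the logit-scale LS means
#' back-transformed to percentages, and the treatment P-value is the
#' likelihood-ratio test against the block-only model.  Complete
#' separation (a category entirely absent or entirely full) is reported
#' with a `separation` flag and boundary means.
#'
#' @param data Data.frame with one row per pen.
#' @param successes,trials Names of the count columns (successes out of
#'   trials, e.g. carcasses in a grade class out of head harvested).
#' @param treatment,block Design columns.
#' @param alpha,alpha_tendency Thresholds for [classify_significance()].
#' @return An `rcbd_fit` object; `ls_means` are percentages, plus a
#'   logical `separation` element.
#' @export
fit_binomial_proportions <- function(data, successes, trials,
                                     treatment = "treatment",
                                     block = "block", alpha = 0.05,
                                     alpha_tendency = 0.10) {
  .check_cols(data, c(successes, trials, treatment, block), "data")
  df <- .rcbd_frame(data, successes, treatment, block)
  df$.n <- data[[trials]]
  if (any(df$.n <= 0)) stop("`trials` must be positive for every pen")
  if (any(df$.y < 0 | df$.y > df$.n)) {
    stop("successes must lie in [0, trials]")
  }
  full <- suppressWarnings(
    stats::glm(cbind(.y, .n - .y) ~ .trt + .blk, family = stats::binomial,
               data = df))
  null <- suppressWarnings(
    stats::glm(cbind(.y, .n - .y) ~ .blk, family = stats::binomial,
               data = df))
  lrt <- stats::anova(null, full, test = "Chisq")
  p <- lrt$`Pr(>Chi)`[2]
  if (is.na(p)) p <- 1
  L <- .lsmean_contrasts(full, df)
  eta <- drop(L %*% stats::coef(full))
  prop <- 100 * stats::plogis(eta)
  se_eta <- sqrt(diag(L %*% stats::vcov(full) %*% t(L)))
  # delta-method SE on the percentage scale
  se <- 100 * stats::dlogis(eta) * se_eta
  sep_by_trt <- tapply(df$.y, df$.trt, sum) %in%
    c(0, tapply(df$.n, df$.trt, sum))
  separation <- any(sep_by_trt) || any(abs(stats::coef(full)) > 15,
                                       na.rm = TRUE)
  structure(list(
    response = successes, ls_means = prop, se = se, sem = mean(se),
    p_value = p,
    classification = classify_significance(p, alpha, alpha_tendency),
    letter_groups = stats::setNames(rep("", length(prop)), names(prop)),
    pairwise = NULL, block_effect = "fixed", separation = separation,
    fit = full
  ), class = "rcbd_fit")
}

#' @exportS3Method base::print
print.rcbd_fit <- function(x, ...) {
  cat("RCBD fit:", x$response, "(block effect:", x$block_effect, ")\n")
  m <- data.frame(ls_mean = round(x$ls_means, 4), se = round(x$se, 4),
                  letters = x$letter_groups)
  print(m, ...)
  cat(sprintf("SEM = %.4g, treatment P = %.3g (%s)\n",
              x$sem, x$p_value, x$classification))
  invisible(x)
}
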