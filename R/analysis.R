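# Cohort-level statistics: feature tables, shrinkage LDA separability,
# Kruskal-Wallis + Dunn comparisons, paired model-vs-clinical tests.

#' Assemble a per-patient feature table
#'
#' Three feature sets are supported: `"clinical"` (HR, CO, PAWP, mPAP,
#' sPAP, dPAP from the routine summaries), `"model"` (the influential
#' parameter subvector plus the PV-loop metrics EDV, ESV, SV, EDP, ESP,
#' SW), and `"combined"` (their union). Model features come from supplied
#' calibration fits when given, otherwise from the cohort's ground-truth
#' parameters and noiseless simulations. Columns are z-scored for use in
#' LDA.
#'
#' @param cohort a [generate_cohort()] result, or a list of
#'   `virtual_patient` objects.
#' @param selector `"clinical"`, `"model"` or `"combined"`.
#' @param fits optional list of [calibrate_patient()] results (one per
#'   patient, same order); their `theta_hat` and fitted simulations then
#'   provide the model features.
#' @return List of class `feature_table`: standardized matrix `features`,
#'   unstandardized `raw`, factor `labels`, `selector`, and column
#'   provenance.
#' @export
build_feature_table <- function(cohort,
                                selector = c("clinical", "model", "combined"),
                                fits = NULL) {
  selector <- match.arg(selector)
  patients <- if (inherits(cohort, "virtual_cohort")) cohort$patients else cohort
  if (!is.null(fits) && length(fits) != length(patients))
    stop("fits must match the cohort patient list")

  clin <- t(vapply(patients, function(pt) {
    s <- pt$summary
    c(HR = s$HR, CO = s$CO, PAWP = s$PAWP, mPAP = s$mPAP,
      sPAP = s$sPAP, dPAP = s$dPAP)
  }, numeric(6)))

  model <- t(vapply(seq_along(patients), function(i) {
    pt <- patients[[i]]
    if (is.null(fits)) {
      theta <- theta_from_parameters(pt$truth)
      pv <- pt$pv
    } else {
      theta <- fits[[i]]$theta_hat
      pv <- pv_loop_metrics(fits[[i]]$sim)
    }
    c(theta, EDV = pv$EDV, ESV = pv$ESV, SV = pv$SV,
      EDP = pv$EDP, ESP = pv$ESP, SW = pv$SW_J)
  }, numeric(15)))

  raw <- switch(selector,
                clinical = clin,
                model = model,
                combined = cbind(clin, model))
  labels <- factor(vapply(patients, function(pt) pt$phenotype, character(1)))
  sds <- apply(raw, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(colnames(raw)[sds == 0], collapse = ", "))
  features <- scale(raw)
  out <- list(features = features, raw = raw, labels = labels,
              selector = selector,
              provenance = if (is.null(fits)) "truth" else "fitted")
  class(out) <- "feature_table"
  out
}

# pooled within-class covariance with diagonal shrinkage
.pooled_cov <- function(X, g, lambda) {
  p <- ncol(X)
  S <- matrix(0, p, p)
  for (lv in levels(g)) {
    Xi <- X[g == lv, , drop = FALSE]
    if (nrow(Xi) > 1)
      S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  S <- S / (nrow(X) - nlevels(g))
  (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
}

.lda_classify <- function(X, g, Xnew, lambda, priors) {
  Sinv <- solve(.pooled_cov(X, g, lambda))
  lv <- levels(g)
  scores <- vapply(lv, function(l) {
    mu <- colMeans(X[g == l, , drop = FALSE])
    drop(Xnew %*% Sinv %*% mu) - 0.5 * drop(mu %*% Sinv %*% mu) +
      log(priors[l])
  }, numeric(nrow(Xnew)))
  lv[max.col(matrix(scores, nrow = nrow(Xnew)))]
}

#' Linear discriminant separability of phenotype groups
#'
#' Gaussian LDA with pooled within-class covariance, shrunk toward a
#' scaled identity when the feature count approaches the sample size or
#' the covariance is ill-conditioned. Returns the two leading discriminant
#' axes (for 2D projection plots) and the leave-one-out classification
#' accuracy, a quantitative separability score.
#'
#' @param ft a [build_feature_table()] result.
#' @param lambda shrinkage intensity in `[0, 1)`; `NULL` selects 0 when
#'   the pooled covariance is well-conditioned and 0.25 otherwise (with a
#'   message).
#' @return List of class `lda_result`: per-patient 2D `projection`,
#'   `scalings` (discriminant vectors), `loo_accuracy`, per-class
#'   `centroids`, `lambda`, `labels`.
#' @export
lda_separability <- function(ft, lambda = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  X <- unclass(ft$features)
  g <- ft$labels
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (k < 2 || any(table(g) < 2))
    stop("need >= 2 classes with >= 2 members each")
  if (is.null(lambda)) {
    S <- .pooled_cov(X, g, 0)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    lambda <- if (n - k > p && min(ev) > 1e-8 * max(ev)) 0 else 0.25
    if (lambda > 0)
      message("pooled covariance ill-conditioned; shrinkage lambda = ", lambda)
  }
  Sw <- .pooled_cov(X, g, lambda)
  mu <- colMeans(X)
  B <- matrix(0, p, p)
  for (lv in levels(g)) {
    d <- colMeans(X[g == lv, , drop = FALSE]) - mu
    B <- B + sum(g == lv) * tcrossprod(d)
  }
  M <- solve(Sw, B)
  ei <- eigen(M)
  n_axes <- min(k - 1, p, 2)
  W <- Re(ei$vectors[, seq_len(n_axes), drop = FALSE])
  proj <- X %*% W
  colnames(proj) <- paste0("LD", seq_len(n_axes))

  priors <- table(g) / n
  loo <- vapply(seq_len(n), function(i) {
    .lda_classify(X[-i, , drop = FALSE], droplevels(g[-i]),
                  X[i, , drop = FALSE], lambda,
                  table(droplevels(g[-i])) / (n - 1))
  }, character(1))
  centroids <- do.call(rbind, lapply(levels(g), function(lv)
    colMeans(proj[g == lv, , drop = FALSE])))
  rownames(centroids) <- levels(g)
  out <- list(projection = proj, scalings = W,
              loo_accuracy = mean(loo == as.character(g)),
              loo_predicted = loo,
              centroids = centroids, lambda = lambda, labels = g,
              selector = ft$selector)
  class(out) <- "lda_result"
  out
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("LDA (%s features): LOO accuracy %.2f, shrinkage %.2f\n",
              x$selector, x$loo_accuracy, x$lambda))
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn pairwise comparisons
#'
#' Rank-based comparison of a metric across phenotype groups: the
#' tie-corrected Kruskal-Wallis H statistic and omnibus p-value, followed
#' by Dunn's z statistics for all group pairs with a configurable
#' multiplicity adjustment (default Holm). Pairs with adjusted p < 0.05
#' are flagged.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of group labels, same length.
#' @param adjust p-adjustment method for the Dunn comparisons (any
#'   [stats::p.adjust()] method; `"none"`, `"bonferroni"`, `"holm"`).
#' @return List of class `group_tests`: `H`, `df`, `p_value`, and data
#'   frame `dunn` (pair, z, p, p_adj, significant). All-identical values
#'   yield `H = NA` with a note.
#' @export
group_tests <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 members each")
  if (length(unique(values)) == 1) {
    return(structure(list(H = NA_real_, df = nlevels(groups) - 1,
                          p_value = NA_real_, dunn = NULL,
                          note = "all values identical; H undefined"),
                     class = "group_tests"))
  }
  kw <- stats::kruskal.test(values, groups)

  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  dunn <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- sum(groups == a); nb <- sum(groups == b)
    z <- (mean(r[groups == a]) - mean(r[groups == b])) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  dunn <- do.call(rbind, dunn)
  dunn$p_adj <- stats::p.adjust(dunn$p, method = adjust)
  dunn$significant <- dunn$p_adj < 0.05
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, dunn = dunn),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  if (is.na(x$H)) {
    cat("Kruskal-Wallis: H undefined (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("Kruskal-Wallis: H = %.3f (df %d), p = %.4g\n",
                x$H, x$df, x$p_value))
    print(x$dunn, digits = 3)
  }
  invisible(x)
}

#' Paired model-vs-clinical agreement test
#'
#' Paired two-sample t-test on the per-patient differences between a
#' model-derived and a clinically measured metric. Note the inverted
#' reading: a significant p (< 0.05) indicates *poor* agreement. When all
#' differences are zero the metric agrees exactly and no test statistic
#' exists.
#'
#' @param model,clinical paired numeric vectors (n >= 3).
#' @return List of class `paired_agreement`: `t`, `df`, `p_value`,
#'   `mean_difference`, `agreement` (`"exact"`, `"consistent"` or
#'   `"poor"`).
#' @export
model_vs_clinical_ttest <- function(model, clinical) {
  stopifnot(length(model) == length(clinical))
  if (length(model) < 3) stop("need n >= 3 pairs")
  d <- model - clinical
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1,
                          p_value = NA_real_, mean_difference = mean(d),
                          agreement = if (all(d == 0)) "exact" else "constant offset"),
                     class = "paired_agreement"))
  }
  tt <- stats::t.test(model, clinical, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_difference = mean(d),
                 agreement = if (tt$p.value < 0.05) "poor" else "consistent"),
            class = "paired_agreement")
}

#' @export
print.paired_agreement <- function(x, ...) {
  if (is.na(x$t)) {
    cat("Paired comparison:", x$agreement,
        sprintf("(mean difference %.3g)\n", x$mean_difference))
  } else {
    cat(sprintf(
      "Paired t: t = %.3f (df %d), p = %.4g -> %s agreement (mean diff %.3g)\n",
      x$t, x$df, x$p_value, x$agreement, x$mean_difference))
  }
  invisible(x)
}
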