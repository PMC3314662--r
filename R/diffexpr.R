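#' Lowess normalization of a probe intensity table
#'
#' Log2-transforms raw intensities and removes, per array, the
#' intensity-dependent bias against a median pseudo-reference array: for each
#' array the deviation M from the per-probe median reference is regressed on
#' the average log intensity A by locally weighted regression
#' ([stats::lowess()]) and the fitted curve is subtracted. This is the
#' single-channel analogue of two-colour MA-plot loess normalization.
#'
#' @param table A `probe_table` of strictly positive raw intensities.
#' @param span Lowess smoother span (fraction of points; default 0.3).
#' @return A `probe_table` on the log2 scale (`log2 = TRUE`).
#' @export
lowess_normalize <- function(table, span = 0.3) {
  stopifnot(inherits(table, "probe_table"))
  if (length(table$probe_ids) == 0 || length(table$array_ids) == 0)
    stop("empty intensity table")
  if (isTRUE(table$log2))
    stop("table is already on the log2 scale")
  if (any(table$values <= 0) || any(!is.finite(table$values)))
    stop("all intensities must be positive and finite before log transform")
  l <- log2(table$values)
  ref <- apply(l, 1, stats::median)
  out <- l
  for (j in seq_len(ncol(l))) {
    M <- l[, j] - ref
    A <- (l[, j] + ref) / 2
    fit <- stats::lowess(A, M, f = span)
    bias <- if (length(unique(fit$x)) < 2) rep(mean(M), length(A))
            else stats::approx(fit$x, fit$y, xout = A, rule = 2,
                               ties = mean)$y
    out[, j] <- l[, j] - bias
  }
  res <- table
  res$values <- out
  res$log2 <- TRUE
  res
}

#' Fit the per-probe-set mixed model for one probe set
#'
#' Fits, for a single probe set, the paired-design model
#' `y = mu + T + P + A + e` with a treatment fixed effect T (inseminated vs
#' non-inseminated), a probe fixed effect P and a random array effect A, and
#' returns the least-squares-mean treatment difference oriented
#' non-inseminated minus inseminated (N - Y) with its p-value.
#'
#' Two routes are available. `"array_means"` (default) is the exact
#' closed-form analysis for the balanced case: treatment is a between-array
#' (whole-plot) factor, so averaging each array over the probe set's probes
#' and comparing array means between conditions with a pooled-variance t test
#' (df = arrays - 2) reproduces the REML treatment contrast and its Wald/F
#' test. `"reml"` fits the model by restricted likelihood via
#' [lmerTest::lmer()] (Satterthwaite df) and falls back to ordinary least
#' squares when the array variance estimate is singular — with three arrays
#' per condition the variance estimate is fragile. With a single probe the P
#' term drops out.
#'
#' @param values Numeric matrix of log2 intensities, probes (rows) of this
#'   probe set by arrays (columns, named by array id), or a vector for a
#'   single-probe set.
#' @param design The [array_design()] data frame covering the columns.
#' @param probe_set_id Identifier carried into the result.
#' @param method `"array_means"` or `"reml"`.
#' @return A one-row data frame: `probe_set_id`, `lsmean_diff` (N - Y, log2
#'   units), `p_raw`, `direction` (`"down_in_embryo"` when the difference is
#'   positive, i.e. expression lower in the inseminated horn), `degenerate`
#'   (TRUE when the residual variance was zero and the p-value is not
#'   informative).
#' @export
fit_probe_set <- function(values, design, probe_set_id = "probe_set",
                          method = c("array_means", "reml")) {
  method <- match.arg(method)
  if (is.vector(values)) values <- matrix(values, nrow = 1,
                                          dimnames = list(NULL, names(values)))
  if (is.null(colnames(values)))
    colnames(values) <- design$array_id
  design <- design[match(colnames(values), design$array_id), ]
  if (anyNA(design$array_id)) stop("design does not cover all value columns")
  cond <- design$condition
  if (length(unique(cond)) < 2)
    stop("both conditions must be present")
  if (length(unique(design$animal_id)) < 2)
    stop("at least two animals are required")

  if (method == "array_means") {
    m <- colMeans(values)
    mN <- m[cond == "non_inseminated"]
    mY <- m[cond == "inseminated"]
    diff <- mean(mN) - mean(mY)
    df <- length(m) - 2
    pooled <- (sum((mN - mean(mN))^2) + sum((mY - mean(mY))^2)) / df
    degenerate <- pooled <= 0
    if (degenerate) {
      warning("zero residual variance for probe set ", probe_set_id,
              "; p-value is degenerate")
      p <- if (diff == 0) 1 else 0
    } else {
      se <- sqrt(pooled * (1 / length(mN) + 1 / length(mY)))
      p <- 2 * stats::pt(-abs(diff / se), df)
    }
  } else {
    long <- data.frame(
      y = as.vector(values),
      probe = factor(rep(seq_len(nrow(values)), ncol(values))),
      condition = rep(cond, each = nrow(values)),
      array = factor(rep(colnames(values), each = nrow(values)))
    )
    form <- if (nrow(values) > 1) y ~ condition + probe + (1 | array)
            else y ~ condition + (1 | array)
    fit <- suppressMessages(suppressWarnings(
      try(lmerTest::lmer(form, data = long), silent = TRUE)))
    singular <- inherits(fit, "try-error") || lme4::isSingular(fit)
    if (singular) {
      form_ols <- if (nrow(values) > 1) y ~ condition + probe
                  else y ~ condition
      fit <- stats::lm(form_ols, data = long)
      co <- summary(fit)$coefficients
    } else {
      co <- stats::coef(summary(fit))
    }
    row <- grep("^condition", rownames(co))
    # coefficient is inseminated - non_inseminated; report N - Y
    diff <- -co[row, "Estimate"]
    p <- co[row, ncol(co)]
    degenerate <- !is.finite(p)
    if (degenerate) p <- if (diff == 0) 1 else 0
  }
  data.frame(
    probe_set_id = probe_set_id, lsmean_diff = unname(diff),
    p_raw = unname(p),
    direction = if (diff > 0) "down_in_embryo" else "up_in_embryo",
    degenerate = degenerate, stringsAsFactors = FALSE
  )
}

#' Fit the mixed model across all probe sets of a table
#'
#' Vectorized application of the balanced-design closed form of
#' [fit_probe_set()] to every probe set of a log2-scale table: probes are
#' averaged to per-array probe-set means and the treatment contrast is tested
#' in the between-array stratum. Probes sharing a `probe_set_id` in the
#' grouping are fitted jointly (the probe fixed effect is eliminated exactly
#' by the array averaging in the balanced design).
#'
#' @param table A `probe_table` on the log2 scale (see [lowess_normalize()]).
#' @param probe_sets Character vector, one probe-set id per probe of the
#'   table; defaults to each probe being its own probe set.
#' @return A data frame with one row per probe set: `probe_set_id`,
#'   `lsmean_diff` (N - Y), `p_raw`, `direction`, `degenerate`.
#' @export
fit_all_probe_sets <- function(table, probe_sets = NULL) {
  stopifnot(inherits(table, "probe_table"))
  if (!isTRUE(table$log2))
    stop("table must be on the log2 scale; run lowess_normalize() first")
  if (is.null(probe_sets)) probe_sets <- table$probe_ids
  if (length(probe_sets) != length(table$probe_ids))
    stop("probe_sets must have one entry per probe")
  grp <- factor(probe_sets, levels = unique(probe_sets))
  counts <- as.vector(table(grp))
  means <- rowsum(table$values, grp, reorder = FALSE) / counts

  cond <- table$design$condition[match(colnames(means),
                                       table$design$array_id)]
  isN <- cond == "non_inseminated"
  mN <- means[, isN, drop = FALSE]
  mY <- means[, !isN, drop = FALSE]
  nN <- ncol(mN); nY <- ncol(mY)
  if (nN == 0 || nY == 0) stop("both conditions must be present")
  diff <- rowMeans(mN) - rowMeans(mY)
  df <- nN + nY - 2
  ssN <- rowSums((mN - rowMeans(mN))^2)
  ssY <- rowSums((mY - rowMeans(mY))^2)
  pooled <- (ssN + ssY) / df
  se <- sqrt(pooled * (1 / nN + 1 / nY))
  p <- 2 * stats::pt(-abs(diff / se), df)
  degenerate <- pooled <= 0
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  data.frame(
    probe_set_id = levels(grp), lsmean_diff = unname(diff),
    p_raw = unname(p),
    direction = ifelse(diff > 0, "down_in_embryo", "up_in_embryo"),
    degenerate = unname(degenerate), stringsAsFactors = FALSE
  )
}

#' Bonferroni adjustment with significance flags
#'
#' Family-wise error control by Bonferroni: `p_adj = min(1, m * p_raw)` over
#' the m tests, flagged significant when the adjusted p-value is below
#' `alpha`.
#'
#' @param p_raw Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame with `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni <- function(p_raw, alpha = 0.05) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  data.frame(p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha)
}

#' Volcano table of differential-expression results
#'
#' One row per probe set with the effect size (lsmean treatment difference,
#' N - Y), `-log10` of the Bonferroni-adjusted p-value, and the significance
#' flag — the numeric content of a volcano plot.
#'
#' @param results Data frame from [fit_all_probe_sets()] (or row-bound
#'   [fit_probe_set()] results).
#' @param alpha Family-wise significance level.
#' @return Data frame: `probe_set_id`, `lsmean_diff`, `neg_log10_p_adj`,
#'   `significant`.
#' @export
volcano_table <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) stop("no results to tabulate")
  adj <- bonferroni(results$p_raw, alpha)
  data.frame(
    probe_set_id = results$probe_set_id,
    lsmean_diff = results$lsmean_diff,
    neg_log10_p_adj = -log10(adj$p_adj),
    significant = adj$significant,
    stringsAsFactors = FALSE
  )
}

#' Comparative CT (delta-delta-CT) quantification
#'
#' Relative qPCR quantification: per group, delta-CT is the mean cycle
#' threshold of the tested gene minus that of the reference gene
#' (beta-actin in the validation assays); delta-delta-CT is the difference of
#' delta-CT between the two groups (first minus second, by convention
#' inseminated minus non-inseminated); the fold change is
#' `2^(-delta-delta-CT)`.
#'
#' @param ct_gene Named list of two numeric vectors: CT replicates of the
#'   tested gene in each group.
#' @param ct_reference Named list matching `ct_gene`: CT replicates of the
#'   reference gene.
#' @return A list: `delta_ct` (named per group), `delta_delta_ct`,
#'   `fold_change`.
#' @export
#' @examples
#' ddct(list(ins = c(25, 25.2), non = c(23, 23.1)),
#'      list(ins = c(20, 20.1), non = c(20, 20)))
ddct <- function(ct_gene, ct_reference) {
  if (!is.list(ct_gene) || length(ct_gene) != 2)
    stop("ct_gene must be a list of two groups")
  if (!is.list(ct_reference) || length(ct_reference) != 2)
    stop("ct_reference must be a list of two groups")
  if (!is.null(names(ct_gene)) && !is.null(names(ct_reference)) &&
      !identical(names(ct_gene), names(ct_reference)))
    stop("group names of ct_gene and ct_reference must match")
  vals <- unlist(c(ct_gene, ct_reference))
  if (any(!is.finite(vals))) stop("CT values must be finite")
  dct <- vapply(seq_len(2), function(g)
    mean(ct_gene[[g]]) - mean(ct_reference[[g]]), numeric(1))
  names(dct) <- names(ct_gene)
  ddct <- dct[[1]] - dct[[2]]
  list(delta_ct = dct, delta_delta_ct = unname(ddct),
       fold_change = 2^(-ddct))
}
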