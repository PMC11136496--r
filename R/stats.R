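## Shared statistics: rank-sum test, Pearson correlation with t-test,
## Dixon's Q gate for qPCR technical triplicates, and delta/delta-delta-Ct
## fold changes.

#' Two-sided unpaired rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' Rank-sum statistic with midranks for ties. The null distribution is exact
#' (full enumeration) when `min(n) <= exact_max_n` and there are no ties, and
#' a tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max_n exact-enumeration cutoff on the smaller sample size.
#' @return List of class `test_result`: `statistic` (rank sum of `x`), `p`,
#'   `method` ("exact" or "approximate"), `n` (per group).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  if (!length(x) || !length(y)) {
    eht_stop("eht_input_error", "both samples must be non-empty")
  }
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  exact <- min(length(x), length(y)) <= exact_max_n && !ties
  r <- rank(pooled)
  if (length(unique(pooled)) == 1) {
    ## fully tied data: the statistic is degenerate, no evidence of a shift
    return(structure(list(statistic = sum(r[seq_along(x)]), p = 1,
                          method = "approximate",
                          n = c(length(x), length(y))),
                     class = "test_result"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  structure(list(statistic = sum(r[seq_along(x)]),
                 p = min(1, wt$p.value),
                 method = if (exact) "exact" else "approximate",
                 n = c(length(x), length(y))), class = "test_result")
}

#' Pearson correlation with Student t-test
#'
#' Sample correlation R with two-sided p-value from
#' t = R sqrt((n - 2) / (1 - R^2)) on n - 2 degrees of freedom.
#' @param x,y numeric vectors, n >= 3.
#' @return List: `R`, `p`, `n`, `applicable` (FALSE with NA values when an
#'   input is constant).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    eht_stop("eht_input_error", "need paired samples with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(R = NA_real_, p = NA_real_, n = length(x), applicable = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x), applicable = TRUE)
}

#' Dixon's Q gate for a technical triplicate
#'
#' If the triplicate SD exceeds `sd_gate` (cycles), the most extreme value is
#' tested with Dixon's r10 ratio Q = gap / range and removed when
#' Q > `q_crit` (two-sided critical value 0.970 at n = 3, alpha = 0.05).
#' At most one value is ever removed.
#'
#' @param values numeric(3) Ct values.
#' @param sd_gate SD threshold that triggers the test.
#' @param q_crit critical value.
#' @return List: `values` (cleaned), `removed` (the removed value or NULL),
#'   `q` (the computed ratio or NA).
#' @export
dixon_filter <- function(values, sd_gate = 0.3, q_crit = 0.970) {
  if (length(values) != 3 || any(!is.finite(values))) {
    eht_stop("eht_input_error", "exactly 3 finite values required")
  }
  if (stats::sd(values) <= sd_gate) {
    return(list(values = values, removed = NULL, q = NA_real_))
  }
  s <- sort(values)
  rng <- s[3] - s[1]
  if (rng == 0) return(list(values = values, removed = NULL, q = NA_real_))
  gap_low <- s[2] - s[1]; gap_high <- s[3] - s[2]
  if (gap_high >= gap_low) { suspect <- s[3]; q <- gap_high / rng }
  else { suspect <- s[1]; q <- gap_low / rng }
  if (q > q_crit) {
    keep <- values[-match(suspect, values)]
    list(values = keep, removed = suspect, q = q)
  } else {
    list(values = values, removed = NULL, q = q)
  }
}

#' Delta-delta-Ct fold changes
#'
#' Per sample and gene, technical replicates are averaged after the Dixon
#' gate ([dixon_filter()], applied to triplicates only); then
#' dCt = Ct(gene) - Ct(reference); ddCt = dCt - mean dCt of the control
#' condition; fold change = 2^(-ddCt) (amplification efficiency fixed at 2).
#' `mode = "dct"` skips the second normalization and reports 2^(-dCt)
#' relative expression instead.
#'
#' @param table data.frame with columns `sample`, `condition`, `gene`, `ct`
#'   (a `replicate` column is optional).
#' @param reference_gene endogenous control gene (e.g. "ef1a").
#' @param control_condition condition used as the ddCt baseline.
#' @param mode "ddct" or "dct".
#' @param sd_gate Dixon SD gate, cycles.
#' @return data.frame: sample, condition, gene, delta_ct, delta_delta_ct,
#'   fold_change, n_removed (outliers gated per sample x gene). Samples
#'   lacking the reference gene are dropped with a warning.
#' @export
delta_delta_ct <- function(table, reference_gene, control_condition,
                           mode = c("ddct", "dct"), sd_gate = 0.3) {
  mode <- match.arg(mode)
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(table))) {
    eht_stop("eht_input_error",
             paste("table must have columns:", paste(need, collapse = ", ")))
  }
  if (!reference_gene %in% table$gene) {
    eht_stop("eht_input_error", "reference gene absent from the table")
  }
  if (mode == "ddct" && !control_condition %in% table$condition) {
    eht_stop("eht_input_error", "control condition absent from the table")
  }
  ## gated mean Ct per sample x gene
  key <- interaction(table$sample, table$gene, drop = TRUE)
  agg <- lapply(split(table, key), function(sub) {
    v <- sub$ct; removed <- 0L
    if (length(v) == 3) {
      dx <- dixon_filter(v, sd_gate = sd_gate)
      removed <- length(v) - length(dx$values)
      v <- dx$values
    }
    data.frame(sample = sub$sample[1], condition = sub$condition[1],
               gene = sub$gene[1], ct_mean = mean(v), n_removed = removed)
  })
  agg <- do.call(rbind, agg)
  ref <- agg[agg$gene == reference_gene, c("sample", "ct_mean")]
  names(ref)[2] <- "ct_ref"
  out <- merge(agg[agg$gene != reference_gene, ], ref, by = "sample",
               all.x = TRUE)
  if (any(is.na(out$ct_ref))) {
    eht_warn("eht_missing_reference",
             paste("samples without reference gene skipped:",
                   paste(unique(out$sample[is.na(out$ct_ref)]), collapse = ", ")))
    out <- out[!is.na(out$ct_ref), , drop = FALSE]
  }
  out$delta_ct <- out$ct_mean - out$ct_ref
  if (mode == "ddct") {
    base <- stats::aggregate(delta_ct ~ gene,
                             out[out$condition == control_condition, ], mean)
    names(base)[2] <- "baseline_dct"
    out <- merge(out, base, by = "gene", all.x = TRUE)
    out$delta_delta_ct <- out$delta_ct - out$baseline_dct
    out$fold_change <- 2^(-out$delta_delta_ct)
    out$baseline_dct <- NULL
  } else {
    out$delta_delta_ct <- NA_real_
    out$fold_change <- 2^(-out$delta_ct)
  }
  out[order(out$gene, out$condition, out$sample),
      c("sample", "condition", "gene", "delta_ct", "delta_delta_ct",
        "fold_change", "n_removed")]
}
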