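#' Combine label-swapped SILAC replicate ratios
#'
#' Each replicate's heavy/light ratio is re-oriented so the functional bait
#' is in the numerator (inverted where the labels were swapped), and the
#' combined value per protein is the mean of the log2 re-oriented ratios
#' over the replicates in which the protein was detected (the geometric
#' mean of ratios, symmetric between enrichment and depletion). Any
#' multiplicative label bias applied antisymmetrically to swapped replicate
#' pairs cancels exactly. The plain arithmetic mean of re-oriented ratios
#' is available via `mean_type = "arithmetic"`.
#'
#' @param table data.frame with columns `protein`, `ratio` (heavy/light,
#'   > 0), `swapped` (logical: TRUE when the functional bait carried the
#'   light label) and optionally `detected` (logical, default TRUE).
#' @param mean_type `"log2"` (default) or `"arithmetic"`.
#' @return data.frame (`protein`, `combined_log2`, `n_reps`), one row per
#'   protein with >= 1 detected replicate; proteins never detected are
#'   dropped with a message.
#' @export
combine_label_swap <- function(table, mean_type = c("log2", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  stopifnot(all(c("protein", "ratio", "swapped") %in% names(table)))
  det <- if (is.null(table$detected)) rep(TRUE, nrow(table)) else table$detected
  tab <- table[det, , drop = FALSE]
  if (any(tab$ratio <= 0)) stop("detected ratios must be strictly positive")
  dropped <- setdiff(unique(table$protein), unique(tab$protein))
  if (length(dropped))
    message(length(dropped), " protein(s) with no detected replicate excluded")
  oriented <- ifelse(tab$swapped, 1 / tab$ratio, tab$ratio)
  sp <- split(oriented, tab$protein)
  combined <- if (mean_type == "log2") {
    vapply(sp, function(r) mean(log2(r)), numeric(1))
  } else {
    vapply(sp, function(r) log2(mean(r)), numeric(1))
  }
  data.frame(protein = names(sp), combined_log2 = unname(combined),
             n_reps = unname(lengths(sp)), stringsAsFactors = FALSE)
}

#' Upper-tail empirical P value for a protein's combined ratio
#'
#' `(1 + #{proteins with combined value >= target's}) / (n + 1)`; the
#' target itself is included in the count (ties count as >=), so the
#' smallest attainable value is `2 / (n + 1)`.
#'
#' @param combined numeric vector of combined log2 ratios (named, or use
#'   `target` as an index).
#' @param target protein name or index.
#' @return empirical P in (0, 1].
#' @export
silac_empirical_pvalue <- function(combined, target) {
  if (length(combined) < 2) stop("need >= 2 proteins")
  v <- combined[[target]]
  (1 + sum(combined >= v)) / (length(combined) + 1)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment; output order matches
#' input order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Score a label-swap SILAC screen
#'
#' Combines replicate ratios per protein, assigns every protein an
#' upper-tail empirical P value against the whole screen, and converts
#' P values to Benjamini-Hochberg q-values. Proteins flagged `promiscuous`
#' in the input (high recovery with a control bait) are annotated, not
#' removed.
#'
#' @inheritParams combine_label_swap
#' @return data.frame (`protein`, `combined_log2`, `n_reps`,
#'   `empirical_p`, `q_value`, `promiscuous`), sorted by descending
#'   combined ratio.
#' @export
silac_screen <- function(table, mean_type = "log2") {
  res <- combine_label_swap(table, mean_type)
  n <- nrow(res)
  res$empirical_p <- vapply(seq_len(n), function(i)
    silac_empirical_pvalue(res$combined_log2, i), numeric(1))
  res$q_value <- bh_fdr(res$empirical_p)
  prom <- table$promiscuous
  if (!is.null(prom)) {
    flag <- tapply(prom, table$protein, any)
    res$promiscuous <- as.logical(flag[res$protein])
  } else {
    res$promiscuous <- FALSE
  }
  res[order(-res$combined_log2, res$protein), ]
}
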