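#' Per-gene two-group difference with Student t test
#'
#' Computes, per gene, the difference of group means of log2 expression
#' signals (A minus B) and a two-tailed unpaired t-test P value, by default
#' the equal-variance Student form with nA + nB - 2 degrees of freedom
#' (Welch with `var_equal = FALSE`). Vectorised over genes. When both
#' groups have zero variance the P value is 1 for equal means and 0
#' otherwise.
#'
#' @param mat numeric matrix, genes x samples (rownames = gene ids).
#' @param groups character vector mapping each column to a group.
#' @param group_a,group_b group labels to compare.
#' @param var_equal pool variances (default TRUE).
#' @return data.frame (`gene`, `delta`, `t`, `p`).
#' @export
group_difference_test <- function(mat, groups, group_a, group_b,
                                  var_equal = TRUE) {
  stopifnot(length(groups) == ncol(mat))
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 replicates")
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(mat[, ia, drop = FALSE])
  mb <- rowMeans(mat[, ib, drop = FALSE])
  va <- apply(mat[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(mat[, ib, drop = FALSE], 1, stats::var)
  delta <- ma - mb
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    sedelta <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    sedelta <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- delta / sedelta
  p <- 2 * pt(-abs(tstat), df)
  zerovar <- sedelta == 0
  tstat[zerovar] <- ifelse(delta[zerovar] == 0, 0, Inf * sign(delta[zerovar]))
  p[zerovar] <- ifelse(delta[zerovar] == 0, 1, 0)
  ids <- if (!is.null(rownames(mat))) rownames(mat) else
    as.character(seq_len(nrow(mat)))
  data.frame(gene = ids, delta = unname(delta), t = unname(tstat),
             p = unname(p), stringsAsFactors = FALSE)
}

# distance (bp) from each TSS to the nearest qualifying peak anchor
.nearest_peak_distance <- function(tss, peaks, anchor = c("summit", "edge")) {
  anchor <- match.arg(anchor)
  if (!length(peaks))
    return(rep(Inf, length(tss)))
  pk <- if (anchor == "summit") .summits(peaks) else peaks
  d <- rep(Inf, length(tss))
  hits <- GenomicRanges::distanceToNearest(tss, pk, ignore.strand = TRUE)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Classify p65 target promoters by TA3 responsiveness
#'
#' Rule-based classification from replicate expression signals and
#' high-confidence peak calls. With deltas d_TA3 = mean("+p65 TA3") -
#' mean("p65ko") and d_p65 = mean("+p65") - mean("p65ko"):
#' TA3-responsive requires d_TA3 >= 0.5 and d_p65 >= 0.4;
#' TA3-nonresponsive requires d_p65 >= 0.5 and d_TA3 < 0.4; both
#' additionally require a high-confidence peak (score, -10log10 P,
#' strictly greater than 50) within 2 kb of the TSS (summit distance by
#' default; `anchor = "edge"` for edge distance). Direct targets are the
#' union of the two classes.
#'
#' @param mat genes x samples log2 signal matrix.
#' @param groups column group labels; must contain `"p65ko"`, `"p65"`,
#'   `"p65_TA3"`.
#' @param peaks `GRanges` of p65 peaks with numeric `score` = -10log10(P).
#' @param tss `GRanges` of width-1 TSS positions named by gene id.
#' @param max_distance bp from TSS to nearest qualifying peak (default
#'   2000).
#' @param min_score high-confidence peak score threshold (default 50,
#'   strict).
#' @param anchor `"summit"` (default) or `"edge"` peak distance.
#' @return data.frame (`gene`, `delta_ta3`, `delta_p65`, `peak_distance`,
#'   `class` in {TA3_responsive, TA3_nonresponsive, none}, `p65_direct`).
#' @export
classify_p65_targets <- function(mat, groups, peaks, tss,
                                 max_distance = 2000, min_score = 50,
                                 anchor = "summit") {
  d_ta3 <- group_difference_test(mat, groups, "p65_TA3", "p65ko")$delta
  d_p65 <- group_difference_test(mat, groups, "p65", "p65ko")$delta
  genes <- rownames(mat)
  if (is.null(peaks$score)) stop("peaks must carry a -10log10(P) score")
  hi <- peaks[peaks$score > min_score]
  tss_idx <- match(genes, names(tss))
  dist <- rep(NA_real_, length(genes))
  has_tss <- !is.na(tss_idx)
  dist[has_tss] <- .nearest_peak_distance(tss[tss_idx[has_tss]], hi, anchor)
  near <- !is.na(dist) & dist <= max_distance
  cls <- rep("none", length(genes))
  cls[has_tss & near & d_ta3 >= 0.5 & d_p65 >= 0.4] <- "TA3_responsive"
  cls[has_tss & near & d_p65 >= 0.5 & d_ta3 < 0.4] <- "TA3_nonresponsive"
  cls[!has_tss] <- "unclassified_no_tss"
  data.frame(gene = genes, delta_ta3 = d_ta3, delta_p65 = d_p65,
             peak_distance = dist, class = cls,
             p65_direct = cls %in% c("TA3_responsive", "TA3_nonresponsive"),
             stringsAsFactors = FALSE)
}

#' Classify Zbtb7a-regulated expression
#'
#' With delta = mean("+p65 TA3") - mean("shZbtb7a + p65 TA3") and the
#' two-group t-test P between those groups: up-regulation by Zbtb7a is
#' called strong ("+++") at delta >= 0.5 and weak ("+") at delta >= 0.2,
#' both gated at P < 0.05; down-regulation mirrors the thresholds
#' ("---" at delta <= -0.5, "-" at delta <= -0.2). Strong calls are nested
#' within weak calls.
#'
#' @param mat genes x samples log2 signal matrix.
#' @param groups column group labels; must contain `"p65_TA3"` and
#'   `"shZbtb7a_p65_TA3"`.
#' @param var_equal passed to [group_difference_test()].
#' @return data.frame (`gene`, `delta`, `p`, `up_strong`, `up_weak`,
#'   `down_strong`, `down_weak`, `label`), `label` the strongest symbol or
#'   `"none"`.
#' @export
classify_zbtb7a_regulation <- function(mat, groups, var_equal = TRUE) {
  res <- group_difference_test(mat, groups, "p65_TA3", "shZbtb7a_p65_TA3",
                               var_equal = var_equal)
  sig <- res$p < 0.05
  out <- data.frame(gene = res$gene, delta = res$delta, p = res$p,
                    up_strong = sig & res$delta >= 0.5,
                    up_weak = sig & res$delta >= 0.2,
                    down_strong = sig & res$delta <= -0.5,
                    down_weak = sig & res$delta <= -0.2,
                    stringsAsFactors = FALSE)
  out$label <- with(out, ifelse(up_strong, "+++",
                         ifelse(up_weak, "+",
                         ifelse(down_strong, "---",
                         ifelse(down_weak, "-", "none")))))
  out
}

#' Top-N factor-dependent target genes
#'
#' High-confidence targets of a manipulated transcription factor: the `n`
#' genes with the greatest absolute factor-dependent expression change
#' among those significant at P < 0.05 (two-tailed t test between groups).
#' Ties in |delta| are broken by gene id for determinism; if fewer than `n`
#' genes are significant, all are returned with a warning.
#'
#' @inheritParams group_difference_test
#' @param n list size (default 200).
#' @param alpha significance gate (default 0.05).
#' @return character vector of gene ids, ranked.
#' @export
top_n_targets <- function(mat, groups, group_a, group_b, n = 200,
                          alpha = 0.05, var_equal = TRUE) {
  res <- group_difference_test(mat, groups, group_a, group_b, var_equal)
  sig <- res[res$p < alpha, ]
  sig <- sig[order(-abs(sig$delta), sig$gene), ]
  if (nrow(sig) < n) {
    if (nrow(sig) > 0 || n > 0)
      warning("only ", nrow(sig), " significant genes for top-", n, " list")
    return(sig$gene)
  }
  sig$gene[seq_len(n)]
}
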