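#' Simulation configuration
#'
#' One declarative configuration drives every generator. Defaults define a
#' desk-scale study: a 2 x 2 Mb genome, ~500 promoters, a base cleavage
#' rate of 0.05 cuts/bp scaled tenfold inside open chromatin, log-normal
#' (sdlog 0.3) multiplicative hexamer cleavage bias, a 10-bp planted motif
#' whose occupancy drops from 0.8 to 0.2 on factor knockdown, three
#' replicates per expression group with additive normal noise (sd 0.1),
#' and a 700-protein label-swap SILAC screen with five true binders at
#' log2 ratio 2 and replicate noise sd 0.5.
#'
#' @param seed integer master seed; every generator is a pure function of
#'   (config, seed).
#' @param ... overrides for any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
    n_promoters = 500L,
    promoter_halfwidth = 1000L,   # promoter interval = TSS +/- 1 kb
    n_enhancers = 100L,
    frac_bound = 0.4,             # promoters bound by the factor
    frac_dependent = 0.5,         # bound promoters with dependent access
    base_rate = 0.05,             # cuts per bp outside open chromatin
    access_bump = 10,             # accessibility factor in open windows
    bump_halfwidth = 600L,
    dependent_knockdown_factor = 0.4,  # bump retained on knockdown
    hexamer_bias_sd = 0.3,        # sdlog of log-normal per-hexamer factor
    motif_consensus = "GGGACCCCTC",
    motif_offset = -300L,         # planted motif start relative to TSS
    occupancy = c(control = 0.8, knockdown = 0.2),
    protection_depth = 0.5,
    protection_halfwidth = 5L,    # protected central window = 10 bp
    peak_width = 400L,
    n_peaks = 200L,
    rho = 0.5,                    # peak-pair co-occurrence probability
    n_genes = 1000L,
    n_ta3_responsive = 60L,
    n_ta3_nonresponsive = 40L,
    n_zbtb7a_up_strong = 40L,
    n_zbtb7a_up_weak = 40L,
    n_zbtb7a_down_strong = 40L,
    n_zbtb7a_down_weak = 40L,
    expr_noise_sd = 0.1,
    n_replicates = 3L,
    silac_n_proteins = 700L,
    silac_n_binders = 5L,
    silac_binder_log2 = 2,
    silac_label_bias = 2,
    silac_noise_sd = 0.5,
    silac_n_reps = 4L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with planted regulatory annotation
#'
#' Uniform-random sequence with evenly spaced, randomly stranded promoter
#' TSSs, interleaved enhancer midpoints, and motif consensus occurrences
#' planted upstream of every bound promoter's TSS (reverse-complemented on
#' minus-strand placements). DHS regions are the open windows around
#' promoter TSSs and enhancer midpoints. A seeded per-hexamer cleavage
#' bias table is drawn once here and reused by [simulate_cut_track()].
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome`: `genome` (DNAStringSet), `sizes`,
#'   `tss` (width-1 stranded, named, with `bound` / `dependent` truth),
#'   `promoters`, `enhancers`, `dhs`, `motifs`, `hexamer_factors`,
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  sizes <- config$chrom_lengths
  seqs <- lapply(sizes, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  # spread promoters over chromosomes proportionally to length
  n_prom <- config$n_promoters
  prop <- sizes / sum(sizes)
  n_by <- round(n_prom * prop)
  n_by[length(n_by)] <- n_prom - sum(n_by[-length(n_by)])
  motif <- toupper(config$motif_consensus)
  mw <- nchar(motif)
  si <- .seqinfo(sizes)
  margin <- 5000L
  tss_list <- list(); enh_list <- list()
  for (ci in seq_along(sizes)) {
    L <- sizes[[ci]]
    n <- n_by[[ci]]
    pos <- round(seq(margin, L - margin, length.out = n))
    str <- sample(c("+", "-"), n, replace = TRUE)
    tss_list[[ci]] <- GenomicRanges::GRanges(names(sizes)[ci],
                                             IRanges::IRanges(pos, width = 1),
                                             strand = str, seqinfo = si)
    ne <- round(config$n_enhancers * prop[[ci]])
    if (ne > 0) {
      epos <- round(pos[seq_len(min(ne, n - 1))] +
                      diff(pos)[seq_len(min(ne, n - 1))] / 2)
      enh_list[[ci]] <- GenomicRanges::GRanges(names(sizes)[ci],
                                               IRanges::IRanges(epos, width = 1),
                                               seqinfo = si)
    }
  }
  tss <- do.call(c, tss_list)
  names(tss) <- sprintf("gene%04d", seq_along(tss))
  enhancers <- if (length(enh_list)) do.call(c, enh_list) else
    GenomicRanges::GRanges(seqinfo = si)
  n_bound <- round(config$frac_bound * length(tss))
  bound <- seq_along(tss) %in% sample(seq_along(tss), n_bound)
  dep <- rep(FALSE, length(tss))
  dep[bound][seq_len(round(config$frac_dependent * n_bound))] <- TRUE
  tss$bound <- bound
  tss$dependent <- dep
  # plant one motif instance upstream of each bound promoter TSS
  mstart <- GenomicRanges::start(tss)[bound] + config$motif_offset
  mstr <- sample(c("+", "-"), sum(bound), replace = TRUE)
  mchrom <- as.character(GenomicRanges::seqnames(tss))[bound]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  for (i in seq_along(mstart)) {
    s <- mstart[i]
    word <- if (mstr[i] == "-") rc else motif
    seqs[[mchrom[i]]][s:(s + mw - 1)] <- strsplit(word, "")[[1]]
  }
  motifs <- GenomicRanges::GRanges(mchrom,
                                   IRanges::IRanges(mstart, width = mw),
                                   strand = mstr, seqinfo = si)
  motifs$gene <- names(tss)[bound]
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(sizes)
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(GenomicRanges::start(tss) - config$promoter_halfwidth,
                     GenomicRanges::start(tss) + config$promoter_halfwidth - 1L),
    strand = GenomicRanges::strand(tss))
  names(promoters) <- names(tss)
  open_anchors <- c(GenomicRanges::granges(tss), enhancers)
  dhs <- GenomicRanges::reduce(GenomicRanges::GRanges(
    GenomicRanges::seqnames(open_anchors),
    IRanges::IRanges(GenomicRanges::start(open_anchors) - config$bump_halfwidth,
                     GenomicRanges::start(open_anchors) + config$bump_halfwidth)))
  hex <- rlnorm(4096, meanlog = 0, sdlog = config$hexamer_bias_sd)
  hex <- hex / mean(hex)
  structure(list(genome = genome, sizes = sizes, tss = tss,
                 promoters = promoters, enhancers = enhancers, dhs = dhs,
                 motifs = motifs, hexamer_factors = hex, config = config),
            class = "sim_genome")
}

#' Simulate a DNase cut-site track
#'
#' Per-base Poisson cut counts with rate = base rate x hexamer-context
#' bias x accessibility x occupancy protection. Accessibility multiplies
#' the base rate by `access_bump` within the open window around each
#' promoter TSS and enhancer midpoint; on knockdown the bump at dependent
#' promoters is reduced to `dependent_knockdown_factor` of its value. At
#' each motif instance the central `2 * protection_halfwidth` bases are
#' attenuated by `(1 - occupancy * protection_depth)`, occupancy per
#' condition.
#'
#' @param sim a [simulate_genome()] result.
#' @param condition `"control"` or `"knockdown"`.
#' @param bias apply the hexamer cleavage bias (default TRUE).
#' @param seed RNG seed for the Poisson draws (default derives from the
#'   config seed and condition).
#' @param occupancy optional override of the condition's motif occupancy
#'   (in \[0, 1\]), e.g. for occupancy-titration experiments.
#' @return a [cut_track()] at cut-site resolution.
#' @export
simulate_cut_track <- function(sim, condition = c("control", "knockdown"),
                               bias = TRUE, seed = NULL, occupancy = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$config
  if (is.null(seed))
    seed <- cfg$seed + 1000L + (condition == "knockdown")
  set.seed(seed)
  occ <- if (is.null(occupancy)) cfg$occupancy[[condition]] else occupancy
  stopifnot(occ >= 0, occ <= 1)
  cov <- list()
  for (chrom in names(sim$sizes)) {
    L <- sim$sizes[[chrom]]
    rate <- rep(cfg$base_rate, L)
    if (bias) {
      codes <- .hexamer_codes(.base_codes(sim$genome[[chrom]]))
      fac <- rep(1, L)
      ok <- !is.na(codes)
      fac[ok] <- sim$hexamer_factors[codes[ok] + 1]
      rate <- rate * fac
    }
    sel <- as.character(GenomicRanges::seqnames(sim$tss)) == chrom
    anchors <- GenomicRanges::start(sim$tss)[sel]
    bump <- rep(cfg$access_bump, sum(sel))
    if (condition == "knockdown") {
      depfac <- ifelse(sim$tss$dependent[sel],
                       cfg$dependent_knockdown_factor, 1)
      bump <- 1 + (bump - 1) * depfac
    }
    esel <- as.character(GenomicRanges::seqnames(sim$enhancers)) == chrom
    anchors <- c(anchors, GenomicRanges::start(sim$enhancers)[esel])
    bump <- c(bump, rep(cfg$access_bump, sum(esel)))
    for (i in seq_along(anchors)) {
      idx <- max(1, anchors[i] - cfg$bump_halfwidth):
        min(L, anchors[i] + cfg$bump_halfwidth)
      rate[idx] <- rate[idx] * bump[i]
    }
    msel <- as.character(GenomicRanges::seqnames(sim$motifs)) == chrom
    if (any(msel) && occ > 0) {
      ms <- GenomicRanges::start(sim$motifs)[msel]
      me <- GenomicRanges::end(sim$motifs)[msel]
      centre <- floor((ms + me) / 2)
      for (cm in centre) {
        idx <- max(1, cm - cfg$protection_halfwidth + 1):
          min(L, cm + cfg$protection_halfwidth)
        rate[idx] <- rate[idx] * (1 - occ * cfg$protection_depth)
      }
    }
    cov[[chrom]] <- rpois(L, rate)
  }
  cut_track(cov, fragment_length = 1L)
}

#' Simulate a pair of peak sets with controlled co-occurrence
#'
#' Set A is placed uniformly; each B peak is co-located with a randomly
#' chosen A peak (same centre, jittered by less than half a width, so the
#' pair overlaps) with probability `rho`, else placed uniformly. The
#' realised co-location count is returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param rho co-occurrence probability (default from config).
#' @param seed RNG seed (default config seed + 2000).
#' @return list: `a`, `b` (`GRanges`), `n_colocated`, `sizes`.
#' @export
simulate_peak_pair <- function(config = sim_config(), rho = NULL,
                               seed = NULL) {
  if (is.null(rho)) rho <- config$rho
  stopifnot(rho >= 0, rho <= 1)
  if (is.null(seed)) seed <- config$seed + 2000L
  set.seed(seed)
  sizes <- config$chrom_lengths
  w <- config$peak_width
  n <- config$n_peaks
  si <- .seqinfo(sizes)
  place <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE,
                    prob = sizes / sum(sizes))
    start <- floor(runif(n, 1, sizes[chrom] - w))
    list(chrom = chrom, start = start)
  }
  a <- place(n)
  b <- place(n)
  co <- runif(n) < rho
  if (any(co)) {
    src <- sample(n, sum(co), replace = TRUE)
    jit <- round(runif(sum(co), -w / 2 + 1, w / 2 - 1))
    b$chrom[co] <- a$chrom[src]
    b$start[co] <- pmax(1, a$start[src] + jit)
  }
  as_gr <- function(p) sort(GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(p$start, width = w), seqinfo = si))
  list(a = as_gr(a), b = as_gr(b), n_colocated = sum(co), sizes = sizes)
}

#' Simulate a replicated expression study with planted target classes
#'
#' Four experimental groups (`p65ko`, `p65`, `p65_TA3`,
#' `shZbtb7a_p65_TA3`) with `n_replicates` replicates each; per-gene
#' signal = baseline + group effect + N(0, `expr_noise_sd`). Planted
#' classes: TA3-responsive genes (effects 0.6 over p65ko in the TA3 group
#' and 0.5 in the p65 group, with a high-confidence peak planted within
#' 2 kb of the TSS), TA3-nonresponsive genes (0.6 in p65, 0.2 in TA3, peak
#' planted), and Zbtb7a-regulated classes with TA3-vs-knockdown deltas of
#' +/-0.6 (strong) and +/-0.3 (weak). Gene TSSs live on one synthetic
#' chromosome at 5-kb spacing.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default config seed + 3000).
#' @return list: `mat` (genes x samples), `groups`, `tss`, `peaks`,
#'   `truth` (data.frame of planted classes), `sizes`.
#' @export
simulate_expression <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 3000L
  set.seed(seed)
  cfg <- config
  n <- cfg$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  idx <- seq_len(n)
  ta3r <- idx <= cfg$n_ta3_responsive
  ta3n <- !ta3r & idx <= cfg$n_ta3_responsive + cfg$n_ta3_nonresponsive
  z0 <- cfg$n_ta3_responsive + cfg$n_ta3_nonresponsive
  zus <- !ta3r & !ta3n & idx <= z0 + cfg$n_zbtb7a_up_strong
  zuw <- idx > z0 + cfg$n_zbtb7a_up_strong &
    idx <= z0 + cfg$n_zbtb7a_up_strong + cfg$n_zbtb7a_up_weak
  z1 <- z0 + cfg$n_zbtb7a_up_strong + cfg$n_zbtb7a_up_weak
  zds <- idx > z1 & idx <= z1 + cfg$n_zbtb7a_down_strong
  zdw <- idx > z1 + cfg$n_zbtb7a_down_strong &
    idx <= z1 + cfg$n_zbtb7a_down_strong + cfg$n_zbtb7a_down_weak
  eff_p65 <- ifelse(ta3r, 0.5, ifelse(ta3n, 0.6, 0))
  eff_ta3 <- ifelse(ta3r, 0.6, ifelse(ta3n, 0.2, 0))
  # Zbtb7a knockdown delta relative to the TA3 group
  zdelta <- ifelse(zus, 0.6, ifelse(zuw, 0.3,
             ifelse(zds, -0.6, ifelse(zdw, -0.3, 0))))
  zdelta[ta3r] <- 0.6  # TA3-responsive genes also lose expression on knockdown
  groups <- rep(c("p65ko", "p65", "p65_TA3", "shZbtb7a_p65_TA3"),
                each = cfg$n_replicates)
  base <- rnorm(n, mean = 7, sd = 1)
  mu <- cbind(p65ko = base, p65 = base + eff_p65, p65_TA3 = base + eff_ta3,
              shZbtb7a_p65_TA3 = base + eff_ta3 - zdelta)
  mat <- matrix(NA_real_, n, length(groups),
                dimnames = list(genes, paste0(groups, "_r",
                                              rep(seq_len(cfg$n_replicates),
                                                  times = 4))))
  for (j in seq_along(groups))
    mat[, j] <- mu[, groups[j]] + rnorm(n, 0, cfg$expr_noise_sd)
  spacing <- 5000L
  sizes <- c(chrE = (n + 2L) * spacing)
  tss <- GenomicRanges::GRanges("chrE",
                                IRanges::IRanges(idx * spacing, width = 1),
                                strand = "+")
  names(tss) <- genes
  has_peak <- ta3r | ta3n
  pk_off <- round(runif(sum(has_peak), -1500, 1500))
  peaks <- GenomicRanges::GRanges(
    rep("chrE", sum(has_peak)),
    IRanges::IRanges(pmax(1, idx[has_peak] * spacing + pk_off - 100L),
                     width = 200L))
  peaks$score <- rep(80, sum(has_peak))
  truth <- data.frame(gene = genes,
                      class = ifelse(ta3r, "TA3_responsive",
                               ifelse(ta3n, "TA3_nonresponsive", "none")),
                      zbtb7a_label = ifelse(zus | ta3r, "+++",
                                     ifelse(zuw, "+",
                                     ifelse(zds, "---",
                                     ifelse(zdw, "-", "none")))),
                      stringsAsFactors = FALSE)
  list(mat = mat, groups = groups, tss = tss, peaks = peaks, truth = truth,
       sizes = sizes)
}

#' Simulate a label-swap SILAC pull-down screen
#'
#' True binders carry log2 ratio `silac_binder_log2`; all other proteins
#' are null. Each replicate observes the true log2 ratio with sign set by
#' its label orientation, plus the multiplicative heavy-label bias
#' `silac_label_bias` and N(0, `silac_noise_sd`) noise; half the
#' replicates are label-swapped.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default config seed + 4000).
#' @return list: `table` (long data.frame: protein, replicate, ratio,
#'   swapped, detected), `truth` (data.frame: protein, binder).
#' @export
simulate_silac <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 4000L
  set.seed(seed)
  cfg <- config
  prot <- sprintf("prot%04d", seq_len(cfg$silac_n_proteins))
  truth <- rep(FALSE, cfg$silac_n_proteins)
  truth[sample(cfg$silac_n_proteins, cfg$silac_n_binders)] <- TRUE
  t_log2 <- ifelse(truth, cfg$silac_binder_log2, 0)
  reps <- seq_len(cfg$silac_n_reps)
  swapped <- reps %% 2 == 0
  rows <- lapply(reps, function(r) {
    sign <- if (swapped[r]) -1 else 1
    obs <- sign * t_log2 + log2(cfg$silac_label_bias) +
      rnorm(cfg$silac_n_proteins, 0, cfg$silac_noise_sd)
    data.frame(protein = prot, replicate = r, ratio = 2^obs,
               swapped = swapped[r], detected = TRUE,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       truth = data.frame(protein = prot, binder = truth,
                          stringsAsFactors = FALSE))
}

#' Null accessibility deltas for empirical-threshold calibration
#'
#' Draws per-promoter accessibility differences from one common normal
#' distribution, the null situation in which factor-bound and
#' factor-negative promoters are exchangeable.
#'
#' @param n number of promoters.
#' @param sd delta standard deviation (cuts/bp).
#' @param seed RNG seed.
#' @return data.frame (`region`, `delta`) suitable for
#'   [call_differential_accessibility()].
#' @export
simulate_null_deltas <- function(n, sd = 0.2, seed = 1L) {
  set.seed(seed)
  data.frame(region = sprintf("prom%05d", seq_len(n)),
             delta = rnorm(n, 0, sd), stringsAsFactors = FALSE)
}
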