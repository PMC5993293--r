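#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth.
# A 2 x 2 Mb genome with ~500 promoters, planted factor motifs upstream of
# bound promoters, hexamer cleavage bias, and DNase cut-site tracks for a
# control and a factor-knockdown condition. Writes standard-format inputs
# for the later stages under results/data/.

suppressMessages(library(accessilate))

out <- "results/data"          # small annotation + truth tables
bulk <- "scratch/data"         # genome sequence and per-base tracks
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(bulk, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260930)
sim <- simulate_genome(cfg)
message("genome: ", sum(sim$sizes) / 1e6, " Mb, ", length(sim$tss),
        " promoters (", sum(sim$tss$bound), " bound, ",
        sum(sim$tss$dependent), " accessibility-dependent), ",
        length(sim$motifs), " planted motif instances")

Biostrings::writeXStringSet(sim$genome, file.path(bulk, "genome.fa"))
write_chrom_sizes(sim$sizes, file.path(out, "genome.chrom.sizes"))
rtracklayer::export(sim$promoters, file.path(out, "promoters.bed"))
rtracklayer::export(sim$dhs, file.path(out, "dhs_regions.bed"))
rtracklayer::export(sim$motifs, file.path(out, "motif_instances.bed"))

for (cond in c("control", "knockdown")) {
  trk <- simulate_cut_track(sim, cond)
  write_bedgraph(trk, file.path(bulk, paste0("cuts_", cond, ".bedGraph")))
  message(cond, " track: ", round(track_total(trk) / 1e3), "k cut sites")
}

truth <- data.frame(gene = names(sim$tss),
                    bound = sim$tss$bound,
                    dependent = sim$tss$dependent)
jsonlite::write_json(truth, file.path(out, "ground_truth.json"))
message("annotation written under ", out, "; sequence and tracks under ", bulk)
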