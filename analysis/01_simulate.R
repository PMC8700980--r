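#!/usr/bin/env Rscript
# Generate the synthetic study: genome, annotations, motifs with planted
# promoter sites, reference regulatory network with edges broken in ASD, and
# NB expression counts for iPSC/NPC/neuron x normal/ASD.

library(regcascade)

dir.create("results", showWarnings = FALSE)
cfg <- default_config()
design <- sim_design()
study <- stage_simulate("results", cfg, design)

cat(sprintf("Simulated %d genes x %d samples over %d cell types.\n",
            nrow(study$counts), ncol(study$counts),
            length(unique(study$sheet$cell_type))))
cat(sprintf("Planted: %d reference edges, %d motif sites, %d enhancer links, %d edges broken in ASD.\n",
            nrow(study$network), nrow(study$truth$motif_sites),
            nrow(study$truth$enhancer_links), nrow(study$truth$broken_edges)))
cat("Outputs: results/{genome.fa, genes.bed, enhancers.bed, network.tsv,\n")
cat("         motifs.jaspar, counts.tsv, samples.tsv, pathways.gmt, truth.json}\n")
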