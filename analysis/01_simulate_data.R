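#!/usr/bin/env Rscript
# Simulate the study inputs: a coordinate database of ~115 experiments
# with planted seed-linked co-activation and label enrichments, and a
# small resting-state sample with matching planted networks. The foci
# database is serialized in the Sleuth-style text dialect; the manifests
# record every planted assignment for later scoring.

source("analysis/common.R")

g <- study_grid()
message("grid: ", paste(g$shape, collapse = "x"), " voxels, ",
        n_voxels(g), " in mask")

gen <- generate_database(db_spec(), g)
save_sleuth_database(gen$db, file.path(RESULTS, "foci_database.txt"))
message("  wrote ", file.path(RESULTS, "foci_database.txt"),
        " (", length(gen$db), " experiments, ", n_foci(gen$db), " foci)")
write_tsv(gen$manifest, "foci_manifest.tsv")

rs <- generate_rs_dataset(rs_spec(), g)
message(sprintf("resting-state sample: %d participants x %d volumes (TR %.1f s)",
                length(rs$datasets), dim(rs$datasets[[1]]$data)[4],
                rs$datasets[[1]]$tr_seconds))
write_tsv(rs$manifest, "rs_manifest.tsv")

# quick sanity summary of the planted structure
sel <- suppressWarnings(
  select_experiments_by_seed(gen$db, study_seeds(g)$A))
message(sprintf("experiments with a focus in seed A: %d (planted: %d)",
                length(sel), sum(gen$manifest$hit_seedA)))
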