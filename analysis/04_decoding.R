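#!/usr/bin/env Rscript
# Functional decoding of the two seeds against the task labels of the
# simulated database: forward (binomial) and reverse (chi-square + Bayes)
# inference per seed, the FDR-corrected seed contrast with main-effect
# masking, and the both-seed conjunction.

source("analysis/common.R")

g <- study_grid()
db <- load_sleuth_database(file.path(RESULTS, "foci_database.txt"), g)
seeds <- study_seeds(g)

tab_a <- decode_seed(db, seeds$A)
tab_b <- decode_seed(db, seeds$B)
write_tsv(tab_a, "decoding_A.tsv")
write_tsv(tab_b, "decoding_B.tsv")
message("robust labels seed A: ",
        paste(tab_a$label[tab_a$robust], collapse = ", "))
message("robust labels seed B: ",
        paste(tab_b$label[tab_b$robust], collapse = ", "))

ct <- contrast_decoding(db, seeds$A, seeds$B, decode_a = tab_a,
                        decode_b = tab_b)
write_tsv(ct$a, "decoding_contrast_A.tsv")
write_tsv(ct$b, "decoding_contrast_B.tsv")
message("contrast labels A: ",
        paste(ct$a$label[ct$a$reported], collapse = ", "))
message("contrast labels B: ",
        paste(ct$b$label[ct$b$reported], collapse = ", "))

conj <- conjunction_decoding(tab_a, tab_b)
message("labels robust for both seeds: ",
        if (length(conj)) paste(conj, collapse = ", ") else "(none)")
writeLines(conj, file.path(RESULTS, "decoding_conjunction.txt"))
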