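#!/usr/bin/env Rscript
# Generate the synthetic study data: for each strain state (reference
# genome-reduced strain "ref" and its regulator-repaired derivative
# "abrb"), a labeling experiment (measured fragment MIDs), a culture time
# course, and one shared expression table for the strain contrast.
# Everything downstream (02-04) reads these files.

suppressPackageStartupMessages(library(emuflux))

out <- file.path("results", "simulated")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20220524

net <- make_network("TOY_CMP")
writeLines(serialize_network(net), file.path(out, "network_toy_cmp.txt"))
write_fragment_library(toy_fragment_library("TOY_CMP"),
                       file.path(out, "fragments.yml"))

manifest <- list(seed = seed, preset = "TOY_CMP", mid_sd = 0.003,
                 tc_noise_sd = 0.02, strains = list())
for (strain in c("ref", "abrb")) {
  sc <- make_scenario("TOY_CMP", strain, seed = seed + match(strain, c("ref", "abrb")))
  d <- simulate_measurements(sc)
  write_mid_table(d$mids, file.path(out, sprintf("mids_%s.csv", strain)))
  utils::write.csv(d$time_course,
                   file.path(out, sprintf("time_course_%s.csv", strain)),
                   row.names = FALSE)
  yaml::write_yaml(sc$labeling, file.path(out, "labeling.yml"))
  manifest$strains[[strain]] <- list(seed = sc$seed,
                                     truth_net = as.list(sc$truth$net),
                                     truth_exch = as.list(sc$truth$exch),
                                     mu = sc$truth$mu)
  cat(sprintf("[%s] %d fragments, %d time points, true glycolytic flux %.3f\n",
              strain, length(d$mids), nrow(d$time_course),
              sc$truth$net[["emp"]]))
}

sc_expr <- make_scenario("TOY_CMP", "ref", seed = seed + 10)
tb <- simulate_expression(sc_expr)
sig <- data.frame(gene_id = rownames(tb$signals), tb$signals,
                  check.names = FALSE)
utils::write.table(sig, file.path(out, "expression.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
sets <- do.call(rbind, lapply(names(tb$sets), function(s)
  data.frame(gene_id = tb$sets[[s]], set_id = s)))
utils::write.table(sets, file.path(out, "gene_sets.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("[expr] %d genes x %d samples, %d set assignments\n",
            nrow(tb$signals), ncol(tb$signals), nrow(sets)))

jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("wrote", out, "\n")
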