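# Regenerates the shipped fixture files and frozen regression snapshots.
# Run from the repository root AFTER installing the package:
#   Rscript tools/make_snapshots.R
# Snapshots guard against silent drift: tests compare freshly computed
# results byte-for-byte against these files, so changing fixture rules or
# algorithms requires rerunning this script deliberately.

library(macpol)

ext <- file.path("inst", "extdata")
snap <- file.path(ext, "snapshots")
dir.create(snap, recursive = TRUE, showWarnings = FALSE)

fx <- macrophage_fixture()
net <- fx$network
scheme <- fx$scheme

write_network(net, file.path(ext, "macrophage_trn_synthetic.bnet"))
write_network(net, file.path(ext, "macrophage_trn_synthetic.json"))
write_phenotype_scheme(scheme, file.path(ext, "phenotype_scheme_macrophage.json"))

# --- exhaustive census snapshot (counts by period) -----------------------
aset <- enumerate_attractors(net)
periods <- vapply(aset$attractors, function(a) a$period, integer(1))
census <- list(
  n_nodes = length(net$nodes),
  n_attractors = length(periods),
  periods = as.list(table(periods)),
  basin_sum = sum(vapply(aset$attractors, function(a) a$basin_size, numeric(1)))
)
writeLines(jsonlite::toJSON(census, auto_unbox = TRUE, pretty = TRUE),
           file.path(snap, "macrophage_census.json"))

# --- fate-map snapshots under two documented TME conditions --------------
# Attractors are one-per-input-configuration here (inputs are held), so a
# TME condition selects attractors by the values of the input nodes.
input_nodes <- c("HIF1A", "IFNG", "GMCSF", "IL4", "IL6", "IL10", "IL1B",
                 "TNFA", "TGFB")
select_by_inputs <- function(aset, cond) {
  keep <- vapply(aset$attractors, function(a) {
    all(a$states[1, names(cond)] == cond)
  }, logical(1))
  aset$attractors <- aset$attractors[keep]
  aset
}
full_cond <- function(values) setNames(values, input_nodes)

conds <- list(
  # monocyte in an IL-10 microenvironment: only IL10 on -> cyclic attractor
  il10_only = full_cond(c(0, 0, 0, 0, 0, 1, 0, 0, 0)),
  # hyper-inflammatory milieu: IFNG + GMCSF + TNFA on -> pure M1 fixed point
  inflammatory = full_cond(c(0, 1, 1, 0, 0, 0, 0, 1, 0))
)
for (nm in names(conds)) {
  sub <- select_by_inputs(aset, conds[[nm]])
  stopifnot(length(sub$attractors) == 1L)
  fm <- build_fate_map(net, sub, scheme)
  export_fate_map(fm, file.path(snap, sprintf("fatemap_%s.tsv", nm)))
}

cat("snapshots written:\n")
print(list.files(snap))
cat(sprintf("census: %d attractors, periods %s\n", census$n_attractors,
            paste(names(census$periods), unlist(census$periods),
                  sep = ":", collapse = ", ")))
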