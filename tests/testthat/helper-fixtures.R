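# Shared fixtures: a small planted cohort and a fast model configuration so
# unit tests that need a trained model stay in the seconds range.

small_cohort <- function(seed = 5, effect_size = 2, ...) {
  generate_cohort(n_drugs = 12, n_cells = 12, n_genes = 40,
                  effect_size = effect_size, seed = seed, ...)
}

small_inputs <- function(seed = 5, ...) cohort_inputs(small_cohort(seed, ...))

fast_config <- function(...) {
  args <- list(hidden_size = 10, n_heads = 2, epochs = 30, dropout_rate = 0.1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}

# Graph + similarity bundle for a given input bundle and mask.
build_graph_parts <- function(inputs, mask = NULL, pad_mode = "zero") {
  Acg <- build_cell_gene_adjacency(inputs$expression)
  Adg <- build_drug_gene_adjacency(inputs$dti, inputs$response$drug_ids,
                                   colnames(inputs$expression), pad_mode)
  graph <- assemble_graph(inputs$response$labels, Acg, Adg, mask)
  list(graph = graph, feats = gtdr:::build_similarities(inputs),
       Acg = Acg, Adg = Adg)
}
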