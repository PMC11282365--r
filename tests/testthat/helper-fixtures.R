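# random ultrametric tree (coalescent shape) with given tip labels
random_chronogram <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::rcoal(n)
  tr$tip.label <- labels
  tr
}

# internal node ages keyed by node name, from a chronogram
named_node_ages <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  nn <- node_names(tree)
  ages <- node_ages(tree)
  stats::setNames(ages[nn$node], nn$node_name)
}

# tip labels under an internal node
descendant_tips_of <- function(tree, node) {
  ape::extract.clade(tree, node)$tip.label
}

# the published calibration ages of the six-species example, as a tibble
table1_ages <- function() {
  ex <- small_example_db()
  ex$table1
}
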