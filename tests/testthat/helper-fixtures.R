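# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Pectinate (caterpillar) tree with unit branch lengths.
make_caterpillar <- function(n) {
  tr <- ape::stree(n, "right")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

make_balanced <- function(n) {
  tr <- ape::stree(n, "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# Pure-birth tree with n tips and positive branch lengths.
rand_yule <- function(n) ape::rphylo(n, 1, 0)

# Named trait helper.
tipvec <- function(tree, values) stats::setNames(values, tree$tip.label)

# The published Red List census of the 837 reef corals.
paper_census <- c(CR = 4, EN = 23, VU = 198, NT = 174, LC = 289, DD = 149)
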