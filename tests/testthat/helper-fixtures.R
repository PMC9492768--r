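# Shared fixtures, built in code.

# Two-node chain A -> B: A holds its state, B copies A.
chain_rules <- function() {
  list(
    A = enumerate_candidates("A", character(0), integer(0)),
    B = enumerate_candidates("B", "A", 1L)
  ) |> lapply(`[[`, 1)
}

chain_network <- function() {
  signed_network(data.frame(from = "A", to = "B", sign = 1L), name = "chain")
}

# binary_matrix from a plain 0/1 matrix (continuous defaults to 2x states)
make_binary <- function(states, metadata = NULL, continuous = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) {
    rownames(states) <- paste0("cell", seq_len(nrow(states)))
  }
  storage.mode(states) <- "integer"
  if (is.null(continuous)) continuous <- states * 2
  dimnames(continuous) <- dimnames(states)
  if (is.null(metadata)) {
    metadata <- tibble::tibble(cell_id = rownames(states))
  }
  structure(list(states = states, continuous = continuous,
                 metadata = tibble::as_tibble(metadata)),
            class = "binary_matrix", method = "fixture")
}

# Minimal KGML document: entries A, B, C (C has two member genes C1, C2),
# A activates B, B inhibits C-group members.
kgml_fixture <- function() {
  '<?xml version="1.0"?>
<pathway name="path:test01" title="Toy pathway">
  <entry id="1" name="hsa:1" type="gene">
    <graphics name="A"/>
  </entry>
  <entry id="2" name="hsa:2" type="gene">
    <graphics name="B"/>
  </entry>
  <entry id="3" name="hsa:3 hsa:4" type="gene">
    <graphics name="C1, C2"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
</pathway>'
}

graphml_fixture <- function(sign_b = "i") {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<graphml xmlns="http://graphml.graphdrawing.org/xmlns">
  <key id="d0" for="edge" attr.name="signal" attr.type="string"/>
  <graph id="G" edgedefault="directed">
    <node id="A"/>
    <node id="B"/>
    <edge source="A" target="B"><data key="d0">%s</data></edge>
  </graph>
</graphml>', sign_b)
}

write_tmp <- function(text, ext) {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}
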