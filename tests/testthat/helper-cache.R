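# Expensive shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# descriptor table for the 19 packaged compounds, computed from structure
packaged_descriptors <- function() {
  cached("descriptors", function() {
    compute_descriptors(tzd_compounds(), seed = 1L)
  })
}

# one embedded small molecule for geometry tests
embedded_phenol <- function() {
  cached("phenol", function() {
    embed_mol(mol_from_smiles("Oc1ccccc1", id = "phenol"), seed = 1L)
  })
}
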