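# Shared fixture bundle, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- make_fixtures(seed = 42)
  .fixture_cache$fx
}

write_tsv_matrix <- function(E, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(E, path)
  path
}
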