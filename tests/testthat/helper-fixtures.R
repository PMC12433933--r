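# Shared fixtures: a mortality-like historical control data set
# (10 negative-control groups of 50 animals, moderate proportion, slight
# overdispersion) built in code, and its file form for the CSV/CLI tests.

mortality_like_hcd <- function() {
  hcd(y = c(10, 12, 21, 14, 13, 16, 9, 15, 18, 10), n = rep(50, 10))
}

write_fixture_csv <- function(data = mortality_like_hcd()) {
  path <- tempfile(fileext = ".csv")
  write_hcd(data, path)
  path
}

# run a CLI invocation, returning list(code, json) from captured stdout
run_cli_json <- function(args) {
  out <- capture.output(code <- hcl_cli(args))
  list(code = code,
       json = if (length(out)) {
         jsonlite::fromJSON(paste(out, collapse = ""))
       } else NULL)
}
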