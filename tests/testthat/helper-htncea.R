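# Shared fixtures: parse the bundled configuration once per test run.

.fixtures <- new.env(parent = emptyenv())

base_params <- function() {
  if (is.null(.fixtures$ps))
    .fixtures$ps <- load_parameters(htncea_example_config())
  .fixtures$ps
}

# All-point-mass variant of the base configuration (degenerate PSA).
point_params <- function() {
  if (is.null(.fixtures$ps_point)) {
    ps <- base_params()
    .fixtures$ps_point <- htncea:::walk_params(ps, function(p, path) {
      p$dist <- dist_point(p$value)
      p
    })
  }
  .fixtures$ps_point
}

# Write a modified copy of the bundled YAML config and return its path.
write_modified_config <- function(modify) {
  raw <- yaml::read_yaml(htncea_example_config())
  raw <- modify(raw)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  path
}
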