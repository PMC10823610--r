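# shared fixtures: load the packaged base case once per test run
fixture <- default_params()

# a variant with no background mortality and no recurrence: the chain is the
# identity and occupancy must stay constant
frozen_cohort_params <- function(params = fixture) {
  params$mortality$life_table$rate[] <- 0
  params$recurrence$annual_prob[] <- 0
  params
}

# both arms share the intervention's 90-day distribution: the only remaining
# difference is the drug-acquisition cost
no_difference_params <- function(params = fixture) {
  params$d90$huk <- params$d90$edb
  params
}

modified_config <- function(edit) {
  # write an edited copy of the packaged YAML config to a temp file
  raw <- yaml::read_yaml(system.file("extdata", "base_case_2021_cny.yaml",
                                     package = "strokecea"))
  raw <- edit(raw)
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(raw, path)
  path
}
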