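# Small SWC fixtures written on the fly.

swc_file <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# soma point + 5-compartment dendrite chain
swc_chain6 <- function() swc_file(c(
  "# soma + chain of 5",
  "1 1 0 0 0 2 -1",
  "2 3 1 0 0 1 1",
  "3 3 2 0 0 1 2",
  "4 3 3 0 0 1 3",
  "5 3 4 0 0 1 4",
  "6 3 5 0 0 1 5"))

# 3-point soma, one dendrite hanging off each soma point
swc_multisoma <- function() swc_file(c(
  "1 1 0 0 0 2 -1",
  "2 1 1 0 0 2 1",
  "3 1 2 0 0 2 2",
  "4 3 0 1 0 1 1",
  "5 3 1 1 0 1 2",
  "6 3 2 1 0 1 3"))

# soma + axon chain + dendrite chain
swc_with_axon <- function() swc_file(c(
  "1 1 0 0 0 2 -1",
  "2 2 0 -1 0 1 1",
  "3 2 0 -2 0 1 2",
  "4 3 0 1 0 1 1",
  "5 3 0 2 0 1 4"))

# canonical prepared morphology: collapsed + stripped
prepared <- function(path) strip_axon(collapse_soma(read_swc(path)))
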