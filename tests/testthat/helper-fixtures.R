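# Shared fixtures, all generated in code.

small_ref <- function(len = 2000, seed = 101) make_reference(len, 0.4, seed)

# Two-clade hierarchy on a 2 kb reference: A (root, 2 sites) with child B,
# and an unrelated root C.
small_panels <- function() {
  diagnostic_panels(data.frame(
    haplogroup = c("A", "A", "B", "C", "C"),
    parent = c(NA, NA, "A", NA, NA),
    position = c(150L, 900L, 400L, 1200L, 1500L),
    ref = c("C", "G", "A", "T", "C"),
    alt = c("T", "A", "G", "C", "T"),
    class = "transition"
  ))
}

noiseless_params <- function(coverage = 20) {
  damage_params(delta_ss = 0, delta_ds = 0, seq_error = 0,
                coverage = coverage)
}

# Reconstruct the original (undamaged) fragment a read was drawn from.
true_fragment <- function(hap, truth_row) {
  frag <- paleobov:::circ_substr(as.character(hap), truth_row$ref_start,
                                 truth_row$length)
  if (truth_row$strand == "-") paleobov:::revcomp(frag) else frag
}
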