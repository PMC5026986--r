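# Small in-code fixtures shared across test files.

# A minimal well-formed concentration table: one tree treatment, weeks 0 and 4.
make_profile_fixture <- function(nh4 = c(174, 94), no2 = c(11, 0),
                                 no3 = c(219, 332), treatment = "unfiltered",
                                 source = "tree", weeks = c(0L, 4L)) {
  tibble::tibble(
    sample_id = paste0("s", seq_along(weeks)),
    source = source, treatment = treatment, week = weeks,
    nh4_uM = nh4, no2_uM = no2, no3_uM = no3)
}

# Forward two-pool mixing oracle: combine C_old at d_old with C_new at d_new.
mix_forward <- function(c_old, d_old, c_new, d_new) {
  (c_old * d_old + c_new * d_new) / (c_old + c_new)
}
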