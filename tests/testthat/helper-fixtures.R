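# Shared helpers: the packaged dataset, a raw-2x2 constructor, and toy sets.

fixture <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- fas_fasl_preeclampsia()
    ds
  }
})

# An arbitrary 2x2 (a = exposed cases, b = unexposed cases, c = exposed
# controls, d = unexposed controls) expressed through the homozygote contrast,
# which maps (n22, n11) of each arm straight onto (exposed, unexposed).
tab2x2 <- function(a, b, c, d, id = NA_character_) {
  build_contrast(c(b, 0, a), c(d, 0, c), "homozygote", study_id = id)
}

# Swap case and control arms of a contrast table (for reciprocity checks).
swap_arms <- function(t) tab2x2(t$c, t$d, t$a, t$b, id = t$study_id)

# Per-study Woolf log-OR and SE computed independently of the package's
# estimate path (plain arithmetic on the four cells).
woolf_oracle <- function(tables) {
  do.call(rbind, lapply(tables, function(t) {
    data.frame(y = log(t$a * t$d / (t$b * t$c)),
               se = sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d))
  }))
}
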