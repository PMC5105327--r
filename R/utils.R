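# Reduce hours onto the half-open circle [0, 24). Plain `%% 24` can return
# exactly 24 for tiny negative inputs (floating point), which is outside
# the cyclic basis domain; snap that case back to 0.
#' @noRd
wrap24 <- function(t) {
  t <- t %% 24
  t[t >= 24] <- 0
  t
}
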