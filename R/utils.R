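# Round half away from zero. base::round() rounds half to even, which would
# make ROI bounds depend on the parity of w/h; all pixel-geometry rounding in
# the package goes through this helper so the brute-force oracles can share it.
round_half_out <- function(x) {
  trunc(x + sign(x) * 0.5)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(fmt, ..., class = "thermoface_error") {
  abort(sprintf(fmt, ...), class = class)
}
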