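#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation, parse and
# clustering failures programmatically.
vz_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "velozone_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vz_validation_error <- function(msg, ...) vz_stop(msg, "velozone_validation_error", ...)
vz_parse_error <- function(msg, ...) vz_stop(msg, "velozone_parse_error", ...)
vz_cluster_error <- function(msg, ...) vz_stop(msg, "velozone_cluster_error", ...)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sub-seed derivation: keeps every derived seed a valid 32-bit integer and
# decorrelated across indices for any small master seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269) %% 2147483629) + 1L
}
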