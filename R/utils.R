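## internal helpers

## multiplicative lognormal noise with mean exactly 1 and fractional SD cv
rlnorm_unit_mean <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## look up a PPFD-keyed parameter map (named numeric vector); linear
## interpolation between keys, flat extrapolation beyond the range
ppfd_lookup <- function(map, ppfd) {
  keys <- as.numeric(names(map))
  if (any(is.na(keys))) abort("PPFD map must have numeric names")
  if (length(keys) == 1L) return(rep(unname(map), length(ppfd)))
  ord <- order(keys)
  stats::approx(keys[ord], unname(map)[ord], xout = ppfd, rule = 2)$y
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}

## derive a stream of child seeds from one master seed without touching
## the caller's RNG state more than once
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
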