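# Internal helpers: RNG hygiene and seed substreams.

# Save / restore the global RNG state so seeded package functions do not
# perturb the caller's stream.
.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic substream seed from a master seed and a stage name, stable
# under adding stages.  Plain polynomial string hash folded into [0, 2^31-2].
.substreamSeed <- function(master, name) {
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(name))
    h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Draw n derived seeds reproducibly from one seed.
.derivedSeeds <- function(seed, n) {
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
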