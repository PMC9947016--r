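# Run code under a fixed RNG seed without disturbing the caller's RNG
# stream: generators are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integral over (x, y).
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
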