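# Internal helpers: classed conditions and deterministic rounding.

dr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dynroot_error")))
}

dr_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "dynroot_warning")))
}

# round-half-up; base round() is half-even, which would make the 8-bit
# rescale depend on parity of the scaled value
round_half_up <- function(x) floor(x + 0.5)

# clip + round into the 8-bit intensity contract
clip8 <- function(x) {
  as.integer(pmin(255, pmax(0, round_half_up(x))))
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
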