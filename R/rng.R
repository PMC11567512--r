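# Deterministic stream splitting and counter-based uniforms.
#
# All randomness in a simulation run flows from a single master seed.
# Per-purpose streams are derived by hashing a text label (plus the
# replicate index) into a 31-bit seed; the policy id is deliberately NOT
# part of the derivation, so that different policies run on common random
# numbers.  Event-level draws that must be order-independent (consumable
# availability, treatment effectiveness) are instead generated by a
# counter-based hash keyed on the episode id and attempt number.

.M31 <- 2147483647  # 2^31 - 1, Park-Miller modulus (exact in doubles)
.A31 <- 16807

# one multiplicative-congruential mixing step; exact because
# s * 16807 + b < 2^53 for s < 2^31
.mix <- function(s, b) {
  (s * .A31 + b + 1) %% .M31
}

#' Derive a deterministic sub-stream seed from a master seed
#'
#' Hashes a purpose label and replicate index into a 31-bit seed for
#' `set.seed()`. The same `(master_seed, replicate, label)` triple always
#' yields the same stream; the policy under evaluation must never enter the
#' label, so that policy comparisons use common random numbers.
#'
#' @param master_seed Integer master seed of the run.
#' @param replicate Integer replicate index (1-based).
#' @param label Character purpose label, e.g. `"incidence:day:120"`.
#' @return An integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
stream_seed <- function(master_seed, replicate, label) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  s <- (abs(as.numeric(master_seed)) + 1) %% .M31
  s <- .mix(s, replicate)
  for (b in utf8ToInt(as.character(label))) s <- .mix(s, b)
  # extra diffusion rounds
  s <- .mix(.mix(s, 97), 13)
  as.integer(s %% (.M31 - 2) + 1)
}

# set R's RNG from a derived stream; callers draw vectorised variates after
set_stream <- function(master_seed, replicate, label) {
  set.seed(stream_seed(master_seed, replicate, label))
}

#' Counter-based uniform deviate keyed on integers
#'
#' Returns a deterministic uniform in (0, 1) as a pure function of
#' `(seed, i, j, k)`. Used for per-episode, per-attempt draws (consumable
#' availability, effectiveness) so that the outcome of one patient's HSI
#' does not depend on the order in which the day's queue was scanned --
#' a requirement for the unconstrained-limit identity across policies.
#'
#' @param seed Integer base seed (derive via [stream_seed()]).
#' @param i,j,k Integer keys (e.g. episode id, attempt, draw index).
#'   Vectorised over `i`.
#' @return Numeric vector of uniforms in (0, 1), same length as `i`.
#' @export
hash_u <- function(seed, i, j = 0, k = 0) {
  x <- bitwXor(as.integer(seed %% .M31), -1640531527L)  # golden-ratio salt
  x <- .fmix32(bitwXor(x, as.integer(i %% .M31)))
  x <- .fmix32(bitwXor(x, as.integer(j %% .M31)))
  x <- .fmix32(bitwXor(x, as.integer(k %% .M31)))
  (bitwAnd(x, 2147483647L) + 0.5) / 2147483648
}

# exact (a * b) mod 2^32 on 32-bit patterns held in R integers, via 16-bit
# limb split so every intermediate stays below 2^53
.mul32 <- function(a, b) {
  au <- as.numeric(a); au[au < 0] <- au[au < 0] + 4294967296
  lo <- au %% 65536; hi <- au %/% 65536
  v <- (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
  v[v >= 2147483648] <- v[v >= 2147483648] - 4294967296
  as.integer(v)
}

# murmur3 32-bit finalizer: genuinely nonlinear bit mixing, so hashes of
# related keys are statistically independent for our purposes
.fmix32 <- function(x) {
  x <- bitwXor(x, bitwShiftR(x, 16L))
  x <- .mul32(x, 2246822507)   # 0x85ebca6b
  x <- bitwXor(x, bitwShiftR(x, 13L))
  x <- .mul32(x, 3266489909)   # 0xc2b2ae35
  bitwXor(x, bitwShiftR(x, 16L))
}
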