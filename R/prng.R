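# Minimal Lehmer ("minstd") linear congruential generator used only for the
# fixed, participant-independent stimulus order of the task schedules.
# state' = 16807 * state mod (2^31 - 1). Keeping the schedule stream separate
# from R's session RNG means a schedule is a pure function of its order seed,
# unaffected by set.seed() or any simulation noise drawn around it.

.minstd_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  state <- (abs(floor(seed)) %% (m - 1L)) + 1
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

.minstd_next <- function(gen) {
  gen$state <- (16807 * gen$state) %% 2147483647
  gen$state / 2147483647
}

# integer in 1..n
.minstd_int <- function(gen, n) {
  floor(.minstd_next(gen) * n) + 1L
}

# Fisher-Yates shuffle driven by the minstd stream
.minstd_shuffle <- function(gen, x) {
  n <- length(x)
  if (n < 2) return(x)
  for (i in n:2) {
    j <- .minstd_int(gen, i)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

# longest run of identical consecutive values
.max_run <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(as.character(x))$lengths)
}

# shuffle until no more than `max_run` consecutive identical elements
.constrained_shuffle <- function(gen, x, max_run = 3L, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    cand <- .minstd_shuffle(gen, x)
    if (.max_run(cand) <= max_run) return(cand)
  }
  stop("constrained shuffle failed to satisfy the run-length bound")
}
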