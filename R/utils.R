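# Internal: evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards so library calls never
# perturb user-level randomness.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Fixed internal seed for the "random" ties method when the caller supplies
# none: random tie-breaking stays reproducible by default.
.DEFAULT_TIE_SEED <- 20210517L

.METHODS <- c("BH", "BY", "Bon", "Sidak", "Holm", "Hoch")

.matchMethod <- function(method) {
  if (length(method) != 1L || !method %in% .METHODS)
    stop("unknown adjustment method '", paste(method, collapse = ","),
         "'; options are ", paste(.METHODS, collapse = ", "), call. = FALSE)
  method
}

.asPValueSet <- function(p, naPolicy = "remove", tiesMethod = "random",
                         tieSeed = NULL) {
  if (is(p, "PValueSet")) p
  else PValueSet(p, naPolicy = naPolicy, tiesMethod = tiesMethod,
                 tieSeed = tieSeed)
}
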