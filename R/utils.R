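# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state on exit so generators behave as pure functions of
# their parameter object.
local_seed <- function(seed, env = parent.frame()) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  do.call(on.exit,
          list(bquote(assign(".Random.seed", .(old), globalenv())), add = TRUE),
          envir = env)
  set.seed(seed)
}
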