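# Lazily computed, cached full-scale runs shared by the summary-statistic
# tests (each configuration is expensive; several tests read the same runs).
.fullScaleCache <- new.env(parent = emptyenv())

fullScaleRuns <- function(name, maker) {
  if (!exists(name, envir = .fullScaleCache))
    assign(name, maker(), envir = .fullScaleCache)
  get(name, envir = .fullScaleCache)
}

# three replicate full-scale evolution runs for a given spec
evolveReplicates <- function(k, spec, seeds = c(101, 202, 303)) {
  lapply(seeds, function(s)
    evolve(evolutionConfig(k, spec = spec, seed = s)))
}

meanRepComponent <- function(runs, component) {
  mean(vapply(runs, function(r)
    representativeObjectives(r)[[component]], numeric(1)))
}
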