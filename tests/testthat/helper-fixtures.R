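# Small fixtures shared across tests; everything is generated in code.

# a fast, small synthetic configuration
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nNeuronsPop1 = 20, nNeuronsPop2 = 30, nTrialsPerTask = 20,
                   reliabilityTarget = 0.8, seed = 11)
  do.call(synthConfig, utils::modifyList(defaults, args))
}

# noiseless configuration (reliability target 1 => zero trial noise)
noiselessConfig <- function(...) {
  tinyConfig(reliabilityTarget = 1, nTrialsPerTask = 4, ...)
}

# a bare TrialTensor from an array
tensorFromArray <- function(arr, frameRate = 10) {
  tt <- dim(arr)[2]
  trialTensor(arr, (seq_len(tt) - 1 - floor(tt / 2)) / frameRate,
              "Reach", frameRate)
}

# points on a circle, optionally sheared
circleTraj <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}
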