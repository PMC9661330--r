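# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Desk-scale head model and leadfield: 16 symmetric channels, 24 mm grid.
small_model <- function() {
  fixture("small_model", function() head_model(electrodes = 16,
                                               grid_spacing = 24))
}

small_leadfield <- function() {
  fixture("small_leadfield", function() make_leadfield(small_model()))
}

# One simulated subject (short blocks keep unit tests quick).
short_config <- function(...) {
  args <- utils::modifyList(
    list(n_neg = 2, n_pos = 2, n_channels = 16,
         run_layout = list(list("EC", 10), list("EO", 10))),
    list(...))
  do.call(sim_config, args)
}

small_recording <- function() {
  fixture("small_recording", function() {
    simulate_subject(short_config(seed = 42),
                     small_leadfield(),
                     list(suvr = 0.90), seed = 42)
  })
}

# White-noise recording with EC/EO markers, no structure.
noise_recording <- function(n_ch = 8, secs = 12, fs = 250, seed = 7) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * secs * fs), n_ch), fs,
                markers = data.frame(onset_s = c(0, secs / 2),
                                     duration_s = c(secs / 2, secs / 2),
                                     condition = c("EC", "EO")))
}
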