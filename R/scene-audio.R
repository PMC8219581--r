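#' Synthesize the audio track of a scene
#'
#' Collects the auditory objects of a scene (tones, noise, audio files
#' are out of scope for synthesis and must be WAV readable by
#' [read_wav()]), synthesizes each at the test's audio rate, schedules
#' them at their `start_time`, applies the device audiovisual-offset
#' correction and mixes them into one scene-length buffer.
#'
#' @param test A valid [stim_test()].
#' @param scene Scene name.
#' @param bindings Named list of variable values for the trial.
#' @param seed Integer seed for stochastic audio (noise).
#' @return An [audio_buffer()] spanning the scene duration.
#' @export
scene_audio <- function(test, scene, bindings = list(),
                        seed = test$settings$rng_seed) {
  sc <- NULL
  for (sec in test$sections) {
    sc <- find_by_name(sec$scenes, scene)
    if (!is.null(sc)) break
  }
  if (is.null(sc)) stop(sprintf("no scene named '%s'", scene), call. = FALSE)
  rate <- test$settings$audio_rate
  refresh <- test$settings$display$refresh_rate
  dur_s <- if (identical(sc$duration$unit, "frames"))
    sc$duration$value / refresh else sc$duration$value
  ctx <- list(frame = 0L, total_frames = 1L, refresh_rate = refresh)
  events <- list()
  for (nm in sc$objects) {
    st <- find_by_name(test$stimuli, nm)
    if (!st$type %in% auditory_types) next
    onset <- if (is.null(st$properties$start_time)) 0 else
      resolve_property(st, "start_time", bindings, ctx)
    dur <- if (is.null(st$properties$duration)) dur_s - onset else
      resolve_property(st, "duration", bindings, ctx)
    amp <- if (is.null(st$properties$amplitude)) 0.5 else
      resolve_property(st, "amplitude", bindings, ctx)
    buf <- switch(st$type,
      tone = synth_tone(resolve_property(st, "tone_frequency", bindings, ctx),
                        dur, amp,
                        ramp = if (is.null(st$properties$ramp)) 0.005 else
                          resolve_property(st, "ramp", bindings, ctx),
                        sample_rate = rate),
      noise = synth_auditory_noise(dur, amp, rate,
                                   seed = derive_seed(seed, 53, length(events))),
      audio_file = read_wav(resolve_property(st, "file_path", bindings, ctx)))
    events[[length(events) + 1L]] <- list(buffer = buf, onset = onset)
  }
  mix_scene_audio(events, dur_s, rate, test$settings$av_offset_ms)
}
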