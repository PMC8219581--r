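#' Audio buffers
#'
#' Mono sample buffers of reals in \[-1, 1\]. The default sample rate is
#' 44.1 kHz; buffer duration in seconds is `length(samples) / sample_rate`,
#' so a requested duration is realized exactly to within half a sample.
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param sample_rate Sample rate in Hz.
#' @return An `audio_buffer` object.
#' @export
audio_buffer <- function(samples, sample_rate = 44100) {
  if (any(abs(samples) > 1 + 1e-12))
    stop("samples must lie within [-1, 1]", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples @ %g Hz (%.4f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

buffer_duration <- function(buf) length(buf$samples) / buf$sample_rate

#' Synthesize a pure tone
#'
#' `samples[i] = amplitude * env(i) * sin(2*pi*frequency*i/sample_rate)`
#' with a linear on/off amplitude ramp of length `ramp` seconds (0 allowed)
#' to avoid onset/offset clicks. The sample count is
#' `round(duration * sample_rate)`.
#'
#' @param frequency Tone frequency in Hz (must be below Nyquist).
#' @param duration Duration in seconds (> 0).
#' @param amplitude Peak amplitude in \[0, 1\].
#' @param ramp Linear ramp length in seconds (default 5 ms).
#' @param sample_rate Sample rate in Hz (default 44100).
#' @return An [audio_buffer()].
#' @export
synth_tone <- function(frequency, duration, amplitude = 0.5, ramp = 0.005,
                       sample_rate = 44100) {
  if (frequency >= sample_rate / 2)
    stop(sprintf("frequency %g Hz is at or above Nyquist (%g Hz): aliasing",
                 frequency, sample_rate / 2), call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  n <- as.integer(round(duration * sample_rate))
  i <- seq_len(n) - 1
  env <- rep(1, n)
  nr <- as.integer(round(ramp * sample_rate))
  if (nr > 0 && n > 2 * nr) {
    ramp_up <- seq(0, 1, length.out = nr + 1)[-1]
    env[seq_len(nr)] <- ramp_up
    env[(n - nr + 1):n] <- rev(ramp_up)
  }
  audio_buffer(amplitude * env * sin(2 * pi * frequency * i / sample_rate),
               sample_rate)
}

#' Synthesize auditory white noise
#'
#' Independent uniform samples in `[-amplitude, amplitude]`.
#'
#' @inheritParams synth_tone
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return An [audio_buffer()].
#' @export
synth_auditory_noise <- function(duration, amplitude = 0.5,
                                 sample_rate = 44100, seed = NULL) {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  n <- as.integer(round(duration * sample_rate))
  audio_buffer(with_local_seed(seed,
    stats::runif(n, -amplitude, amplitude)), sample_rate)
}

#' Schedule and mix audio events into a scene buffer
#'
#' Each event is a buffer plus an onset (seconds from scene start). The
#' device audiovisual-offset correction `av_offset_ms` shifts every onset
#' by the measured audio lead/lag of the device so that sound and image
#' specified at the same onset actually coincide. Overlapping events sum
#' and are hard-clipped to \[-1, 1\] (with a warning); events pushed
#' before 0 are truncated at 0 with a warning, and samples beyond the
#' scene end are dropped with a warning.
#'
#' @param events List of `list(buffer = <audio_buffer>, onset = <s>)`.
#' @param scene_duration Scene duration in seconds.
#' @param sample_rate Output sample rate in Hz.
#' @param av_offset_ms Signed audiovisual onset correction in ms.
#' @return An [audio_buffer()] of `round(scene_duration * sample_rate)`
#'   samples.
#' @export
mix_scene_audio <- function(events, scene_duration, sample_rate = 44100,
                            av_offset_ms = 0) {
  n <- as.integer(round(scene_duration * sample_rate))
  out <- numeric(n)
  for (ev in events) {
    buf <- ev$buffer
    onset <- ev$onset + av_offset_ms / 1000
    start <- as.integer(round(onset * sample_rate))  # 0-based
    s <- buf$samples
    if (start < 0) {
      warning("event onset before scene start; truncating at 0")
      s <- s[(-start + 1):length(s)]
      start <- 0L
    }
    if (length(s) == 0L) next
    end <- start + length(s)  # 0-based exclusive
    if (end > n) {
      warning("event extends beyond scene end; truncating")
      s <- s[seq_len(max(0L, n - start))]
      end <- start + length(s)
    }
    if (length(s) == 0L) next
    idx <- (start + 1L):end
    out[idx] <- out[idx] + s
  }
  if (any(abs(out) > 1)) {
    warning("mixed audio exceeds full scale; hard-clipping to [-1, 1]")
    out <- pmin(1, pmax(-1, out))
  }
  audio_buffer(out, sample_rate)
}

#' Write an audio buffer as a 16-bit PCM mono WAV file
#'
#' Plain RIFF/WAVE container, PCM16 little-endian, one channel.
#' A write/read round trip reproduces the samples to within one
#' quantization step (1/32768).
#'
#' @param buffer An [audio_buffer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path) {
  s <- pmin(1, pmax(-1, buffer$samples))
  pcm <- as.integer(round(s * 32767))
  rate <- as.integer(round(buffer$sample_rate))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path (as written by [write_wav()]).
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file", call. = FALSE)
  rate <- NA_integer_; bits <- NA_integer_; channels <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      channels <- fmt[2]
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (bits != 16L || channels != 1L)
        stop("only 16-bit mono PCM is supported", call. = FALSE)
      pcm <- readBin(con, "integer", size / 2L, 2, signed = TRUE,
                     endian = "little")
      return(audio_buffer(pcm / 32767, rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}
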