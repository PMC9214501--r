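#' Spike trains
#'
#' Per-neuron sorted spike times over a common recording window.  Used by
#' the spike-train cross-correlogram estimator \code{\link{cspk}} and by
#' \code{\link{split_active_quiet}}.
#'
#' @param spike_times list of numeric vectors (seconds), one per neuron,
#'   each strictly increasing and inside \code{[0, duration]}.
#' @param duration total recording time in seconds.
#' @return An object of class \code{ddc_spikes} with fields
#'   \code{spike_times}, \code{duration} and \code{n_neurons}.
#' @export
ddc_spiketrains <- function(spike_times, duration) {
  if (!is.list(spike_times)) stop("`spike_times` must be a list of numeric vectors")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number (seconds)")
  if (is.null(names(spike_times)))
    names(spike_times) <- paste0("n", seq_along(spike_times))
  for (i in seq_along(spike_times)) {
    tk <- spike_times[[i]]
    if (!is.numeric(tk)) stop("spike times of neuron ", i, " are not numeric")
    if (length(tk)) {
      if (any(tk < 0 | tk > duration))
        stop("neuron ", names(spike_times)[i], " has spike times outside [0, duration]")
      if (any(diff(tk) <= 0))
        stop("spike times of neuron ", names(spike_times)[i],
             " are not strictly increasing")
    }
    spike_times[[i]] <- as.numeric(tk)
  }
  structure(list(spike_times = spike_times, duration = duration,
                 n_neurons = length(spike_times)),
            class = "ddc_spikes")
}

#' @export
print.ddc_spikes <- function(x, ...) {
  rates <- vapply(x$spike_times, length, 0L) / x$duration
  cat(sprintf("<ddc_spikes> %d neurons over %g s, mean rate %.3g Hz\n",
              x$n_neurons, x$duration, mean(rates)))
  invisible(x)
}

#' Firing rates in Hz
#' @param spikes a \code{\link{ddc_spiketrains}}.
#' @export
firing_rates <- function(spikes) {
  stopifnot(inherits(spikes, "ddc_spikes"))
  vapply(spikes$spike_times, length, 0L) / spikes$duration
}

#' Bin spike trains into counts on a regular grid
#'
#' @param spikes a \code{\link{ddc_spiketrains}}.
#' @param dt bin width in seconds.
#' @return integer matrix, neurons by bins; bin k covers
#'   \code{[(k-1) dt, k dt)}.
#' @export
bin_spikes <- function(spikes, dt) {
  stopifnot(inherits(spikes, "ddc_spikes"), dt > 0)
  nb <- ceiling(spikes$duration / dt)
  out <- matrix(0L, spikes$n_neurons, nb)
  for (i in seq_len(spikes$n_neurons)) {
    tk <- spikes$spike_times[[i]]
    if (length(tk)) {
      b <- pmin(floor(tk / dt) + 1L, nb)
      tb <- tabulate(b, nbins = nb)
      out[i, ] <- tb
    }
  }
  rownames(out) <- names(spikes$spike_times)
  out
}
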