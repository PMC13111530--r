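# Synthetic raster generators with known ground truth. Every generator
# seeds its own RNG stream and restores the caller's, so identical calls
# are byte-identical and nothing leaks into global RNG state.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.poissonTrain <- function(rate, t0, t1) {
  span <- t1 - t0
  if (rate <= 0 || span <= 0) return(numeric())
  n <- stats::rpois(1L, rate * span)
  sort(stats::runif(n, t0, t1))
}

#' Homogeneous Poisson population
#'
#' Each unit fires as an independent homogeneous Poisson process, the null
#' model of a fully decorrelated network: every cross-correlogram is
#' uniform in expectation.
#'
#' @param nUnits number of units.
#' @param duration recording duration in seconds.
#' @param rate firing rate in Hz; a scalar or one rate per unit.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param unitIds optional unit names (default \code{u01, u02, ...}).
#' @return A \linkS4class{SpikeRecording}.
#' @export
genPoissonPopulation <- function(nUnits = 20, duration = 600, rate = 5,
                                 seed = 1, unitIds = NULL) {
  stopifnot(nUnits >= 1, duration > 0, all(rate >= 0))
  rate <- rep_len(rate, nUnits)
  ids <- unitIds %||% sprintf("u%02d", seq_len(nUnits))
  trains <- .withSeed(seed, lapply(rate, .poissonTrain, t0 = 0, t1 = duration))
  names(trains) <- ids
  SpikeRecording(trains, duration = duration,
                 source = sprintf("synthetic:poisson seed=%d", seed))
}

#' Leader/follower pair with a fixed, jittered lag
#'
#' The "leader" unit is homogeneous Poisson; every leader event spawns a
#' "follower" event at \code{lag} seconds later plus Gaussian jitter.
#' Follower events pushed outside \code{[0, duration]} are dropped, and the
#' train re-sorted (jitter may reorder events). With leader as reference
#' the cross-correlogram mass sits almost entirely at positive lags, so
#' the area left of zero is near 0 (a "strong" leader/follower pair) with
#' its dominant peak at +lag.
#'
#' @param rate leader rate in Hz.
#' @param duration seconds.
#' @param lag follower delay in seconds (> 0).
#' @param jitterSd standard deviation of the Gaussian timing jitter (s).
#' @param seed RNG seed.
#' @return A \linkS4class{SpikeRecording} with units \code{leader} and
#'   \code{follower}.
#' @export
genLaggedPair <- function(rate = 2, duration = 600, lag = 0.01,
                          jitterSd = 0.002, seed = 1) {
  stopifnot(lag > 0, jitterSd >= 0, rate > 0, duration > 0)
  .withSeed(seed, {
    leader <- .poissonTrain(rate, 0, duration)
    follower <- leader + lag +
      if (jitterSd > 0) stats::rnorm(length(leader), 0, jitterSd) else 0
    follower <- sort(follower[follower >= 0 & follower <= duration])
    SpikeRecording(list(leader = leader, follower = follower),
                   duration = duration,
                   source = sprintf("synthetic:lagged_pair lag=%g seed=%d",
                                    lag, seed))
  })
}

.burstTrains <- function(nUnits, t0, t1, burstPeriod, burstLen, inBurstRate,
                         participation, baselineRate) {
  starts <- seq(t0, t1 - 1e-12, by = burstPeriod)
  lapply(seq_len(nUnits), function(u) {
    ev <- .poissonTrain(baselineRate, t0, t1)
    for (s in starts) {
      if (stats::runif(1L) > participation) next
      bEnd <- min(s + burstLen, t1)
      ev <- c(ev, .poissonTrain(inBurstRate, s, bEnd))
    }
    sort(ev)
  })
}

#' Population-wide periodic bursting
#'
#' Bursts of length \code{burstLen} start every \code{burstPeriod} seconds;
#' each unit joins each burst with probability \code{participation} and
#' fires at \code{inBurstRate} within it, over a sparse Poisson baseline.
#' Cross-correlograms of such a population show peaks at integer multiples
#' of the burst period.
#'
#' @param nUnits number of units.
#' @param duration seconds.
#' @param burstPeriod seconds between burst onsets.
#' @param burstLen burst duration in seconds (< burstPeriod).
#' @param inBurstRate within-burst rate, Hz.
#' @param participation per-unit, per-burst join probability in [0, 1].
#' @param baselineRate between-burst rate, Hz.
#' @param seed RNG seed.
#' @return A \linkS4class{SpikeRecording}.
#' @export
genPeriodicBursts <- function(nUnits = 10, duration = 120,
                              burstPeriod = 0.25, burstLen = 0.05,
                              inBurstRate = 120, participation = 1,
                              baselineRate = 0.2, seed = 1) {
  stopifnot(burstLen < burstPeriod, participation >= 0, participation <= 1)
  trains <- .withSeed(seed, .burstTrains(nUnits, 0, duration, burstPeriod,
                                         burstLen, inBurstRate,
                                         participation, baselineRate))
  names(trains) <- sprintf("u%02d", seq_len(nUnits))
  SpikeRecording(trains, duration = duration,
                 source = sprintf("synthetic:periodic_bursts period=%g seed=%d",
                                  burstPeriod, seed))
}

.genSegment <- function(spec, nUnits, t0, t1) {
  scenario <- spec$scenario %||% "poisson"
  if (scenario == "poisson") {
    rate <- rep_len(spec$rate %||% 5, nUnits)
    if (!is.null(spec$deadFraction) && spec$deadFraction > 0) {
      nDead <- floor(spec$deadFraction * nUnits)
      dead <- sample.int(nUnits, nDead)
      rate[dead] <- 0
    }
    lapply(rate, .poissonTrain, t0 = t0, t1 = t1)
  } else if (scenario == "periodic_bursts") {
    .burstTrains(nUnits, t0, t1,
                 spec$burstPeriod %||% 0.25, spec$burstLen %||% 0.05,
                 spec$inBurstRate %||% 120, spec$participation %||% 1,
                 spec$baselineRate %||% 0.2)
  } else stop("unknown segment scenario: ", scenario)
}

#' Mid-recording regime switch
#'
#' Generates \code{[0, switchTime)} under the \code{before} parameter list
#' and \code{[switchTime, duration)} under \code{after}; \code{after}
#' inherits any field it does not override. This emulates treatment-like
#' events: synchronization onset (switch from \code{poisson} to
#' \code{periodic_bursts}), per-unit death (\code{deadFraction} of units
#' drop to rate 0 after the switch), or -- with identical before/after
#' parameters -- a negative control in which nothing truly changes.
#'
#' @param before,after parameter lists with a \code{scenario} field
#'   (\code{"poisson"} or \code{"periodic_bursts"}) plus the matching
#'   generator arguments; \code{after} may add \code{deadFraction}.
#' @param switchTime seconds, in (0, duration).
#' @param duration total recording length, seconds.
#' @param nUnits number of units.
#' @param seed RNG seed.
#' @return A \linkS4class{SpikeRecording}; a \code{switch_time} attribute
#'   on the source string records the ground truth.
#' @export
genRegimeSwitch <- function(before = list(scenario = "poisson", rate = 5),
                            after = list(), switchTime = 300,
                            duration = 600, nUnits = 20, seed = 1) {
  stopifnot(switchTime > 0, switchTime < duration)
  after <- utils::modifyList(before, after)
  trains <- .withSeed(seed, {
    pre <- .genSegment(before, nUnits, 0, switchTime)
    post <- .genSegment(after, nUnits, switchTime, duration)
    Map(function(a, b) sort(c(a, b)), pre, post)
  })
  names(trains) <- sprintf("u%02d", seq_len(nUnits))
  SpikeRecording(trains, duration = duration,
                 treatments = data.frame(time = switchTime, label = "switch"),
                 source = sprintf("synthetic:regime_switch t=%g seed=%d",
                                  switchTime, seed))
}

#' Dispatch a named synthetic scenario
#'
#' Convenience wrapper used by the command-line interface: builds one of
#' the four scenarios from a flat parameter list.
#'
#' @param scenario one of \code{"poisson"}, \code{"lagged_pair"},
#'   \code{"periodic_bursts"}, \code{"regime_switch"}.
#' @param ... forwarded to the matching generator.
#' @param seed RNG seed.
#' @return A \linkS4class{SpikeRecording}.
#' @export
simulateRecording <- function(scenario = c("poisson", "lagged_pair",
                                           "periodic_bursts",
                                           "regime_switch"),
                              ..., seed = 1) {
  scenario <- match.arg(scenario)
  fn <- switch(scenario,
               poisson = genPoissonPopulation,
               lagged_pair = genLaggedPair,
               periodic_bursts = genPeriodicBursts,
               regime_switch = genRegimeSwitch)
  fn(..., seed = seed)
}
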