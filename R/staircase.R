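# Auditory detection-threshold staircase: a descending/ascending method of
# limits in fixed dB steps, repeated until two consecutive passes agree.

#' Run one descending/ascending staircase pass
#'
#' The tone starts at `start_db` and is decreased in `step_db` steps until
#' the observer reports not hearing it; it is then increased in `step_db`
#' steps from one step above the last "no" until the observer reports
#' hearing it again. The level of that first ascending "yes" is the pass
#' threshold — the lowest intensity at which the tone was perceived.
#'
#' The observer's stochastic responses are drawn from the current RNG
#' stream in presentation order; [detection_threshold()] seeds the stream
#' once per run from `observer$seed`.
#'
#' @param observer a [make_observer()].
#' @param start_db starting level (default 60 dB HL).
#' @param step_db step size (default 5 dB).
#' @param floor_db if the observer still hears the tone at this level the
#'   descent stops and the floor is treated as the pass threshold, with a
#'   warning (default 0 dB).
#' @param ceiling_db if no ascending "yes" is obtained by this level the
#'   staircase is declared runaway and errors (default `start_db + 20`).
#' @return A list of class `staircase_pass` with `levels_db`, `responses`
#'   (logical, per presentation) and `pass_threshold_db`.
#' @export
run_pass <- function(observer, start_db = 60, step_db = 5, floor_db = 0,
                     ceiling_db = start_db + 20) {
  stopifnot(inherits(observer, "observer"))
  if (!(step_db > 0)) stop_param("`step_db` must be positive")
  levels <- numeric(0)
  resp <- logical(0)
  present <- function(level) {
    levels[length(levels) + 1L] <<- level
    r <- observer_response(observer, level)
    resp[length(resp) + 1L] <<- r
    r
  }

  # descending phase: down in steps until the first "no"
  level <- start_db
  repeat {
    heard <- present(level)
    if (!heard) break
    if (level <= floor_db) {
      warning(sprintf(
        "observer still hears the tone at the %g dB floor; using it as threshold",
        floor_db))
      return(structure(list(levels_db = levels, responses = resp,
                            pass_threshold_db = floor_db),
                       class = "staircase_pass"))
    }
    level <- level - step_db
  }

  # ascending phase: up from one step above the last "no" until a "yes"
  repeat {
    level <- level + step_db
    if (level > ceiling_db) {
      stop_param("runaway staircase: no 'yes' response up to the %g dB ceiling",
                 ceiling_db)
    }
    if (present(level)) break
  }
  structure(list(levels_db = levels, responses = resp,
                 pass_threshold_db = level),
            class = "staircase_pass")
}

#' @export
print.staircase_pass <- function(x, ...) {
  cat(sprintf("<staircase_pass> %d presentations, threshold %g dB\n",
              length(x$levels_db), x$pass_threshold_db))
  invisible(x)
}

#' Detection threshold by repeated staircase passes
#'
#' Runs [run_pass()] repeatedly (each pass restarting at `start_db`) until
#' two consecutive passes yield the same pass threshold; that agreed value
#' is the detection threshold. At least two passes are always run. If no two
#' consecutive passes agree within `max_passes`, a non-convergence error is
#' raised carrying all passes (condition class
#' `edahab_staircase_nonconvergence`, with the passes in `$passes`).
#'
#' @param observer a [make_observer()]; its `seed` (if any) seeds the
#'   response stream for the whole run, making results reproducible.
#' @param start_db,step_db as in [run_pass()].
#' @param max_passes maximum number of passes (>= 2, default 10).
#' @param ... passed on to [run_pass()].
#' @return A list of class `threshold_result` with `passes` (list of
#'   `staircase_pass`), `final_threshold_db` and `n_passes`.
#' @export
detection_threshold <- function(observer, start_db = 60, step_db = 5,
                                max_passes = 10, ...) {
  stopifnot(inherits(observer, "observer"))
  if (max_passes < 2) stop_param("`max_passes` must be >= 2")
  with_seed(observer$seed, {
    passes <- list()
    repeat {
      passes[[length(passes) + 1L]] <-
        run_pass(observer, start_db = start_db, step_db = step_db, ...)
      np <- length(passes)
      if (np >= 2L) {
        a <- passes[[np - 1L]]$pass_threshold_db
        b <- passes[[np]]$pass_threshold_db
        if (isTRUE(all.equal(a, b))) {
          return(structure(list(passes = passes, final_threshold_db = b,
                                n_passes = np),
                           class = "threshold_result"))
        }
      }
      if (np >= max_passes) {
        cond <- structure(
          class = c("edahab_staircase_nonconvergence", "error", "condition"),
          list(message = sprintf(
            "no two consecutive passes agreed within %d passes", max_passes),
            call = sys.call(-1), passes = passes))
        stop(cond)
      }
    }
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %g dB after %d passes\n",
              x$final_threshold_db, x$n_passes))
  invisible(x)
}
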