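#' Prompt schedules for rest / movement / imagined-movement tasks
#'
#' A prompt schedule is the ground-truth task timeline of a session: a set of
#' non-overlapping, sorted intervals labelled `rest`, `movement` or
#' `imagined`, covering `[0, total_duration_s)`. Gaps between labelled
#' intervals are implicitly rest; [prompt_schedule()] materialises them so the
#' stored intervals always tile the session.
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `label`
#'   (character, one of `"rest"`, `"movement"`, `"imagined"`). Intervals must
#'   be non-overlapping, sorted and within `[0, total_duration_s]`.
#' @param total_duration_s total session length in seconds.
#' @return An object of class `prompt_schedule`: a list with `intervals`
#'   (gap-filled, tiling the session) and `total_duration_s`.
#' @seealso [make_prompt_schedule()] for randomised interleaved prompts.
#' @export
prompt_schedule <- function(intervals, total_duration_s) {
  assert_scalar_num(total_duration_s, "total_duration_s", lo = 1e-9)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            label = character(0), stringsAsFactors = FALSE)
  }
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(intervals))) {
    stop("`intervals` needs columns start_s, end_s, label", call. = FALSE)
  }
  intervals <- intervals[need]
  intervals$label <- as.character(intervals$label)
  bad <- setdiff(unique(intervals$label), c("rest", "movement", "imagined"))
  if (length(bad)) {
    stop("unknown interval label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(intervals)) {
    intervals <- intervals[order(intervals$start_s), , drop = FALSE]
    if (any(intervals$end_s <= intervals$start_s)) {
      stop("each interval must have end_s > start_s", call. = FALSE)
    }
    if (min(intervals$start_s) < -1e-9 ||
        max(intervals$end_s) > total_duration_s + 1e-9) {
      stop("intervals must lie within [0, total_duration_s]", call. = FALSE)
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start_s[-1L] < intervals$end_s[-nrow(intervals)] - 1e-9)) {
      stop("intervals overlap", call. = FALSE)
    }
  }
  out <- fill_rest_gaps(intervals, total_duration_s)
  structure(list(intervals = out, total_duration_s = total_duration_s),
            class = "prompt_schedule")
}

# Insert explicit rest intervals in the gaps so intervals tile the session.
fill_rest_gaps <- function(intervals, total_duration_s) {
  pieces <- list()
  cursor <- 0
  if (nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      if (intervals$start_s[i] > cursor + 1e-9) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          start_s = cursor, end_s = intervals$start_s[i], label = "rest",
          stringsAsFactors = FALSE)
      }
      pieces[[length(pieces) + 1L]] <- intervals[i, , drop = FALSE]
      cursor <- intervals$end_s[i]
    }
  }
  if (cursor < total_duration_s - 1e-9) {
    pieces[[length(pieces) + 1L]] <- data.frame(
      start_s = cursor, end_s = total_duration_s, label = "rest",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Generate an interleaved rest/movement prompt schedule
#'
#' Reproduces the prompted task used to calibrate and evaluate movement
#' decoders: movement prompts of various lengths interleaved with rest
#' periods. Movement durations are i.i.d. uniform on `duration_range_s`; the
#' remaining session time is split across the surrounding rest periods
#' (each at least `min_rest_s`). Optionally, some prompts are
#' imagined-movement prompts (motor imagery: cortical desynchronization
#' without overt movement).
#'
#' @param duration_s total session length (s), > 0.
#' @param n_movements number of movement prompts (>= 0).
#' @param duration_range_s length-2 numeric, min/max prompt duration (s).
#' @param seed integer seed; the schedule is a deterministic function of the
#'   arguments and the seed.
#' @param n_imagined number of the prompts to label `imagined` (taken from the
#'   end of the prompt sequence).
#' @param min_rest_s minimum rest period between prompts (s).
#' @return A [prompt_schedule()].
#' @examples
#' sched <- make_prompt_schedule(120, n_movements = 5,
#'                               duration_range_s = c(5, 10), seed = 7)
#' subset(sched$intervals, label == "movement")
#' @export
make_prompt_schedule <- function(duration_s, n_movements, duration_range_s,
                                 seed, n_imagined = 0, min_rest_s = 2) {
  assert_scalar_num(duration_s, "duration_s", lo = 1e-9)
  assert_scalar_num(n_movements, "n_movements", lo = 0)
  assert_scalar_num(n_imagined, "n_imagined", lo = 0, hi = n_movements)
  n <- as.integer(n_movements)
  if (n == 0L) {
    return(prompt_schedule(NULL, duration_s))
  }
  if (length(duration_range_s) != 2L || any(!is.finite(duration_range_s)) ||
      duration_range_s[1] <= 0 || duration_range_s[2] < duration_range_s[1] ||
      duration_range_s[2] >= duration_s) {
    stop("`duration_range_s` must be an increasing pair within (0, duration_s)",
         call. = FALSE)
  }
  # Feasibility is checked against the worst draw so it never depends on the seed.
  if (n * duration_range_s[2] + (n + 1) * min_rest_s > duration_s) {
    stop(sprintf(
      "infeasible packing: %d prompts of up to %g s plus %g s rests exceed %g s",
      n, duration_range_s[2], min_rest_s, duration_s), call. = FALSE)
  }
  res <- with_seed(sub_seed(seed, "schedule"), {
    durs <- runif(n, duration_range_s[1], duration_range_s[2])
    slack <- duration_s - sum(durs) - (n + 1) * min_rest_s
    w <- runif(n + 1)
    gaps <- min_rest_s + slack * w / sum(w)
    starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(durs[-n]))
    list(starts = starts, durs = durs)
  })
  label <- rep("movement", n)
  if (n_imagined > 0) label[seq.int(n - n_imagined + 1L, n)] <- "imagined"
  prompt_schedule(
    data.frame(start_s = res$starts, end_s = res$starts + res$durs,
               label = label, stringsAsFactors = FALSE),
    duration_s)
}

#' Look up schedule labels at given times
#'
#' @param schedule a [prompt_schedule()].
#' @param times_s numeric vector of times (s).
#' @return character vector of labels (`rest` outside any interval).
#' @export
schedule_labels <- function(schedule, times_s) {
  stopifnot(inherits(schedule, "prompt_schedule"))
  iv <- schedule$intervals
  lab <- rep("rest", length(times_s))
  for (i in seq_len(nrow(iv))) {
    sel <- times_s >= iv$start_s[i] & times_s < iv$end_s[i]
    lab[sel] <- iv$label[i]
  }
  lab
}

#' @export
print.prompt_schedule <- function(x, ...) {
  tab <- table(x$intervals$label)
  cat(sprintf("<prompt_schedule> %.1f s, %s\n", x$total_duration_s,
              paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
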