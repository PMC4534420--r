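#' PCASL acquisition protocol
#'
#' A protocol bundles the timing parameters of one background-suppressed
#' PCASL acquisition: labeling duration (LD), post-labeling delay (PLD),
#' repetition time (TR), the two background-suppression inversion pulse
#' times (measured from the start of the labeling train), and the number
#' of label/control pairs acquired (NSA).
#'
#' @param label_duration Labeling duration in ms.
#' @param post_label_delay Post-labeling delay in ms.
#' @param repetition_time Repetition time in ms (one volume per TR, so a
#'   label/control pair takes `2 * repetition_time`).
#' @param bs1_time,bs2_time Times of the two background-suppression
#'   inversion pulses in ms; must satisfy
#'   `bs1_time < bs2_time < label_duration + post_label_delay`.
#' @param n_pairs Number of label/control pairs (NSA); at least 1.
#' @param name Optional protocol label.
#' @return An object of class `asl_protocol`.
#' @examples
#' p <- asl_protocol(2150, 1500, 4000, 2390, 3366, n_pairs = 400)
#' scan_time_minutes(p)
#' @export
asl_protocol <- function(label_duration, post_label_delay, repetition_time,
                         bs1_time, bs2_time, n_pairs = 400L,
                         name = NULL) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
    as.numeric(x)
  }
  label_duration <- num1(label_duration, "label_duration")
  post_label_delay <- num1(post_label_delay, "post_label_delay")
  repetition_time <- num1(repetition_time, "repetition_time")
  bs1_time <- num1(bs1_time, "bs1_time")
  bs2_time <- num1(bs2_time, "bs2_time")
  n_pairs <- num1(n_pairs, "n_pairs")
  if (any(c(label_duration, post_label_delay, repetition_time,
            bs1_time, bs2_time) <= 0))
    stop("all protocol durations must be positive", call. = FALSE)
  if (n_pairs < 1 || n_pairs != round(n_pairs))
    stop("'n_pairs' must be an integer >= 1", call. = FALSE)
  if (!(bs1_time < bs2_time && bs2_time < label_duration + post_label_delay))
    stop("background-suppression pulses must satisfy ",
         "bs1_time < bs2_time < label_duration + post_label_delay",
         call. = FALSE)
  structure(
    list(label_duration = label_duration,
         post_label_delay = post_label_delay,
         repetition_time = repetition_time,
         bs1_time = bs1_time,
         bs2_time = bs2_time,
         n_pairs = as.integer(n_pairs),
         name = name),
    class = "asl_protocol")
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat(sprintf("PCASL protocol%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'")))
  cat(sprintf("  LD %g ms, PLD %g ms, TR %g ms, BS %g/%g ms, NSA %d\n",
              x$label_duration, x$post_label_delay, x$repetition_time,
              x$bs1_time, x$bs2_time, x$n_pairs))
  cat(sprintf("  scan time %.1f min\n", scan_time_minutes(x)))
  invisible(x)
}

# The four acquisition schemes of the study design, NSA = 400 each.
.protocol_presets <- list(
  exp1 = list(ld = 1650, pld = 1500, tr = 3500, bs1 = 1672, bs2 = 2803),
  exp2 = list(ld = 1650, pld = 2000, tr = 4000, bs1 = 1671, bs2 = 3164),
  exp3 = list(ld = 2150, pld = 1500, tr = 4000, bs1 = 2390, bs2 = 3366),
  exp4 = list(ld = 2150, pld = 1000, tr = 3500, bs1 = 2261, bs2 = 2989)
)

#' Built-in protocol presets
#'
#' The four LD/PLD variants of the acquisition scheme (all with 400
#' label/control pairs): `exp1` = 1650/1500 (TR 3500), `exp2` = 1650/2000
#' (TR 4000), `exp3` = 2150/1500 (TR 4000), `exp4` = 2150/1000 (TR 3500).
#' `exp3` is the WM-optimized variant used for the threshold-sensitivity
#' and sub-mask analyses.
#'
#' @param which Preset id, one of `"exp1" ... "exp4"`.
#' @param n_pairs Number of label/control pairs (default 400).
#' @return An `asl_protocol`.
#' @examples
#' protocol_preset("exp3")
#' @export
protocol_preset <- function(which = c("exp1", "exp2", "exp3", "exp4"),
                            n_pairs = 400L) {
  which <- match.arg(which)
  p <- .protocol_presets[[which]]
  asl_protocol(p$ld, p$pld, p$tr, p$bs1, p$bs2, n_pairs = n_pairs,
               name = which)
}

#' Total scan time of a protocol
#'
#' The full acquisition takes `n_pairs * 2 * repetition_time`.  The
#' table-facing value is truncated (not rounded) to one decimal place:
#' 400 pairs at TR 3500 ms is 2800 s = 46.67 min, printed as 46.6.
#'
#' @param protocol An `asl_protocol`.
#' @param truncate Truncate to one decimal place (default `TRUE`); set
#'   `FALSE` for the exact value.
#' @return Scan time in minutes.
#' @seealso [nsa_to_minutes()] for partial-acquisition times.
#' @export
scan_time_minutes <- function(protocol, truncate = TRUE) {
  stopifnot(inherits(protocol, "asl_protocol"))
  mins <- protocol$n_pairs * 2 * protocol$repetition_time / 60000
  if (truncate) trunc(mins * 10) / 10 else mins
}

#' Scan time needed for a given number of signal averages
#'
#' Maps an NSA prefix (number of label/control pairs kept) to wall-clock
#' scan time, unrounded: `nsa * 2 * repetition_time` in minutes.
#'
#' @param nsa Number of pairs, between 1 and `protocol$n_pairs`;
#'   vectorized.
#' @param protocol An `asl_protocol`.
#' @return Minutes of scanning (numeric, same length as `nsa`).
#' @export
nsa_to_minutes <- function(nsa, protocol) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (any(!is.finite(nsa)) || any(nsa < 1) || any(nsa > protocol$n_pairs) ||
      any(nsa != round(nsa)))
    stop("'nsa' must be whole numbers in [1, n_pairs]", call. = FALSE)
  nsa * 2 * protocol$repetition_time / 60000
}

#' Summarize protocols as a characteristics table
#'
#' Returns one row per protocol with LD, PLD, TR, the two BS pulse times,
#' scan time (truncated to one decimal), and appends the total scan time
#' across protocols in whole minutes (each protocol's time floored to a
#' whole minute before summing, the convention used when quoting a
#' per-subject session total such as 2x46 + 2x53 = 198 min).
#'
#' @param protocols A list of `asl_protocol` objects; defaults to the
#'   four presets.
#' @return A list with `table` (data.frame) and `total_minutes`.
#' @examples
#' protocol_table()$total_minutes  # 198
#' @export
protocol_table <- function(protocols = lapply(c("exp1", "exp2", "exp3",
                                                "exp4"), protocol_preset)) {
  stopifnot(length(protocols) >= 1,
            all(vapply(protocols, inherits, TRUE, "asl_protocol")))
  tab <- data.frame(
    experiment = vapply(seq_along(protocols), function(i) {
      nm <- protocols[[i]]$name
      if (is.null(nm)) as.character(i) else nm
    }, character(1)),
    ld_ms = vapply(protocols, `[[`, 0, "label_duration"),
    pld_ms = vapply(protocols, `[[`, 0, "post_label_delay"),
    tr_ms = vapply(protocols, `[[`, 0, "repetition_time"),
    bs1_ms = vapply(protocols, `[[`, 0, "bs1_time"),
    bs2_ms = vapply(protocols, `[[`, 0, "bs2_time"),
    nsa = vapply(protocols, function(p) as.numeric(p$n_pairs), 0),
    scan_time_min = vapply(protocols, scan_time_minutes, 0)
  )
  total <- sum(floor(vapply(protocols, scan_time_minutes, 0,
                            truncate = FALSE)))
  list(table = tab, total_minutes = total)
}
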