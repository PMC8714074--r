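# Maximal-length shift-register sequences (m-sequences).
#
# An order-n m-sequence is the +/-1-mapped output of a Fibonacci LFSR whose
# feedback taps form a primitive polynomial over GF(2). One period has length
# 2^n - 1, contains 2^(n-1) values of +1 and 2^(n-1) - 1 values of -1, every
# circular subword of length n exactly once (the all -1 word never occurs),
# and is closed under the shift-and-multiply property. These sequences set
# the polarity of each stimulus impulse in the reverse-correlation protocol.

# Primitive feedback polynomials (Fibonacci taps, highest stage included) for
# the supported orders. Several choices per order where convenient so that
# random draws can vary the polynomial as well as the state and phase.
.mseq_catalog <- list(
  `2`  = list(c(2L, 1L)),
  `3`  = list(c(3L, 2L), c(3L, 1L)),
  `4`  = list(c(4L, 3L), c(4L, 1L)),
  `5`  = list(c(5L, 3L), c(5L, 2L)),
  `6`  = list(c(6L, 5L), c(6L, 1L)),
  `7`  = list(c(7L, 6L), c(7L, 3L), c(7L, 1L)),
  `8`  = list(c(8L, 6L, 5L, 4L), c(8L, 6L, 5L, 3L), c(8L, 7L, 6L, 1L)),
  `9`  = list(c(9L, 5L), c(9L, 4L)),
  `10` = list(c(10L, 7L), c(10L, 3L)),
  `11` = list(c(11L, 9L), c(11L, 2L)),
  `12` = list(c(12L, 6L, 4L, 1L)),
  `13` = list(c(13L, 4L, 3L, 1L)),
  `14` = list(c(14L, 5L, 3L, 1L)),
  `15` = list(c(15L, 14L), c(15L, 1L), c(15L, 4L)),
  `16` = list(c(16L, 15L, 13L, 4L))
)

#' Supported m-sequence orders
#'
#' Orders for which a primitive feedback polynomial is available in the
#' built-in catalog.
#'
#' @return Integer vector of supported register orders.
#' @export
msequence_orders <- function() as.integer(names(.mseq_catalog))

# Run a Fibonacci LFSR for one full period; error if the tap set is not
# maximal (period < 2^n - 1). Output is taken from the last register stage.
.lfsr_period <- function(order, taps, state) {
  n_states <- 2L^order - 1L
  out <- integer(n_states)
  st <- state
  enc0 <- sum(state * 2^(seq_len(order) - 1))
  for (i in seq_len(n_states)) {
    out[i] <- st[order]
    fb <- sum(st[taps]) %% 2L
    st <- c(fb, st[-order])
    if (sum(st * 2^(seq_len(order) - 1)) == enc0 && i < n_states) {
      stop(sprintf(
        "taps {%s} are not primitive for order %d: observed period %d < %d",
        paste(taps, collapse = ","), order, i, n_states
      ), call. = FALSE)
    }
  }
  out
}

#' Generate an m-sequence from explicit LFSR taps
#'
#' Runs a Fibonacci linear-feedback shift register of the given order for one
#' full period and maps register output bits to stimulus polarities
#' (`1 -> +1`, `0 -> -1`). The tap set must describe a primitive feedback
#' polynomial: if the observed state period is shorter than `2^order - 1`
#' an error reports the observed period.
#'
#' @param order Register length `n >= 2`.
#' @param taps Integer vector of register stages fed back through XOR; must
#'   include `order` (the polynomial has degree `order`).
#' @param initial_state Bit vector (0/1) of length `order`, not all zero.
#'   Defaults to all ones.
#' @param label Optional provenance label stored with the sequence.
#' @return An object of class `msequence` with fields `order`, `taps`,
#'   `initial_state`, `phase` and `values` (one full period of +/-1).
#' @examples
#' m <- generate_msequence(3, c(3, 2))
#' m$values # +1 +1 +1 -1 -1 +1 -1
#' @export
generate_msequence <- function(order, taps, initial_state = rep(1L, order),
                               label = NULL) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 2L)
    stop("'order' must be a single integer >= 2", call. = FALSE)
  taps <- sort(unique(as.integer(taps)), decreasing = TRUE)
  if (any(taps < 1L) || any(taps > order))
    stop("'taps' must be register stages in 1..order", call. = FALSE)
  if (!(order %in% taps))
    stop("'taps' must include the highest stage (degree = order)", call. = FALSE)
  initial_state <- as.integer(initial_state)
  if (length(initial_state) != order || !all(initial_state %in% c(0L, 1L)))
    stop("'initial_state' must be a 0/1 vector of length 'order'", call. = FALSE)
  if (all(initial_state == 0L))
    stop("'initial_state' must not be all zero", call. = FALSE)
  bits <- .lfsr_period(order, taps, initial_state)
  structure(list(
    order = order,
    taps = taps,
    initial_state = initial_state,
    phase = 0L,
    label = label,
    values = ifelse(bits == 1L, 1L, -1L)
  ), class = "msequence")
}

#' Draw a random m-sequence
#'
#' Draws a primitive polynomial from the built-in catalog, a random nonzero
#' initial state, and a random circular phase. Randomness comes from R's
#' global RNG stream, so results are reproducible under [set.seed()].
#'
#' @param order Register order, one of [msequence_orders()].
#' @param label Optional provenance label.
#' @return An `msequence` object (see [generate_msequence()]); `phase` records
#'   the applied circular shift.
#' @export
random_msequence <- function(order, label = NULL) {
  order <- as.integer(order)
  key <- as.character(order)
  if (!key %in% names(.mseq_catalog))
    stop(sprintf("order %d not in the supported catalog (%s)", order,
                 paste(range(msequence_orders()), collapse = "-")), call. = FALSE)
  polys <- .mseq_catalog[[key]]
  taps <- polys[[sample.int(length(polys), 1L)]]
  repeat {
    state <- sample(c(0L, 1L), order, replace = TRUE)
    if (any(state == 1L)) break
  }
  m <- generate_msequence(order, taps, state, label = label)
  n <- length(m$values)
  phase <- sample.int(n, 1L) - 1L
  if (phase > 0L)
    m$values <- c(m$values[(phase + 1L):n], m$values[seq_len(phase)])
  m$phase <- phase
  m
}

.rotate <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0L) x else c(x[(k + 1L):n], x[seq_len(k)])
}

#' Verify the defining properties of an m-sequence
#'
#' Checks a +/-1 vector against the three defining m-sequence properties:
#' balance (`2^(n-1)` values of +1 and one fewer -1), uniqueness of all
#' circular subwords of length `n` (with the all -1 subword absent), and
#' closure of the elementwise product with every nonzero circular shift
#' (the product is again a circular shift of the sequence).
#'
#' A vector whose length is not of the form `2^n - 1` fails with a reason
#' rather than raising an error.
#'
#' @param values Vector of +1/-1 values (one putative period).
#' @return A list with logical fields `balance`, `subword_unique`,
#'   `shift_product`, `pass`, and a character `reason` ("" when `pass`).
#' @export
verify_msequence <- function(values) {
  if (inherits(values, "msequence")) values <- values$values
  fail <- function(reason) list(balance = FALSE, subword_unique = FALSE,
                                shift_product = FALSE, pass = FALSE,
                                reason = reason)
  if (!all(values %in% c(-1, 1)))
    return(fail("values must contain only -1 and +1"))
  len <- length(values)
  order <- round(log2(len + 1))
  if (order < 2 || 2^order - 1 != len)
    return(fail(sprintf("length %d is not of the form 2^n - 1", len)))
  values <- as.integer(values)
  balance <- sum(values == 1L) == 2L^(order - 1L) &&
    sum(values == -1L) == 2L^(order - 1L) - 1L
  # circular subwords of length n, encoded as integers
  ext <- c(values, values[seq_len(order - 1L)])
  bits <- as.integer(ext == 1L)
  codes <- vapply(seq_len(len), function(i) {
    sum(bits[i:(i + order - 1L)] * 2^(0:(order - 1L)))
  }, numeric(1))
  subword_unique <- !anyDuplicated(codes) && !any(codes == 0)
  # Shift-product closure via substring search in the doubled sequence.
  # Under the bit->sign map 1 -> +1 (which gives the stated +1/-1 balance)
  # the elementwise product with a shifted copy equals a time-shifted copy
  # of the sequence with *flipped* signs; under the opposite map it equals a
  # time-shifted copy directly. Both conventions are accepted here.
  chars <- paste(ifelse(values == 1L, "1", "0"), collapse = "")
  doubled <- paste0(chars, chars)
  neg_doubled <- paste0(chartr("01", "10", chars), chartr("01", "10", chars))
  shift_product <- TRUE
  for (s in seq_len(len - 1L)) {
    prod <- values * .rotate(values, s)
    pstr <- paste(ifelse(prod == 1L, "1", "0"), collapse = "")
    if (!grepl(pstr, doubled, fixed = TRUE) &&
        !grepl(pstr, neg_doubled, fixed = TRUE)) {
      shift_product <- FALSE
      break
    }
  }
  pass <- balance && subword_unique && shift_product
  list(balance = balance, subword_unique = subword_unique,
       shift_product = shift_product, pass = pass,
       reason = if (pass) "" else "one or more m-sequence properties failed")
}

#' Extend an m-sequence by circular tiling
#'
#' Repeats the period circularly up to `total_length`, so that the final
#' `2^n - 1` entries always form exactly one full period (a circular shift of
#' the original). The recording protocol extends order-8 sequences to 400
#' impulses and analyses only the final 255, discarding onset transients.
#'
#' @param mseq An `msequence` object or a +/-1 period vector.
#' @param total_length Target length, `>=` the period length (default 400).
#' @return Integer vector of +/-1 of length `total_length`.
#' @export
extend_circular <- function(mseq, total_length = 400L) {
  values <- if (inherits(mseq, "msequence")) mseq$values else as.integer(mseq)
  n <- length(values)
  total_length <- as.integer(total_length)
  if (total_length < n)
    stop(sprintf("total_length (%d) must be >= the period length (%d)",
                 total_length, n), call. = FALSE)
  # final n entries must be the LAST contiguous window of the periodic
  # extension ending at the period boundary, i.e. start the tiling so that
  # position total_length lines up with the end of a period
  offset <- (n - (total_length %% n)) %% n
  values[((seq_len(total_length) - 1L + offset) %% n) + 1L]
}

#' @export
print.msequence <- function(x, ...) {
  cat(sprintf("m-sequence: order %d, period %d, taps {%s}, phase %d\n",
              x$order, length(x$values), paste(x$taps, collapse = ","),
              x$phase))
  cat(sprintf("  +1: %d, -1: %d\n", sum(x$values == 1L), sum(x$values == -1L)))
  invisible(x)
}

#' Write / read an m-sequence
#'
#' CSV stores one signed value per row (column `value`); JSON additionally
#' stores provenance (order, taps, initial state, phase, label).
#'
#' @param mseq An `msequence` object.
#' @param path Output file path; format inferred from the `.csv`/`.json`
#'   extension.
#' @return `write_msequence()` returns `path` invisibly; `read_msequence()`
#'   returns an `msequence` (JSON) or a bare +/-1 vector (CSV).
#' @export
write_msequence <- function(mseq, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      order = mseq$order, taps = mseq$taps,
      initial_state = mseq$initial_state, phase = mseq$phase,
      label = mseq$label, values = mseq$values
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(value = mseq$values), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_msequence
#' @export
read_msequence <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(
      order = as.integer(x$order), taps = as.integer(x$taps),
      initial_state = as.integer(x$initial_state),
      phase = as.integer(x$phase),
      label = if (is.null(x$label)) NULL else x$label,
      values = as.integer(x$values)
    ), class = "msequence")
  } else {
    as.integer(utils::read.csv(path)$value)
  }
}
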