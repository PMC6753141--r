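#' Cohort generator configuration
#'
#' Median component values and inter-subject/inter-finger dispersion for the
#' synthetic cohort. No component values are published for real fingers, so
#' the medians are order-of-magnitude-plausible tissue values: interface and
#' tissue resistances of 1e2--1e3 ohm and membrane capacitances of a few to
#' tens of nanofarad. Dispersion is the log-normal `sdlog` applied
#' independently to every component of every finger, which is what makes
#' subjects (and fingers within a subject) electrically distinct.
#'
#' @param epi,dermis,sweat named numeric vectors `c(Rs=, Rp=, Cp=)` of median
#'   component values (ohms, ohms, farads) for the electrode/epidermis,
#'   dermis and sweat-duct blocks.
#' @param body_resistance median series body resistance, ohms, absorbed into
#'   the interior section of each pair circuit.
#' @param dispersion log-normal `sdlog` for all component draws (>= 0).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(epi = c(Rs = 300, Rp = 2000, Cp = 20e-9),
                          dermis = c(Rs = 150, Rp = 1000, Cp = 10e-9),
                          sweat = c(Rs = 500, Rp = 5000, Cp = 5e-9),
                          body_resistance = 100,
                          dispersion = 0.35) {
  for (nm in c("epi", "dermis", "sweat")) {
    v <- get(nm)
    if (!all(c("Rs", "Rp", "Cp") %in% names(v)) || any(v <= 0) ||
        any(!is.finite(v)))
      stop("'", nm, "' must be positive c(Rs=, Rp=, Cp=)", call. = FALSE)
  }
  if (body_resistance <= 0) stop("body_resistance must be > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  structure(list(epi = epi, dermis = dermis, sweat = sweat,
                 body_resistance = body_resistance, dispersion = dispersion),
            class = "cohort_config")
}

#' Sample one subject's stable anatomy
#'
#' Draws, for each of the five fingers, an electrode/epidermis, a dermis and
#' a sweat-duct Z-block, plus a body resistance, all log-normally around the
#' configured medians. These parameters are the subject's identity: they stay
#' fixed across sessions while session drift and noise move around them.
#'
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param config a [cohort_config()].
#' @return A list of class `subject_template` with elements `fingers` (list
#'   of 5, each with `epi`, `dermis`, `sweat` [z_block()]s) and
#'   `body_resistance`.
#' @export
sample_subject <- function(seed, config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config", call. = FALSE)
  set.seed(as.integer(seed))
  draw <- function(med) stats::rlnorm(1L, meanlog = log(med),
                                      sdlog = config$dispersion)
  fingers <- lapply(1:5, function(i) {
    blocks <- lapply(c("epi", "dermis", "sweat"), function(layer) {
      m <- config[[layer]]
      z_block(Rs = draw(m[["Rs"]]), Rp = draw(m[["Rp"]]), Cp = draw(m[["Cp"]]))
    })
    names(blocks) <- c("epi", "dermis", "sweat")
    blocks
  })
  structure(list(fingers = fingers,
                 body_resistance = draw(config$body_resistance)),
            class = "subject_template")
}

#' Build a finger-pair circuit from a subject template
#'
#' Wires the two fingers' half-circuits into the four-block pair circuit:
#' `z1`/`z4` are the two fingers' electrode/epidermis blocks; the interior
#' dermis path `z2` merges both fingers' dermis blocks in series (resistances
#' add, capacitances combine in series) with the body resistance absorbed
#' into its series arm; the sweat path `z3` merges the two sweat blocks the
#' same way. Pairs sharing a finger therefore share that finger's parameters
#' exactly, which induces realistic correlation between pair spectra.
#'
#' @param tmpl a [sample_subject()] template.
#' @param a,b finger indices, `1 <= a < b <= 5`.
#' @return A [pair_circuit()].
#' @export
pair_circuit_from_template <- function(tmpl, a, b) {
  if (!inherits(tmpl, "subject_template"))
    stop("'tmpl' must be a subject_template", call. = FALSE)
  pair_index(a, b)  # validates
  fa <- tmpl$fingers[[a]]
  fb <- tmpl$fingers[[b]]
  series <- function(x, y, extra_rs = 0) {
    z_block(Rs = x$Rs + y$Rs + extra_rs,
            Rp = x$Rp + y$Rp,
            Cp = x$Cp * y$Cp / (x$Cp + y$Cp))
  }
  pair_circuit(z1 = fa$epi,
               z2 = series(fa$dermis, fb$dermis, tmpl$body_resistance),
               z3 = series(fa$sweat, fb$sweat),
               z4 = fb$epi)
}

#' Session state scale from drift and hand temperature
#'
#' Impedance varies inversely with hand temperature and drifts from day to
#' day even at fixed temperature; both effects are common-mode across all
#' finger pairs. The session scale is `s = drift * (1 + gamma * (t_ref - T))`:
#' monotonically decreasing in temperature, equal to `drift` at the
#' reference temperature.
#'
#' @param temperature hand temperature, degrees Celsius.
#' @param drift session-level multiplicative drift factor (> 0).
#' @param gamma temperature coefficient per degree Celsius (>= 0).
#' @param t_ref reference temperature, degrees Celsius.
#' @return The scalar state scale `s` (> 0).
#' @export
session_scale <- function(temperature, drift = 1, gamma = 0.02, t_ref = 33) {
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  if (drift <= 0) stop("'drift' must be > 0", call. = FALSE)
  s <- drift * (1 + gamma * (t_ref - temperature))
  if (any(s <= 0))
    stop("temperature/gamma combination yields non-positive state scale",
         call. = FALSE)
  s
}

#' Generate a labelled synthetic cohort of impedance spectra
#'
#' Emulates the structure of a multi-session acquisition campaign: each
#' subject has stable circuit parameters; each (subject, session) draws a
#' log-normal common-mode drift and a hand temperature, combined by
#' [session_scale()] into one multiplicative factor applied to all 10 pair
#' spectra; each individual placement additionally multiplies every pair's
#' spectrum by `exp(eps)`, `eps ~ N(0, noise_sigma^2)` drawn independently
#' per record and pair (re-placement/contact variation).
#'
#' @param n_subjects,n_sessions,n_repeats cohort geometry
#'   (`n_subjects >= 2`, `n_sessions >= 2`, `n_repeats >= 1`). The study
#'   being emulated used 41 subjects over at least 5 sessions with 8--10
#'   placements each.
#' @param drift_sigma `sdlog` of the session drift factor (>= 0).
#' @param noise_sigma standard deviation of per-placement log-noise (>= 0).
#' @param drift_heterogeneity `sdlog` of an optional per-pair perturbation
#'   of each session's drift (>= 0). The default 0 keeps drift perfectly
#'   common-mode (the premise of the ratio transform); positive values
#'   break that premise so its robustness can be studied.
#' @param gamma,t_ref temperature model, see [session_scale()].
#' @param temp_range range hand temperatures are drawn from uniformly,
#'   degrees Celsius.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @param config a [cohort_config()].
#' @param grid frequency grid, hertz.
#' @return An object of class `spectra_dataset`: list with `meta` (data frame
#'   `subject_id`, `session_id`, `repeat_index`, `temperature`), `spectra`
#'   (array `records x 10 pairs x frequencies` of `|Z|` in ohms), `grid`,
#'   and `pairs` ([finger_pairs()]).
#' @export
generate_dataset <- function(n_subjects = 41, n_sessions = 5, n_repeats = 10,
                             drift_sigma = 0.2, noise_sigma = 0.02,
                             drift_heterogeneity = 0,
                             gamma = 0.02, t_ref = 33,
                             temp_range = c(29, 37),
                             seed = 1, config = cohort_config(),
                             grid = frequency_grid()) {
  if (n_subjects < 2 || n_sessions < 2 || n_repeats < 1)
    stop("need n_subjects >= 2, n_sessions >= 2, n_repeats >= 1",
         call. = FALSE)
  if (drift_sigma < 0 || noise_sigma < 0 || drift_heterogeneity < 0)
    stop("drift_sigma, noise_sigma and drift_heterogeneity must be >= 0",
         call. = FALSE)
  seed <- as.integer(seed)
  fp <- finger_pairs()
  n_pairs <- nrow(fp)
  n_freq <- length(grid)

  # stable per-subject anatomy, each from its own derived seed
  base_spectra <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    tmpl <- sample_subject((seed + 7919L * i) %% .Machine$integer.max, config)
    m <- matrix(0, n_pairs, n_freq)
    for (p in seq_len(n_pairs))
      m[p, ] <- pair_impedance(
        pair_circuit_from_template(tmpl, fp$a[p], fp$b[p]), grid)
    base_spectra[[i]] <- m
  }

  set.seed(seed)
  n_rec <- n_subjects * n_sessions * n_repeats
  spectra <- array(0, dim = c(n_rec, n_pairs, n_freq),
                   dimnames = list(NULL, fp$label,
                                   format(grid, scientific = FALSE,
                                          trim = TRUE)))
  meta <- data.frame(subject_id = character(n_rec),
                     session_id = character(n_rec),
                     repeat_index = integer(n_rec),
                     temperature = numeric(n_rec),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n_subjects)) {
    for (ses in seq_len(n_sessions)) {
      drift <- stats::rlnorm(1L, 0, drift_sigma)
      temp <- stats::runif(1L, temp_range[1L], temp_range[2L])
      s <- session_scale(temp, drift = drift, gamma = gamma, t_ref = t_ref)
      # scale_state multiplies the whole spectrum by s exactly, so the
      # session effect is applied as a single multiplicative factor
      s_pair <- s * stats::rlnorm(n_pairs, 0, drift_heterogeneity)
      sess_spec <- base_spectra[[i]] * s_pair
      for (r in seq_len(n_repeats)) {
        row <- row + 1L
        eps <- stats::rnorm(n_pairs, 0, noise_sigma)
        spectra[row, , ] <- sess_spec * exp(eps)
        meta$subject_id[row] <- sprintf("S%02d", i)
        meta$session_id[row] <- sprintf("D%02d", ses)
        meta$repeat_index[row] <- r
        meta$temperature[row] <- temp
      }
    }
  }
  new_spectra_dataset(meta, spectra, grid, fp)
}

new_spectra_dataset <- function(meta, spectra, grid, pairs = finger_pairs()) {
  stopifnot(nrow(meta) == dim(spectra)[1L],
            dim(spectra)[2L] == nrow(pairs),
            dim(spectra)[3L] == length(grid))
  key <- paste(meta$subject_id, meta$session_id, meta$repeat_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, session, repeat) keys", call. = FALSE)
  if (any(spectra <= 0))
    stop("all impedance magnitudes must be > 0", call. = FALSE)
  structure(list(meta = meta, spectra = spectra, grid = grid, pairs = pairs),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(
    "Impedance spectra dataset: %d records (%d subjects, %d sessions)\n",
    nrow(x$meta), length(unique(x$meta$subject_id)),
    length(unique(paste(x$meta$subject_id, x$meta$session_id)))))
  cat(sprintf("  %d finger pairs x %d frequencies (%.0f-%.0f kHz)\n",
              nrow(x$pairs), length(x$grid),
              min(x$grid) / 1e3, max(x$grid) / 1e3))
  invisible(x)
}

#' @export
as.data.frame.spectra_dataset <- function(x, ...) {
  n_rec <- nrow(x$meta)
  n_pairs <- nrow(x$pairs)
  n_freq <- length(x$grid)
  rec <- rep(seq_len(n_rec), times = n_pairs * n_freq)
  p <- rep(rep(seq_len(n_pairs), each = n_rec), times = n_freq)
  f <- rep(seq_len(n_freq), each = n_rec * n_pairs)
  out <- data.frame(subject_id = x$meta$subject_id[rec],
                    session_id = x$meta$session_id[rec],
                    repeat_index = x$meta$repeat_index[rec],
                    temperature_C = x$meta$temperature[rec],
                    finger_a = x$pairs$a[p],
                    finger_b = x$pairs$b[p],
                    frequency_hz = as.integer(x$grid[f]),
                    impedance_ohm = x$spectra[cbind(rec, p, f)],
                    stringsAsFactors = FALSE)
  out[order(rec, p, f), , drop = FALSE]
}

# number of records
n_records <- function(ds) nrow(ds$meta)

# one record's 10 x 25 magnitude matrix
record_spectra <- function(ds, i) ds$spectra[i, , , drop = TRUE]
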