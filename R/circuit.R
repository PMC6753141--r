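#' Z-block circuit element
#'
#' Constructs the three-element RC motif used throughout the finger-pair
#' impedance model: a series resistance `Rs` (extracellular fluid, plus skin
#' resistance for the electrode-interface blocks) in series with a parallel
#' combination of `Rp` (intracellular fluid) and `Cp` (cell-membrane
#' capacitance).
#'
#' @param Rs series resistance, ohms (> 0).
#' @param Rp parallel resistance, ohms (> 0).
#' @param Cp parallel capacitance, farads (> 0).
#' @return An object of class `z_block`.
#' @examples
#' z_block(Rs = 100, Rp = 1000, Cp = 10e-9)
#' @export
z_block <- function(Rs, Rp, Cp) {
  for (nm in c("Rs", "Rp", "Cp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  structure(list(Rs = Rs, Rp = Rp, Cp = Cp), class = "z_block")
}

#' @export
print.z_block <- function(x, ...) {
  cat(sprintf("Z-block: Rs = %.4g ohm, Rp = %.4g ohm, Cp = %.4g F\n",
              x$Rs, x$Rp, x$Cp))
  invisible(x)
}

#' Complex impedance of one Z-block
#'
#' Evaluates `Rs + Rp / (1 + i 2 pi f Rp Cp)`. At DC this is `Rs + Rp`
#' (the capacitor is open); as `f` grows it tends to `Rs` (the capacitor
#' shorts the intracellular branch), so the magnitude is strictly decreasing
#' in frequency.
#'
#' @param params a [z_block()].
#' @param f frequency in hertz, a non-negative numeric vector.
#' @return Complex impedance in ohms, same length as `f`.
#' @export
z_block_impedance <- function(params, f) {
  params <- as_z_block(params)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0))
    stop("'f' must be finite and non-negative", call. = FALSE)
  params$Rs + params$Rp / (1 + 2i * pi * f * params$Rp * params$Cp)
}

as_z_block <- function(x) {
  if (inherits(x, "z_block")) return(x)
  if (is.list(x) && all(c("Rs", "Rp", "Cp") %in% names(x)))
    return(z_block(x$Rs, x$Rp, x$Cp))
  stop("cannot interpret object as a z_block", call. = FALSE)
}

#' Finger-pair equivalent circuit
#'
#' A pair of fingers spans four Z-blocks: the two electrode/epidermis
#' interfaces `z1` and `z4` in series with an interior section in which the
#' dermis path `z2` lies in parallel with the sweat-gland/duct path `z3`
#' (sweat ducts shunt the deeper tissue, as in the standard electrode-skin
#' equivalent circuit).
#'
#' @param z1 electrode/epidermis block, current-source side ([z_block()]).
#' @param z2 dermis block.
#' @param z3 sweat-gland/duct block.
#' @param z4 electrode/epidermis block, current-drain side.
#' @return An object of class `pair_circuit`.
#' @export
pair_circuit <- function(z1, z2, z3, z4) {
  structure(list(z1 = as_z_block(z1), z2 = as_z_block(z2),
                 z3 = as_z_block(z3), z4 = as_z_block(z4)),
            class = "pair_circuit")
}

#' @export
print.pair_circuit <- function(x, ...) {
  cat("Finger-pair circuit: Z1 + (Z2 || Z3) + Z4\n")
  for (nm in c("z1", "z2", "z3", "z4")) {
    b <- x[[nm]]
    cat(sprintf("  %s: Rs = %.4g, Rp = %.4g ohm, Cp = %.4g F\n",
                nm, b$Rs, b$Rp, b$Cp))
  }
  invisible(x)
}

#' Measurement frequency grid
#'
#' The default grid mirrors the acquisition protocol: 20 kHz to 500 kHz in
#' 20 kHz steps, 25 points. Frequencies below 20 kHz are excluded because
#' contact pressure and skin hydration perturb them.
#'
#' @param fmin,fmax,fstep grid limits and step, hertz.
#' @return Strictly increasing numeric vector of frequencies (hertz).
#' @export
frequency_grid <- function(fmin = 20e3, fmax = 500e3, fstep = 20e3) {
  if (fmin <= 0 || fstep <= 0 || fmax < fmin)
    stop("invalid frequency grid", call. = FALSE)
  f <- seq(fmin, fmax, by = fstep)
  if (length(f) < 1L) stop("empty frequency grid", call. = FALSE)
  f
}

#' Impedance magnitude spectrum of a finger-pair circuit
#'
#' Complex sum `Z1(f) + (Z2(f) || Z3(f)) + Z4(f)`, returned as magnitudes.
#' The hardware being modelled records RMS voltage, so the observable is
#' `|Z|`, not phase.
#'
#' @param circuit a [pair_circuit()].
#' @param grid frequencies in hertz (strictly increasing), e.g.
#'   [frequency_grid()].
#' @return Numeric vector of `|Z|` in ohms, one per grid point, named by
#'   frequency.
#' @export
pair_impedance <- function(circuit, grid = frequency_grid()) {
  if (!inherits(circuit, "pair_circuit"))
    stop("'circuit' must be a pair_circuit", call. = FALSE)
  if (length(grid) == 0L)
    stop("empty frequency grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  z1 <- z_block_impedance(circuit$z1, grid)
  z2 <- z_block_impedance(circuit$z2, grid)
  z3 <- z_block_impedance(circuit$z3, grid)
  z4 <- z_block_impedance(circuit$z4, grid)
  ztot <- z1 + (z2 * z3) / (z2 + z3) + z4
  stats::setNames(Mod(ztot), format(grid, scientific = FALSE, trim = TRUE))
}

#' Common-mode state scaling of a circuit
#'
#' Scales every resistance by `s` and divides every capacitance by `s`,
#' emulating a physiological state in which all finger components change at
#' the same rate (temperature, hydration, blood flow). Because every `Rp*Cp`
#' product is preserved, the whole impedance spectrum scales exactly by `s`
#' at every frequency -- which is why ratios of two pair spectra are
#' invariant under such drift.
#'
#' @param circuit a [pair_circuit()].
#' @param s positive multiplicative state factor.
#' @return A new `pair_circuit` whose spectrum is `s` times the original.
#' @export
scale_state <- function(circuit, s) {
  if (!inherits(circuit, "pair_circuit"))
    stop("'circuit' must be a pair_circuit", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("state scale 's' must be a single positive number", call. = FALSE)
  scaled <- lapply(circuit, function(b) z_block(b$Rs * s, b$Rp * s, b$Cp / s))
  structure(scaled, class = "pair_circuit")
}
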