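#' Lumped-element parameters of the brain-to-amplifier recording chain
#'
#' Constructs the twelve-element parameter set of the transmission model of a
#' multichannel epicortical recording system. The chain is broken into six
#' blocks per line: spread resistance through tissue and meninges (`R_S`),
#' tissue-electrode interface as a Randles element (`R_E` in series with
#' `R_F` parallel `C_H`), shunt path through the implant insulation to the
#' electrolyte (`R_Sh`, `C_Sh`), coupling path between neighboring lines at
#' the implant level (`R_Imp`, `C_Imp`), coupling path at the interconnect
#' level — connector, headstage and cables — (`R_Int`, `C_Int`), and the
#' amplifier input impedance (`R_Amp`, `C_Amp`).
#'
#' Defaults reproduce the reference parametrization of the modeled
#' acquisition system (epidural platinum microelectrodes, polyimide
#' substrate, Omnetics/ZIF-Clip interconnection, TDT amplifier), obtained
#' from impedance spectroscopy on implantation day.
#'
#' All values are in SI units (ohm, farad). A resistance of `Inf` encodes an
#' absent resistive path (open circuit); a capacitance of `0` encodes an
#' absent capacitive path. Resistances must be positive, capacitances
#' non-negative.
#'
#' @param R_S spread resistance, ohm (tissue and meninges between source and
#'   electrode)
#' @param R_E electrolyte resistance, ohm (access resistance of the line)
#' @param R_F faradaic resistance of the electrode-electrolyte interface, ohm
#' @param C_H Helmholtz double-layer capacitance, farad
#' @param R_Sh,C_Sh shunt path from line to electrolyte through the implant
#'   insulation
#' @param R_Imp,C_Imp coupling path between neighboring channels at the
#'   implant level
#' @param R_Int,C_Int coupling path between neighboring channels at the
#'   interconnect level
#' @param R_Amp,C_Amp amplifier input impedance
#' @return An object of class `chain_parameters` (a named list of the twelve
#'   element values, SI units).
#' @examples
#' p <- chain_parameters()           # reference values
#' p$R_S                             # 45300 ohm
#' chain_parameters(C_H = 4.4e-10)   # a degraded double layer
#' @export
chain_parameters <- function(R_S = 45.3e3, R_E = 7.6e3,
                             R_F = 12.0e6, C_H = 4.4e-9,
                             R_Sh = 0.6e9, C_Sh = 23.0e-12,
                             R_Imp = 1.6e9, C_Imp = 4.8e-12,
                             R_Int = 12.4e6, C_Int = 43.9e-12,
                             R_Amp = 2.5e12, C_Amp = 8.8e-12) {
  p <- list(R_S = R_S, R_E = R_E, R_F = R_F, C_H = C_H,
            R_Sh = R_Sh, C_Sh = C_Sh, R_Imp = R_Imp, C_Imp = C_Imp,
            R_Int = R_Int, C_Int = C_Int, R_Amp = R_Amp, C_Amp = C_Amp)
  validate_chain_parameters(p)
  structure(p, class = "chain_parameters")
}

chain_element_names <- function() {
  c("R_S", "R_E", "R_F", "C_H", "R_Sh", "C_Sh",
    "R_Imp", "C_Imp", "R_Int", "C_Int", "R_Amp", "C_Amp")
}

validate_chain_parameters <- function(p) {
  nm <- chain_element_names()
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0)
    stop("missing chain parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (k in nm) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("chain parameter '", k, "' must be a single numeric value",
           call. = FALSE)
    if (startsWith(k, "R")) {
      if (v <= 0)  # Inf allowed: element absent
        stop("resistance '", k, "' must be positive (Inf = absent), got ", v,
             call. = FALSE)
    } else {
      if (!is.finite(v) || v < 0)
        stop("capacitance '", k, "' must be finite and >= 0, got ", v,
             call. = FALSE)
    }
  }
  invisible(p)
}

#' Scale one element of a chain parameter set
#'
#' Applies a single block variation: multiplies one element by a positive
#' factor, leaving all others untouched. This is the elementary operation of
#' the sensitivity sweep, where the limiting parameter of each block is
#' varied by 5-fold and 10-fold increases and decreases.
#'
#' @param params a [chain_parameters()] object
#' @param element name of the element to vary (e.g. `"C_H"`)
#' @param factor positive scalar multiplier
#' @return A new `chain_parameters` object.
#' @export
scale_element <- function(params, element, factor) {
  stopifnot(inherits(params, "chain_parameters"))
  if (!element %in% chain_element_names())
    stop("unknown chain element '", element, "'", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("variation factor must be a positive finite scalar", call. = FALSE)
  params[[element]] <- params[[element]] * factor
  validate_chain_parameters(params)
  params
}

#' @export
print.chain_parameters <- function(x, ...) {
  cat("Chain parameters (brain-to-amplifier lumped-element model)\n")
  fmt <- function(v, unit) {
    if (is.infinite(v)) return("absent (Inf)")
    pre <- c(1e12, 1e9, 1e6, 1e3, 1, 1e-3, 1e-6, 1e-9, 1e-12)
    sym <- c("T", "G", "M", "k", "", "m", "u", "n", "p")
    i <- which(abs(v) >= pre)[1]
    if (is.na(i)) i <- length(pre)
    sprintf("%g %s%s", v / pre[i], sym[i], unit)
  }
  for (k in chain_element_names()) {
    unit <- if (startsWith(k, "R")) "Ohm" else "F"
    cat(sprintf("  %-6s %s\n", k, fmt(x[[k]], unit)))
  }
  invisible(x)
}

# ---- unit-aware configuration I/O -----------------------------------------

si_prefixes <- stats::setNames(
  c(1e12, 1e9, 1e6, 1e3, 1, 1e-3, 1e-6, 1e-6, 1e-9, 1e-12),
  c("T", "G", "M", "k", "", "m", "u", "µ", "n", "p"))

# "45.3 kOhm" / "4.4 nF" / plain number -> SI value; unit kind checked
parse_si_value <- function(x, key) {
  kind <- if (startsWith(key, "R")) "Ohm" else "F"
  if (is.numeric(x)) return(x)
  s <- trimws(as.character(x))
  m <- regmatches(s, regexec(
    "^([-+0-9.eE]+)\\s*([TGMkmunpµ]?)(Ohm|ohm|Ω|F|f)$", s))[[1]]
  if (length(m) == 0)
    stop("cannot parse value for '", key, "': '", s,
         "' (expected e.g. '45.3 kOhm' or '4.4 nF')", call. = FALSE)
  unit <- m[4]
  unit_kind <- if (unit %in% c("F", "f")) "F" else "Ohm"
  if (unit_kind != kind)
    stop("unit mismatch for '", key, "': got '", unit, "', expected ",
         if (kind == "Ohm") "a resistance" else "a capacitance",
         call. = FALSE)
  as.numeric(m[2]) * si_prefixes[[m[3]]]
}

#' Read and write chain parameters as a unit-annotated config file
#'
#' The on-disk format is YAML with one key per element and values either
#' plain numbers (interpreted as SI: ohm, farad) or strings with an SI
#' prefix and unit, e.g. `R_S: 45.3 kOhm` or `C_H: 4.4 nF`. All twelve
#' element keys must be present; a missing key, an unknown unit or a
#' non-positive value is a schema error naming the offending key. The
#' reference parameter file ships with the package as
#' `system.file("extdata", "chain_reference.yaml", package = "neuroxtalk")`.
#'
#' @param path file path
#' @return [load_chain_parameters()] returns a validated
#'   [chain_parameters()] object; `write_chain_parameters()` returns `path`
#'   invisibly.
#' @export
load_chain_parameters <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  nm <- chain_element_names()
  missing <- setdiff(nm, names(raw))
  if (length(missing) > 0)
    stop("parameter file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- lapply(nm, function(k) parse_si_value(raw[[k]], k))
  names(vals) <- nm
  do.call(chain_parameters, vals)
}

#' @rdname load_chain_parameters
#' @param params a [chain_parameters()] object
#' @export
write_chain_parameters <- function(params, path) {
  stopifnot(inherits(params, "chain_parameters"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
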