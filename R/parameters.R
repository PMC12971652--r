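#' Canonical parameter set of the virus-immune network
#'
#' Returns the canonical parameterization of the six-compartment model as a
#' named numeric vector of all 63 rate, threshold and Hill-coefficient
#' constants. Names follow the field's conventional symbols transliterated to
#' ASCII (`a_v0`, `k_v0`, `n_v0`, ..., `delta`, ..., `d_IL2`), so parameter
#' files and overrides are self-documenting.
#'
#' The basal immune-suppression generation rate `delta` defaults to 2e-4; a
#' historical alternative of 1e-4 circulates for this model, so `delta` (like
#' every other entry) can be overridden via [modify_parameters()].
#'
#' @return Named numeric vector of length 63.
#' @seealso [validate_params()], [modify_parameters()], [read_parameter_file()]
#' @export
#' @examples
#' p <- default_parameters()
#' p[["a_v0"]]   # maximum viral replication rate, 2.5
default_parameters <- function() {
  c(
    # viral load V: input + saturating self-replication - immune clearance - decay
    a_v0 = 2.5,   k_v0 = 0.2,   n_v0 = 3,
    d_v1 = 0.24,  k_v1 = 0.1,   n_v1 = 3,     # clearance by cellular immunity
    d_v2 = 0.16,  k_v2 = 0.225, n_v2 = 3,     # clearance by innate immunity
    d_v3 = 0.06,  k_v3 = 0.3,   n_v3 = 3,     # clearance by humoral immunity
    d_v4 = 0.5,                                # natural viral decay
    # innate immunity I
    a_I0 = 0.3,   k_I0 = 0.025, n_I0 = 3,     # activation by virus
    a_I1 = 0.5,   k_I1 = 0.1,   n_I1 = 3,     # self-activation
    d_I2 = 0.8,   k_I2 = 3,     n_I2 = 3,     # suppression by S
    d_I3 = 1.6,                                # natural decay
    # cellular immunity C
    a_C0 = 1.6,   k_C0 = 0.05,  n_C0 = 3,     # co-activation: innate arm
    k_C1 = 0.05,  n_C1 = 3,                    # co-activation: viral arm
    a_C2 = 1,     k_C2 = 0.4,   n_C2 = 3,     # self-activation
    d_C3 = 0.8,   k_C3 = 3,     n_C3 = 3,     # suppression by S
    d_C4 = 0.8,                                # natural decay
    # humoral immunity H
    a_H0 = 0.3,   k_H0 = 0.05,  n_H0 = 3,     # activation by C
    a_H1 = 0.1,   k_H1 = 0.05,  n_H1 = 3,     # activation by I
    d_H2 = 2.5,   k_H2 = 0.4,   n_H2 = 3,     # suppression by S
    d_H3 = 0.5,                                # natural decay
    # immune suppression S
    delta = 2e-4,                              # basal generation
    a_S0 = 0.1,   k_S0 = 0.08,  n_S0 = 3,     # activation by C
    a_S1 = 0.1,   k_S1 = 0.08,  n_S1 = 3,     # activation by I
    d_S2 = 0.8,   k_S2 = 0.1,   n_S2 = 3,     # down-regulation by IL-6
    d_S3 = 0.8,                                # natural decay
    # interleukin-6
    a_IL0 = 0.025, k_IL0 = 0.5,  n_IL0 = 3,   # production driven by C
    a_IL1 = 1,     k_IL1 = 0.025, n_IL1 = 3,  # production driven by V
    d_IL2 = 3                                  # natural decay
  )
}

#' Canonical baseline state
#'
#' The baseline initial condition used throughout the scenario presets:
#' zero virus with resting immune-module intensities.
#'
#' @return Named numeric state vector `(V, I, C, H, S, IL6)`.
#' @export
default_initial_state <- function() {
  c(V = 0, I = 0.3, C = 1.2, H = 0.4, S = 0.25, IL6 = 0.005)
}

#' Names of the six state variables, in model order.
#' @export
state_names <- function() c("V", "I", "C", "H", "S", "IL6")

# strictly positive decay rates required by boundedness
.decay_names <- c("d_v4", "d_I3", "d_C4", "d_H3", "d_S3", "d_IL2")

#' Validate a parameter set
#'
#' Checks the structural invariants of the model's parameter vector: all 63
#' canonical names present and finite, half-saturation constants `k_*` > 0,
#' Hill coefficients `n_*` > 0 (and >= 1, so derivatives stay defined at the
#' orthant boundary), rates `a_*`, `d_*` and `delta` >= 0, and the six
#' terminal decay rates strictly positive. Reports rather than throws.
#'
#' @param p Named numeric parameter vector (see [default_parameters()]).
#' @return Character vector of violation messages, each naming the offending
#'   field; `character(0)` when `p` is valid.
#' @export
validate_params <- function(p) {
  ref <- names(default_parameters())
  out <- character(0)
  missing <- setdiff(ref, names(p))
  if (length(missing)) {
    out <- c(out, paste0("missing parameter: ", missing))
  }
  extra <- setdiff(names(p), ref)
  if (length(extra)) {
    out <- c(out, paste0("unknown parameter: ", extra))
  }
  present <- intersect(ref, names(p))
  for (nm in present) {
    v <- unname(p[[nm]])
    if (!is.finite(v)) {
      out <- c(out, paste0(nm, " is not finite"))
      next
    }
    if (startsWith(nm, "k_") && v <= 0) {
      out <- c(out, paste0(nm, " must be > 0 (half-saturation constant)"))
    } else if (startsWith(nm, "n_")) {
      if (v <= 0) {
        out <- c(out, paste0(nm, " must be > 0 (Hill coefficient)"))
      } else if (v < 1) {
        out <- c(out, paste0(nm, " must be >= 1 (derivative defined at 0)"))
      }
    } else if (nm %in% .decay_names) {
      if (v <= 0) out <- c(out, paste0(nm, " must be > 0 (decay rate)"))
    } else if (v < 0) {
      out <- c(out, paste0(nm, " must be >= 0"))
    }
  }
  out
}

#' Override selected parameters
#'
#' @param p Base parameter vector.
#' @param ... Named scalar overrides, e.g. `modify_parameters(p, d_v1 = 100)`.
#'   Unknown names are an error.
#' @return The modified parameter vector.
#' @export
modify_parameters <- function(p, ...) {
  ov <- c(...)
  if (length(ov) == 0) return(p)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  }
  p[names(ov)] <- ov
  p
}

#' Read a parameter file
#'
#' Reads a flat key-value document (JSON, or YAML when the `yaml` package is
#' available) keyed by the canonical parameter names. Keys present override
#' the canonical values; missing keys keep their defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param base Parameter vector the file overrides (default [default_parameters()]).
#' @return A full, validated parameter vector.
#' @export
read_parameter_file <- function(path, base = default_parameters()) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML parameter files requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (length(vals) == 0) return(base)
  vals <- unlist(vals)
  bad <- setdiff(names(vals), names(base))
  if (length(bad)) {
    stop("unknown parameter key(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  base[names(vals)] <- as.numeric(vals)
  viol <- validate_params(base)
  if (length(viol)) {
    stop("invalid parameter file ", path, ": ", paste(viol, collapse = "; "))
  }
  base
}
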