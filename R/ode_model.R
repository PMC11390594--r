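#' Species of the senescence protein network
#' @export
MODEL_SPECIES <- c("RAS", "DDR", "p53", "pp53", "p21", "p16", "p38",
                   "pp38", "NFKB", "pNFKB", "IL6", "NOTCH1", "NICD")

#' Condition-input parameters (set by the induction presets)
#' @keywords internal
CONDITION_INPUTS <- c("RAS_input", "DDR_input", "kDDRF", "kRASF",
                      "kDDRFRAS")

#' Build the reference senescence network model
#'
#' A single-cell ODE network of thirteen species covering five interlinked
#' pathways: damage sensing (RAS relaxes to an external `RAS_input`; the
#' DNA damage response DDR integrates an external damage input `kDDRF *
#' DDR_input` and a RAS-driven term `kDDRFRAS * RAS`), p53 (synthesis
#' enhanced by total NF-kB, Michaelis-Menten phosphorylation to active
#' pp53 driven by DDR), cell-cycle inhibitors (p21 induced by pp53, p16
#' induced by pp38, both Michaelis-Menten), stress signalling (p38
#' synthesis repressed by pp53; phosphorylation to pp38 driven by
#' `RAS + alpha * DDR` and repressed by pp53), Notch (constitutive NOTCH1
#' cleaved to NICD at `k_cleave`; the Notch switch steps `k_cleave` down),
#' and inflammation (NF-kB activation driven by pp38 and repressed by
#' NICD; IL-6 induced by active pNF-kB). Every species carries first-order
#' degradation. Concentrations and times are in arbitrary units.
#'
#' The reference parameter values are read from the packaged file
#' `extdata/reference_parameters.csv`, calibrated once (seeded, scripted)
#' so that the twelve phenotype criteria pass; the file, not the code, is
#' the quantitative contract.
#'
#' @param parameters Optional named numeric vector overriding any subset
#'   of the packaged reference values.
#' @return A list of class `"senescence_model"` with `species`,
#'   `parameters`, and the derivative function `rhs(t, state, parms)`.
#' @export
build_reference_model <- function(parameters = NULL) {
  ref <- reference_parameters()
  if (!is.null(parameters)) {
    unknown <- setdiff(names(parameters), names(ref))
    if (length(unknown)) stop("unknown parameter: ", unknown[1])
    ref[names(parameters)] <- parameters
  }
  structure(list(species = MODEL_SPECIES, parameters = ref,
                 rhs = senescence_rhs),
            class = "senescence_model")
}

#' @rdname build_reference_model
#' @export
reference_parameters <- function() {
  path <- system.file("extdata", "reference_parameters.csv",
                      package = "senotemp")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  stats::setNames(tab$value, tab$parameter)
}

senescence_rhs <- function(t, state, parms) {
  with(as.list(c(state, parms)), {
    f_p53 <- V_p53 * DDR * p53 / (K_p53 + p53)
    f_p38 <- V_p38 * (RAS + alpha * DDR) * p38 /
      ((K_p38 + p38) * (1 + phi * pp53))
    f_nf <- V_NF * pp38 * NFKB / ((K_NF + NFKB) * (1 + psi * NICD))
    list(c(
      RAS    = kRASF * (RAS_input - RAS),
      DDR    = kDDRF * DDR_input + kDDRFRAS * RAS - d_DDR * DDR,
      p53    = b_p53 * (1 + a_NF * (NFKB + pNFKB)) - f_p53 +
               k_dp53 * pp53 - d_p53 * p53,
      pp53   = f_p53 - k_dp53 * pp53 - d_pp53 * pp53,
      p21    = b_p21 + V_p21 * pp53 / (K_p21 + pp53) - d_p21 * p21,
      p16    = b_p16 + V_p16 * pp38 / (K_p16 + pp38) - d_p16 * p16,
      p38    = b_p38 / (1 + theta * pp53) - f_p38 + k_dp38 * pp38 -
               d_p38 * p38,
      pp38   = f_p38 - k_dp38 * pp38 - d_pp38 * pp38,
      NFKB   = b_NF - f_nf + k_dNF * pNFKB - d_NF * NFKB,
      pNFKB  = f_nf - k_dNF * pNFKB - d_pNF * pNFKB,
      IL6    = b_IL6 + V_IL6 * pNFKB / (K_IL6 + pNFKB) - d_IL6 * IL6,
      NOTCH1 = b_NOTCH - k_cleave * NOTCH1 - d_NOTCH * NOTCH1,
      NICD   = k_cleave * NOTCH1 - d_NICD * NICD
    )[MODEL_SPECIES])
  })
}

#' Audit the structural invariants of a model
#'
#' Checks that every species has at least one production term and a
#' first-order degradation term (evaluated by finite perturbation of the
#' derivative field at a generic positive state), and that all parameters
#' are positive where required.
#'
#' @param model A `"senescence_model"`.
#' @return Invisibly `TRUE`, or an error.
#' @export
audit_model <- function(model) {
  p <- model$parameters
  nonneg_ok <- c("RAS_input", "DDR_input")
  if (any(p[setdiff(names(p), nonneg_ok)] <= 0))
    stop("non-positive rate parameter")
  state <- stats::setNames(rep(1, length(model$species)), model$species)
  base <- unlist(model$rhs(0, state, p))
  for (sp in model$species) {
    zeroed <- state; zeroed[sp] <- 0
    d0 <- unlist(model$rhs(0, zeroed, p))[sp]
    if (d0 < 0) stop("species ", sp, " lacks a production floor at zero")
    bumped <- state; bumped[sp] <- 2
    dd <- unlist(model$rhs(0, bumped, p))[sp] - base[sp]
    if (dd >= 0) stop("species ", sp, " lacks degradation")
  }
  invisible(TRUE)
}

#' Solve the fixed point of the network for fixed inputs
#'
#' Long relaxation by `deSolve::lsoda` followed by a damped Newton polish
#' using a finite-difference Jacobian (via `pracma`).
#'
#' @param model A `"senescence_model"`.
#' @param parameters Named parameter vector to solve under (defaults to
#'   the model's own).
#' @param init Optional starting state.
#' @param relax_time Relaxation horizon before polishing.
#' @return Named steady-state vector.
#' @export
find_steady_state <- function(model, parameters = model$parameters,
                              init = NULL, relax_time = 400) {
  if (is.null(init))
    init <- stats::setNames(rep(0.1, length(model$species)),
                            model$species)
  sol <- deSolve::lsoda(init, c(0, relax_time), model$rhs, parameters,
                        rtol = 1e-10, atol = 1e-12)
  x <- sol[nrow(sol), model$species]
  f <- function(s) unlist(model$rhs(0, stats::setNames(s, model$species),
                                    parameters))
  for (i in 1:20) {
    fx <- f(x)
    if (max(abs(fx)) < 1e-12) break
    J <- pracma::jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) fx * 0)
    x <- x - step
    x[x < 0] <- 0
  }
  stats::setNames(as.numeric(x), model$species)
}
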