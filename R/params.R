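# Model parameters: construction, validation, carbachol modulation, file I/O.

#' Coupled-clock cell parameters
#'
#' Builds the parameter set of the common-pool coupled-clock pacemaker cell
#' model. Defaults come from the versioned basal parameter file shipped with
#' the package (`inst/extdata/basal_params.json`); any subset can be
#' overridden by name. The two parameters varied in firing-diagram sweeps are
#' `g_CaL` (L-type Ca conductance density, nS/pF) and `P_up` (maximal SR Ca
#' uptake rate, mM/s).
#'
#' @param ... named parameter overrides, e.g. `g_CaL = 0.37, P_up = 1`.
#' @param base optional named list/vector used instead of the shipped basal
#'   file.
#' @return an object of class `cell_params`: a named numeric vector with one
#'   element per model constant.
#' @examples
#' p <- cell_params()
#' dormant <- cell_params(g_CaL = 0.37, P_up = 1)
#' @export
cell_params <- function(..., base = NULL) {
  if (is.null(base)) base <- basal_params()
  p <- unlist(base)[cm_param_names()]
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(over), cm_param_names())
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- unlist(over)
  }
  validate_params(p)
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> coupled-clock SAN cell model (",
      length(x), " constants)\n", sep = "")
  cat(sprintf("  g_CaL = %.4g nS/pF, P_up = %.4g mM/s, C_m = %.3g pF\n",
              x[["g_CaL"]], x[["P_up"]], x[["C_m"]]))
  if (x[["g_KACh"]] > 0)
    cat(sprintf("  carbachol-modulated: g_KACh = %.4g nS/pF\n", x[["g_KACh"]]))
  invisible(x)
}

basal_env <- new.env(parent = emptyenv())

#' Shipped basal parameter set
#'
#' Reads (and caches) the versioned basal parameter file shipped with the
#' package.
#' @return named numeric vector of model constants.
#' @export
basal_params <- function() {
  if (is.null(basal_env$p)) {
    path <- system.file("extdata", "basal_params.json", package = "sansr")
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    basal_env$p <- unlist(j$params)
    basal_env$s <- unlist(j$initial_state)
  }
  basal_env$p
}

#' Shipped initial state fixture
#'
#' A settled late-diastolic state of the basal model, used as the starting
#' point of every simulation (the first seconds are normally discarded before
#' computing metrics).
#' @return named numeric vector of state variables.
#' @export
initial_state <- function() {
  basal_params()
  basal_env$s
}

validate_params <- function(p) {
  if (anyNA(p)) stop("parameters contain NA: ",
                     paste(names(p)[is.na(p)], collapse = ", "))
  nonneg <- c("C_m", "g_CaL", "g_CaT", "g_Kr", "g_Ks", "g_to", "g_sus",
              "g_if", "g_st", "g_bNa", "i_NaK_max", "k_NCX", "g_KACh",
              "P_up", "K_up", "tau_dif_Ca", "tau_tr", "k_s",
              "TC_tot", "TMC_tot", "CM_tot", "CQ_tot",
              "V_i", "V_sub", "V_jSR", "V_nSR")
  bad <- nonneg[p[nonneg] < 0]
  if (length(bad)) stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  if (p[["C_m"]] <= 0) stop("C_m must be positive")
  invisible(TRUE)
}

validate_state <- function(s) {
  if (length(s) != length(cm_state_names()))
    stop("state must have ", length(cm_state_names()), " elements")
  if (any(!is.finite(s))) stop("non-finite state variable(s): ",
                               paste(names(s)[!is.finite(s)], collapse = ", "))
  conc <- c("Ca_i", "Ca_sub", "Ca_nSR", "Ca_jSR")
  if (any(s[conc] < 0)) stop("negative Ca concentration(s)")
  gates <- setdiff(names(s), c("V_m", conc))
  if (any(s[gates] < -1e-9 | s[gates] > 1 + 1e-9))
    stop("gating/occupancy variable(s) outside [0,1]: ",
         paste(gates[s[gates] < -1e-9 | s[gates] > 1 + 1e-9], collapse = ", "))
  invisible(TRUE)
}

#' Apply carbachol (muscarinic stimulation) to a parameter set
#'
#' Carbachol activates I_KACh and attenuates the two clock drivers (g_CaL and
#' P_up), with an optional hyperpolarizing shift of I_f activation. Each
#' effect follows a configurable Hill-type dose-response curve; the defaults
#' are calibrated so that a high dose (1000 nM) renders the basal model
#' dormant while 100 nM only slows it.
#'
#' @param params a `cell_params` object.
#' @param cch carbachol concentration, nM (>= 0; 0 returns `params`
#'   unchanged).
#' @param response list of dose-response constants: `g_kach_max` (nS/pF),
#'   `ec50` (nM), `hill`, `gcal_max_block` and `pup_max_block` (maximal
#'   fractional attenuations in `[0,1]`), `if_shift_max` (mV, negative =
#'   hyperpolarizing).
#' @return a modified `cell_params` object.
#' @export
apply_carbachol <- function(params, cch,
                            response = list(g_kach_max = 0.0084,
                                            ec50 = 250, hill = 1.5,
                                            gcal_max_block = 0.4,
                                            pup_max_block = 0.3,
                                            if_shift_max = -7.8)) {
  stopifnot(inherits(params, "cell_params"))
  if (!is.numeric(cch) || length(cch) != 1 || is.na(cch) || cch < 0)
    stop("cch must be a single nonnegative concentration (nM)")
  if (cch == 0) return(params)
  occ <- cch^response$hill / (cch^response$hill + response$ec50^response$hill)
  p <- unclass(params)
  p[["g_KACh"]] <- p[["g_KACh"]] + response$g_kach_max * occ
  p[["g_CaL"]] <- p[["g_CaL"]] * (1 - response$gcal_max_block * occ)
  p[["P_up"]] <- p[["P_up"]] * (1 - response$pup_max_block * occ)
  p[["E_if_shift"]] <- p[["E_if_shift"]] + response$if_shift_max * occ
  structure(p, class = "cell_params")
}

#' Write / read parameter files
#'
#' Parameter sets are stored as structured JSON (a `params` object plus an
#' optional `initial_state`), the same format as the shipped basal file.
#' @param params a `cell_params` object.
#' @param path file path.
#' @param state optional named state vector stored alongside.
#' @export
write_params <- function(params, path, state = NULL) {
  stopifnot(inherits(params, "cell_params"))
  obj <- list(format = "sansr-cell-params", version = 1L,
              params = as.list(unclass(params)))
  if (!is.null(state)) obj$initial_state <- as.list(state)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cell_params(base = j$params)
}
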