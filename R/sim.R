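# Forward simulation of C3 photosynthesis: given leaf biochemistry and an
# environment, solve the balance between FvCB demand for CO2 and diffusive
# supply through the air-to-chloroplast conductance for the chloroplastic
# CO2 mole fraction C_c.

.leaf_defaults <- function() {
  kin <- tobacco_kinetics()
  c(list(
    V_cmax25 = 100, # umol m-2 s-1
    J_max25 = 180,  # umol m-2 s-1
    V_TPU25 = 12,   # umol m-2 s-1
    R_d25 = 1.5,    # umol m-2 s-1
    phi_J = 0.425,  # mol e- mol-1 photons, apparent PSII yield
    theta_J = 0.85, # J light-response curvature
    g_mc = 0.5      # mol m-2 s-1, mesophyll conductance
  ), kin)
}

.env_defaults <- function() {
  list(
    C_air = 420,    # umol mol-1
    Q = 1500,       # umol m-2 s-1 PPFD
    T_leaf = 298.15, # K
    O = 210,        # mmol mol-1
    g_tc = 0.2,     # mol m-2 s-1, total air-to-chloroplast CO2 conductance
    g_sc = NA_real_, # stomatal CO2 conductance (optional component)
    g_bc = Inf      # boundary-layer CO2 conductance (optional component)
  )
}

#' Build leaf and environment parameter sets for simulation
#'
#' Merges user overrides into the documented defaults (tobacco kinetics of
#' [tobacco_kinetics()]; typical sun-leaf rates; 420 umol mol-1 CO2 at
#' 1500 umol m-2 s-1 PPFD and 25 degC). If a stomatal component `g_sc` is
#' supplied (optionally with `g_bc`), the total conductance `g_tc` is
#' composed in series with the mesophyll: `1/g_tc = 1/g_bc + 1/g_sc +
#' 1/g_mc`; otherwise `g_tc` is used directly.
#'
#' @param overrides named list of parameter overrides drawn from the
#'   documented vocabulary (leaf: `V_cmax25`, `J_max25`, `V_TPU25`, `R_d25`,
#'   `phi_J`, `theta_J`, `g_mc`, kinetics fields; environment: `C_air`, `Q`,
#'   `T_leaf`, `O`, `g_tc`, `g_sc`, `g_bc`). Unknown keys raise an error
#'   naming the nearest valid parameter.
#' @return A list with elements `leaf`, `env` and `defaulted` (names of
#'   parameters left at their defaults).
#' @examples
#' p <- make_parameters(list(V_cmax = 120))
#' p$leaf$V_cmax25
#' @export
make_parameters <- function(overrides = list()) {
  leaf <- .leaf_defaults()
  env <- .env_defaults()
  # accept the common shorthand without the 25 suffix
  alias <- c(V_cmax = "V_cmax25", J_max = "J_max25", V_TPU = "V_TPU25",
             R_d = "R_d25")
  vocab <- c(names(leaf), names(env), names(alias))
  for (key in names(overrides)) {
    k <- if (key %in% names(alias)) alias[[key]] else key
    if (!k %in% c(names(leaf), names(env))) {
      near <- vocab[order(utils::adist(key, vocab, ignore.case = TRUE))][1]
      abort(paste0("unknown parameter '", key, "'; did you mean '", near,
                   "'?"))
    }
    if (k %in% names(leaf)) leaf[[k]] <- overrides[[key]]
    else env[[k]] <- overrides[[key]]
  }
  if (is.finite(env$g_sc) && !("g_tc" %in% names(overrides))) {
    env$g_tc <- 1 / (1 / env$g_bc + 1 / env$g_sc + 1 / leaf$g_mc)
  }
  defaulted <- setdiff(c(names(leaf), names(env)),
                       c(names(overrides), unname(alias[names(overrides)])))
  list(leaf = leaf, env = env, defaulted = defaulted)
}

# electron transport at irradiance Q: non-rectangular hyperbola in Q
electron_transport <- function(Q, phi_J, theta_J, J_max) {
  aq_gross(J_max, phi_J, theta_J, Q)
}

#' Solve the supply-demand balance for chloroplastic CO2
#'
#' Finds the chloroplastic CO2 mole fraction at which FvCB demand
#' `min(A_c, A_j, A_p) - R_d` equals diffusive supply
#' `g_tc * (C_air - C_c)`, by bracketed root-finding on
#' `(1e-6, C_air + 500)` followed by a secant polish to a residual below
#' 1e-10 umol m-2 s-1. Rates and kinetic constants are temperature-adjusted
#' to `T_leaf` first; electron transport J comes from the non-rectangular
#' hyperbola in Q.
#'
#' @param leaf,env parameter lists from [make_parameters()].
#' @param t_leaf_fn optional plug-in: a function of `(leaf, env)` returning
#'   leaf temperature in K (e.g. an external energy-balance solver); when
#'   given it replaces `env$T_leaf`.
#' @return A one-row tibble: `C_c`, `A_net`, `limitation`, the component
#'   rates `A_c`, `A_j`, `A_p`, `J`, the residual, and the drivers.
#' @examples
#' p <- make_parameters()
#' solve_cc(p$leaf, p$env)
#' @export
solve_cc <- function(leaf, env, t_leaf_fn = NULL) {
  if (!is.null(t_leaf_fn)) env$T_leaf <- t_leaf_fn(leaf, env)
  stopifnot(env$C_air > 0, env$g_tc > 0, env$T_leaf > 0)
  Tk <- env$T_leaf
  V_cmax <- arrhenius_scale(leaf$V_cmax25, leaf$Ea_V_cmax, Tk)
  J_max <- arrhenius_scale(leaf$J_max25, leaf$Ea_J_max, Tk)
  R_d <- arrhenius_scale(leaf$R_d25, leaf$Ea_R_d, Tk)
  V_TPU <- if (is.finite(leaf$V_TPU25)) {
    arrhenius_scale(leaf$V_TPU25, leaf$Ea_V_cmax, Tk)
  } else Inf
  kt <- adjust_kinetics(leaf, Tk)
  K_m <- kt$K_c * (1 + env$O / kt$K_o)
  J <- electron_transport(env$Q, leaf$phi_J, leaf$theta_J, J_max)
  demand <- function(cc) {
    fvcb_gross(V_cmax, J, V_TPU, cc, kt$Gamma_star, K_m) - R_d
  }
  f <- function(cc) demand(cc) - env$g_tc * (env$C_air - cc)
  lo <- 1e-6
  hi <- env$C_air + 500
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    abort(sprintf(
      "no sign change in the C_c bracket: f(%g) = %g, f(%g) = %g",
      lo, flo, hi, fhi))
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  # secant polish: uniroot's interval tolerance does not guarantee a tiny
  # residual, the supply-demand invariant does
  for (i in 1:50) {
    fr <- f(root)
    if (abs(fr) < 1e-12) break
    h <- max(abs(root) * 1e-8, 1e-10)
    dfr <- (f(root + h) - fr) / h
    step <- fr / dfr
    if (!is.finite(step)) break
    root <- root - step
  }
  cc <- root
  A_c <- V_cmax * (cc - kt$Gamma_star) / (cc + K_m)
  A_j <- J * (cc - kt$Gamma_star) / (4 * cc + 8 * kt$Gamma_star)
  A_p <- 3 * V_TPU
  lim <- c("Ac", "Aj", "Ap")[which.min(c(A_c, A_j, A_p))]
  tibble(
    C_c = cc, A_net = demand(cc), limitation = lim,
    A_c = A_c, A_j = A_j, A_p = A_p, J = J, residual = f(cc),
    C_air = env$C_air, Q = env$Q, T_leaf = Tk, g_tc = env$g_tc
  )
}

#' Simulate photosynthesis over a parameter grid
#'
#' Runs [solve_cc()] over the Cartesian product of the supplied parameter
#' axes. A failed solve is recorded as a failed row (NA outputs, the error
#' message in `fail_message`) rather than aborting the run.
#'
#' @param vary named list of parameter value vectors (any [make_parameters()]
#'   vocabulary name); the grid is their Cartesian product. An empty list
#'   simulates the single base case.
#' @param base base parameters from [make_parameters()] (default: all
#'   defaults).
#' @param t_leaf_fn optional leaf-temperature plug-in, see [solve_cc()].
#' @return A tibble with one row per grid point: varied inputs, then the
#'   [solve_cc()] outputs and a `failed` flag.
#' @examples
#' simulate_photosynthesis(list(C_air = c(200, 400, 800), Q = c(500, 1500)))
#' @export
simulate_photosynthesis <- function(vary = list(), base = make_parameters(),
                                    t_leaf_fn = NULL) {
  if (length(vary) == 0) {
    grid <- tibble(.row = 1L)
  } else {
    stopifnot(all(lengths(vary) > 0))
    grid <- tibble::as_tibble(expand.grid(vary, KEEP.OUT.ATTRS = FALSE,
                                          stringsAsFactors = FALSE))
  }
  if (nrow(grid) == 0) abort("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ov <- as.list(grid[i, setdiff(names(grid), ".row"), drop = FALSE])
    res <- tryCatch({
      p <- make_parameters(ov)
      # keep non-varied values from `base`
      for (nm in names(base$leaf)) {
        if (!nm %in% names(ov)) p$leaf[[nm]] <- base$leaf[[nm]]
      }
      for (nm in names(base$env)) {
        if (!nm %in% names(ov) && !(nm == "g_tc" && "g_sc" %in% names(ov))) {
          p$env[[nm]] <- base$env[[nm]]
        }
      }
      for (nm in names(ov)) {
        if (nm %in% names(p$leaf)) p$leaf[[nm]] <- ov[[nm]]
        if (nm %in% names(p$env)) p$env[[nm]] <- ov[[nm]]
      }
      sim <- solve_cc(p$leaf, p$env, t_leaf_fn = t_leaf_fn)
      mutate(sim, failed = FALSE, fail_message = NA_character_)
    }, error = function(e) {
      tibble(C_c = NA_real_, A_net = NA_real_, limitation = NA_character_,
             failed = TRUE, fail_message = conditionMessage(e))
    })
    bind_cols(grid[i, setdiff(names(grid), ".row"), drop = FALSE],
              select(res, -dplyr::any_of(intersect(names(grid), names(res)))))
  })
  bind_rows(rows)
}
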