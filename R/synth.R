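# Synthetic-data generator: every curve type the package fits can be
# generated from known true parameters plus additive Gaussian noise, so
# every fitting routine is testable as a generator -> fit round trip
# without instrument data. Driver grids default to realistic measurement
# designs (e.g. the classic light-response irradiance steps 1500, 375, 150,
# 125, 100, 75, 50, 25 umol m-2 s-1 and CO2-response leaf temperatures
# 17.5-40 degC in 2.5 degC steps).

#' Curve kinds the synthetic generator knows
#' @return character vector of kinds.
#' @export
curve_kinds <- function() {
  c("aq", "aci", "t_response", "gs", "r_light_kok", "r_light_yin",
    "r_light_walker_ort", "gmc_variablej", "pv", "vuln")
}

.design_defaults <- function(kind) {
  switch(kind,
    aq = list(
      true_params = list(A_sat = 25, phi_J = 0.05, theta_J = 0.85,
                         R_d = 1.2),
      drivers = list(Q = c(0, 25, 50, 75, 100, 125, 150, 375, 1500)),
      noise_sd = 0.3),
    aci = list(
      true_params = c(list(V_cmax25 = 100, J_max25 = 180, V_TPU25 = 12,
                           R_d25 = 1.5),
                      tobacco_kinetics()),
      drivers = list(C_i = seq(50, 1500, length.out = 12),
                     T_leaf = 298.15, Q = 1500),
      noise_sd = 0.5),
    t_response = list(
      true_params = list(model = "arrhenius", k_ref = 75, E_a = 55000),
      drivers = list(T_leaf = seq(17.5, 40, 2.5) + 273.15),
      noise_sd = 1.5),
    gs = list(
      true_params = list(model = "ballberry", g0 = 0.02, g1 = 9),
      drivers = list(A_net = seq(2, 24, length.out = 10),
                     RH = seq(0.35, 0.8, length.out = 10),
                     D = seq(2.4, 0.6, length.out = 10),
                     C_s = seq(420, 320, length.out = 10)),
      noise_sd = 0.01),
    r_light_kok = list(
      true_params = list(slope = 0.04, R_light = 1.0),
      drivers = list(Q = seq(20, 100, 10)),
      noise_sd = 0.05),
    r_light_yin = list(
      true_params = list(calibration_slope = 0.45, R_light = 0.8),
      drivers = list(Q = seq(20, 100, 10),
                     phi_PSII = seq(0.78, 0.66, length.out = 9)),
      noise_sd = 0.05),
    r_light_walker_ort = list(
      true_params = list(C_i_star = 40, R_light = 1.1,
                         slopes = c(0.02, 0.05, 0.09)),
      drivers = list(C_i = seq(20, 120, 20)),
      noise_sd = 0.05),
    gmc_variablej = list(
      true_params = list(g_mc = 0.25, Gamma_star = 40, R_light = 1),
      drivers = list(A_net = seq(5, 25, length.out = 10),
                     C_i = seq(150, 350, length.out = 10)),
      noise_sd = 0),
    pv = list(
      true_params = list(pi_o = -1.2, RWC_TLP = 92),
      drivers = list(RWC = seq(99, 75, by = -2)),
      noise_sd = 0),
    vuln = list(
      true_params = list(model = "sigmoidal", a = 2, b = -2.5,
                         b_w = 2.7, c_w = 3),
      drivers = list(psi = seq(-0.5, -4.5, length.out = 9)),
      noise_sd = 2),
    abort(paste0("unknown curve kind: ", kind))
  )
}

#' Describe a synthetic curve to generate
#'
#' @param kind one of [curve_kinds()].
#' @param true_params overrides for the kind's default true parameters.
#' @param drivers overrides for the kind's default driver levels.
#' @param noise_sd Gaussian noise SD on the response, in response units
#'   (`NULL`: the kind's default).
#' @param seed integer seed; the same design and seed always generate the
#'   identical table.
#' @param dialect column-name dialect of the emitted table: `"canonical"`
#'   (default), `"licor6400"` or `"licor6800"`.
#' @param n_curves number of replicate curves (tagged `curve_id`, each with
#'   its own noise draw).
#' @return A `curve_design` list.
#' @export
curve_design <- function(kind, true_params = list(), drivers = list(),
                         noise_sd = NULL, seed = 1,
                         dialect = c("canonical", "licor6400", "licor6800"),
                         n_curves = 1) {
  if (length(kind) != 1 || !kind %in% curve_kinds()) {
    abort(paste0("unknown curve kind: ", kind[1], " (available: ",
                 paste(curve_kinds(), collapse = ", "), ")"))
  }
  def <- .design_defaults(kind)
  d <- list(
    kind = kind,
    true_params = modifyList(def$true_params, true_params),
    drivers = modifyList(def$drivers, drivers),
    noise_sd = if (is.null(noise_sd)) def$noise_sd else noise_sd,
    seed = as.integer(seed),
    dialect = match.arg(dialect),
    n_curves = n_curves
  )
  stopifnot(d$noise_sd >= 0, all(lengths(d$drivers) > 0), d$n_curves >= 1)
  structure(d, class = "curve_design")
}

# evaluate the seed locally; global RNG state is untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.synth_one <- function(design) {
  tp <- design$true_params
  dr <- design$drivers
  switch(design$kind,
    aq = tibble(Q = dr$Q, A_net = eval_aq(tp, dr$Q)),
    aci = {
      # one curve per leaf temperature; 25 degC rates and kinetics are
      # Arrhenius-scaled to each T_leaf
      bind_rows(lapply(dr$T_leaf, function(Tk) {
        kt <- adjust_kinetics(tp, Tk)
        p <- list(
          V_cmax = arrhenius_scale(tp$V_cmax25, tp$Ea_V_cmax, Tk),
          J_max = arrhenius_scale(tp$J_max25, tp$Ea_J_max, Tk),
          V_TPU = if (is.finite(tp$V_TPU25)) {
            arrhenius_scale(tp$V_TPU25, tp$Ea_V_cmax, Tk)
          } else Inf,
          R_d = arrhenius_scale(tp$R_d25, tp$Ea_R_d, Tk),
          Gamma_star = kt$Gamma_star, K_c = kt$K_c, K_o = kt$K_o,
          O = kt$O)
        tibble(C_i = dr$C_i, A_net = eval_fvcb_ci(p, dr$C_i)$A_mod,
               T_leaf = Tk, Q = dr$Q)
      }))
    },
    t_response = {
      p <- tp[setdiff(names(tp), "model")]
      tibble(T_leaf = dr$T_leaf,
             rate = eval_t_response(tp$model, p, dr$T_leaf))
    },
    gs = {
      p <- tp[setdiff(names(tp), "model")]
      d <- tibble::as_tibble(dr)
      d$g_sw <- eval_gs_model(tp$model, p, d)
      d
    },
    r_light_kok = tibble(Q = dr$Q,
                         A_net = tp$slope * dr$Q - tp$R_light),
    r_light_yin = {
      x <- dr$Q * dr$phi_PSII / 4
      tibble(Q = dr$Q, phi_PSII = dr$phi_PSII,
             A_net = tp$calibration_slope * x - tp$R_light)
    },
    r_light_walker_ort = {
      # lines through the common point (C_i_star, -R_light)
      bind_rows(lapply(seq_along(tp$slopes), function(i) {
        s <- tp$slopes[i]
        tibble(Q = 50 * i, C_i = dr$C_i,
               A_net = s * (dr$C_i - tp$C_i_star) - tp$R_light)
      }))
    },
    gmc_variablej = {
      # invert the Harley relations so the true g_mc is embedded exactly
      aR <- dr$A_net + tp$R_light
      C_c <- dr$C_i - dr$A_net / tp$g_mc
      if (any(C_c <= tp$Gamma_star)) {
        abort("design implies C_c <= Gamma_star: raise C_i or g_mc")
      }
      J_F <- 4 * aR * (C_c + 2 * tp$Gamma_star) / (C_c - tp$Gamma_star)
      tibble(A_net = dr$A_net, C_i = dr$C_i, J_F = J_F)
    },
    pv = {
      # ideal PV: solute conservation osmotic line plus a linear elastic
      # turgor segment that vanishes at RWC_TLP
      rwc <- dr$RWC
      osm <- tp$pi_o * 100 / rwc
      P_ft <- -tp$pi_o
      turgor <- pmax(0, P_ft * (rwc - tp$RWC_TLP) / (100 - tp$RWC_TLP))
      tibble(RWC = rwc, psi = osm + turgor)
    },
    vuln = {
      p <- tp[setdiff(names(tp), "model")]
      tibble(psi = dr$psi, PLC = eval_vuln(tp$model, p, dr$psi))
    }
  )
}

.response_col <- c(
  aq = "A_net", aci = "A_net", t_response = "rate", gs = "g_sw",
  r_light_kok = "A_net", r_light_yin = "A_net",
  r_light_walker_ort = "A_net", gmc_variablej = "A_net", pv = "psi",
  vuln = "PLC"
)

#' Generate a synthetic curve table
#'
#' Computes the noiseless response from the corresponding `eval_*` model at
#' the design's driver levels, adds seeded Gaussian noise, and (optionally)
#' renames columns into an instrument dialect. The generating parameters
#' are embedded in the `"true_params"` attribute for recovery tests.
#'
#' @param design a [curve_design()].
#' @return A tibble; attributes `"true_params"` and `"design"`. With
#'   `n_curves > 1`, a `curve_id` column tags the replicates.
#' @examples
#' d <- generate_synthetic_curve(curve_design("aq", noise_sd = 0, seed = 42))
#' attr(d, "true_params")
#' @export
generate_synthetic_curve <- function(design) {
  stopifnot(inherits(design, "curve_design"))
  out <- with_local_seed(design$seed, {
    curves <- lapply(seq_len(design$n_curves), function(i) {
      tb <- .synth_one(design)
      rc <- .response_col[[design$kind]]
      if (design$noise_sd > 0) {
        tb[[rc]] <- tb[[rc]] + rnorm(nrow(tb), 0, design$noise_sd)
      }
      if (design$kind == "vuln") tb$PLC <- pmin(pmax(tb$PLC, 0), 100)
      if (design$n_curves > 1) tb <- mutate(tb, curve_id = paste0("curve_", i))
      tb
    })
    bind_rows(curves)
  })
  if (design$dialect != "canonical") {
    vn <- varnames(design$dialect)
    vn <- vn[names(vn) %in% names(out)]
    names(out)[match(names(vn), names(out))] <- unname(vn)
  }
  attr(out, "true_params") <- design$true_params
  attr(out, "design") <- design
  out
}
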