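# CODATA 2018 physical constants (SI)
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  NA_  = 6.02214076e23      # Avogadro number, 1/mol
)

#' Series combination of two capacitances
#'
#' Capacitance of two capacitors in series, `1/C = 1/c1 + 1/c2`. In the
#' Gouy--Chapman--Stern picture the compact (Stern) layer and the diffuse
#' layer combine this way into the total double-layer capacitance. Either
#' argument may be `Inf` to denote a layer so compact it does not limit the
#' total.
#'
#' @param c_stern,c_diffuse Capacitances, strictly positive (Inf allowed).
#' @return The series capacitance, always strictly smaller than either
#'   finite input.
#' @examples
#' series_capacitance(1, 1)          # 0.5
#' series_capacitance(2e-6, Inf)     # 2e-6
#' @export
series_capacitance <- function(c_stern, c_diffuse) {
  if (!is.numeric(c_stern) || !is.numeric(c_diffuse) ||
      any(c_stern <= 0) || any(c_diffuse <= 0) ||
      anyNA(c_stern) || anyNA(c_diffuse)) {
    stop("both capacitances must be strictly positive", call. = FALSE)
  }
  1 / (1 / c_stern + 1 / c_diffuse)
}

#' Convert molar salt concentration to ionic number density
#'
#' @param mol_per_L Molar concentration of a symmetric electrolyte (mol/L).
#' @return Number density n0 in ions per cubic metre (of each sign).
#' @examples
#' ionic_number_density(0.154)  # physiological saline, 0.9% NaCl
#' @export
ionic_number_density <- function(mol_per_L) {
  stopifnot(is.numeric(mol_per_L), all(mol_per_L > 0))
  mol_per_L * 1000 * .const$NA_
}

#' Gouy--Chapman--Stern double-layer capacitance
#'
#' Per-area capacitance of an electrical double layer, combining the Stern
#' (compact) layer and the diffuse layer in series:
#' \deqn{\frac{1}{C_{DL}} = \frac{x_{OHP}}{\varepsilon\varepsilon_0} +
#'   \frac{1}{\left(\frac{2\varepsilon\varepsilon_0 z^2 e^2 n_0}{k_B T}\right)^{1/2}
#'   \cosh\left(\frac{z e \psi}{2 k_B T}\right)}.}
#' The first term is the parallel-plate capacitance of the compact layer of
#' thickness `x_ohp`; the second is the Gouy--Chapman diffuse-layer term,
#' which stiffens (capacitance grows) with ionic strength `n0` and with the
#' magnitude of the surface potential `psi` -- a more highly charged
#' surface compacts the diffuse layer. The relative permittivity is treated
#' as constant across both layers.
#'
#' @param x_ohp Distance from the charged surface to the outer Helmholtz
#'   plane, m, >= 0 (0 collapses the Stern term).
#' @param eps_r Relative permittivity of the medium, > 0.
#' @param n0 Ionic number density, 1/m^3, > 0 (see [ionic_number_density()]).
#' @param z_val Ion valence (non-zero integer).
#' @param psi Potential at the outer Helmholtz plane relative to bulk, V.
#' @param temp_K Absolute temperature, K, > 0.
#' @return Double-layer capacitance per unit area, F/m^2. Even in `psi`
#'   (cosh symmetry) and bounded above by `eps_r * eps0 / x_ohp` when
#'   `x_ohp > 0`.
#' @examples
#' gcs_capacitance(x_ohp = 0, eps_r = 78.5,
#'                 n0 = ionic_number_density(0.154),
#'                 z_val = 1, psi = 0, temp_K = 310)
#' @export
gcs_capacitance <- function(x_ohp, eps_r, n0, z_val, psi, temp_K) {
  if (!is.numeric(x_ohp) || x_ohp < 0) stop("x_ohp must be >= 0", call. = FALSE)
  if (!is.numeric(eps_r) || eps_r <= 0) stop("eps_r must be > 0", call. = FALSE)
  if (!is.numeric(n0) || n0 <= 0) stop("n0 must be > 0", call. = FALSE)
  if (!is.numeric(z_val) || z_val == 0 || z_val != round(z_val)) {
    stop("z_val must be a non-zero integer", call. = FALSE)
  }
  if (!is.numeric(psi) || !is.finite(psi)) stop("psi must be finite", call. = FALSE)
  if (!is.numeric(temp_K) || temp_K <= 0) stop("temp_K must be > 0", call. = FALSE)
  ee0 <- eps_r * .const$eps0
  c_debye <- sqrt(2 * ee0 * z_val^2 * .const$e^2 * n0 / (.const$kB * temp_K))
  c_dif <- c_debye * cosh(z_val * .const$e * psi / (2 * .const$kB * temp_K))
  1 / (x_ohp / ee0 + 1 / c_dif)
}
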