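#' Bendo-capillary length of an adhered membrane
#'
#' The distance over which membrane bending matters near the contact line,
#' \eqn{L_b = \sqrt{k_b / \gamma}}. With the bending stiffness of an
#' actin-coated membrane (about 4e-18 J) and lysis tensions of 0.3--5.0 mN/m
#' this is tens of nanometres -- far below the micrometre scale at which
#' peripheral actin assembly is observed, which is what rules out direct
#' tension propagation as the localization mechanism.
#'
#' @param k_b bending stiffness, J; > 0.
#' @param gamma surface tension, N/m: a scalar or a `[min, max]` bracket.
#' @return length in m: a scalar, or a `[min, max]` bracket when `gamma` is
#'   a bracket (larger tension gives the smaller length).
#' @export
bendocapillary_length <- function(k_b, gamma) {
  if (!is.finite(k_b) || k_b <= 0) stop("k_b must be > 0")
  if (any(!is.finite(gamma)) || any(gamma <= 0)) stop("gamma must be > 0")
  if (length(gamma) == 1L) return(sqrt(k_b / gamma))
  if (length(gamma) != 2L) stop("gamma must be a scalar or a [min, max] bracket")
  sort(sqrt(k_b / gamma))
}

#' Thiele reaction--diffusion length
#'
#' Penetration depth of a reactant diffusing with diffusivity `D` while being
#' consumed at pseudo-first-order rate `k`: \eqn{L_{Th} = \sqrt{D / k}}. For
#' ATP diffusing into an actin network this sets the width of the peripheral
#' band over which diffusion-limited polymerization can occur.
#'
#' @param D diffusivity, m^2/s: scalar or `[min, max]` bracket.
#' @param k reaction rate, 1/s: scalar or `[min, max]` bracket.
#' @return length in m: scalar if both inputs are scalars, else a
#'   `[min, max]` bracket (`min = sqrt(min D / max k)`,
#'   `max = sqrt(max D / min k)`).
#' @export
thiele_length <- function(D, k) {
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be > 0")
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0")
  if (length(D) > 2L || length(k) > 2L)
    stop("D and k must be scalars or [min, max] brackets")
  if (length(D) == 1L && length(k) == 1L) return(sqrt(D / k))
  c(sqrt(min(D) / max(k)), sqrt(max(D) / min(k)))
}

#' Force generated by a myosin thick filament
#'
#' @param n_bound number of simultaneously bound motor dimers; >= 1.
#' @param f_single force per bound motor under isometric conditions, N.
#' @return filament force, N.
#' @export
thick_filament_force <- function(n_bound, f_single) {
  if (!is.finite(n_bound) || n_bound < 1) stop("n_bound must be >= 1")
  if (!is.finite(f_single) || f_single <= 0) stop("f_single must be > 0")
  n_bound * f_single
}

#' Membrane-tension contribution of a thick filament
#'
#' Spreads the filament force over the contact perimeter:
#' \eqn{F / (2 \pi R_L)}. For a 44 pN filament on a 10 um liposome this is
#' of order 1e-7 N/m, comparable to floppy membrane tensions.
#'
#' @param F filament force, N; >= 0.
#' @param R_L liposome contact radius, m; > 0.
#' @return a list with `tension` (N/m) and `order` (power of ten of the
#'   tension's order of magnitude, e.g. -7).
#' @export
filament_tension_contribution <- function(F, R_L) {
  if (!is.finite(F) || F < 0) stop("F must be >= 0")
  if (!is.finite(R_L) || R_L <= 0) stop("R_L must be > 0")
  tension <- F / (2 * pi * R_L)
  list(tension = tension,
       order = if (tension > 0) floor(log10(tension)) else -Inf)
}

#' Compare candidate length scales with the observed localization length
#'
#' Tests the two candidate mechanisms for peripherally localized actin
#' assembly: direct mechanosensing requires the bendo-capillary length to
#' reach the observed localization distance (`L_b >= L_obs`, boundary
#' inclusive); diffusion-limited reaction requires the observed distance to
#' fall within the Thiele bracket (or within one order of magnitude of a
#' scalar Thiele length).
#'
#' @param L_b bendo-capillary length, m (scalar; use the upper end of a
#'   bracket for the most permissive test).
#' @param L_Th Thiele length, m: scalar or `[min, max]` bracket.
#' @param L_obs observed localization length, m.
#' @return a list with logical flags `mechanosensing_supported`,
#'   `reaction_diffusion_supported`, and the ratios `L_b / L_obs` and
#'   `L_obs / L_Th` (against the bracket midpoint for brackets).
#' @export
hypothesis_report <- function(L_b, L_Th, L_obs) {
  if (any(!is.finite(c(L_b, L_Th, L_obs))) || any(c(L_b, L_Th, L_obs) <= 0))
    stop("all lengths must be positive and finite")
  mech <- L_b >= L_obs
  if (length(L_Th) == 2L) {
    L_Th <- sort(L_Th)
    rd <- L_obs >= L_Th[1] && L_obs <= L_Th[2]
    mid <- sqrt(prod(L_Th))
  } else {
    rd <- L_obs >= L_Th / 10 && L_obs <= L_Th * 10
    mid <- L_Th
  }
  list(mechanosensing_supported = mech,
       reaction_diffusion_supported = rd,
       ratio_bending = L_b / L_obs,
       ratio_thiele = L_obs / mid)
}

#' Literature default brackets for the Thiele-length calculation
#'
#' Diffusivity of ATP within a dense actin network and pseudo-first-order
#' actin--ATP reaction rates, at literature scales: `D = 1e-10` m^2/s
#' (about 100 um^2/s) and `k` in `[1, 100]` 1/s. These reproduce a Thiele
#' bracket of 1--10 um.
#'
#' @return a list with `D` (m^2/s) and `k` (`[min, max]`, 1/s).
#' @export
thiele_defaults <- function() {
  list(D = 1e-10, k = c(1, 100))
}
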