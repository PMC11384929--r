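#' Atomic masses used by the stoichiometry routines
#'
#' Integer-valued atomic masses (C 12, H 1, O 16, N 14, S 32). These reproduce
#' the textbook glucose balance (746.7 mL biogas per g VS at 22.4 L/mol); pass
#' \code{iupac_masses()} instead for four-figure IUPAC values.
#'
#' @return Named numeric vector of molar masses in g/mol for C, H, O, N, S.
#' @export
integer_masses <- function() {
  c(C = 12, H = 1, O = 16, N = 14, S = 32)
}

#' @rdname integer_masses
#' @export
iupac_masses <- function() {
  c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)
}

#' Proximate + ultimate characterization of a feedstock
#'
#' Bundles the proximate (TS, VS, ash) and ultimate (CHONS) analysis of a
#' digestion feedstock. Ultimate analysis is interpreted as mass percent of
#' total solids (TS); volatile solids (VS) are percent of TS; TS is percent of
#' fresh mass. Percentages are validated to lie in [0, 100], and the VS + ash
#' and C+H+O+N+S sums are checked against 100 with a small tolerance because
#' analytical rows rarely close exactly.
#'
#' @param carbon_pct_ts,hydrogen_pct_ts,oxygen_pct_ts,nitrogen_pct_ts,sulfur_pct_ts
#'   Elemental mass percentages of TS.
#' @param vs_pct_ts Volatile solids, percent of TS.
#' @param ts_pct Total solids, percent of fresh mass.
#' @param ash_pct_ts Ash, percent of TS.
#' @param label Free-text feedstock name.
#' @param sum_tolerance Absolute percent tolerance for the closure checks.
#' @return An object of class \code{elemental_composition}.
#' @examples
#' glucose_composition()
#' elemental_composition(carbon_pct_ts = 36.76, hydrogen_pct_ts = 5.00,
#'                       oxygen_pct_ts = 11.55, nitrogen_pct_ts = 5.28,
#'                       sulfur_pct_ts = 1.85, vs_pct_ts = 60.44,
#'                       ts_pct = 4.01, ash_pct_ts = 39.56, label = "inoculum")
#' @export
elemental_composition <- function(carbon_pct_ts,
                                  hydrogen_pct_ts,
                                  oxygen_pct_ts = 0,
                                  nitrogen_pct_ts = 0,
                                  sulfur_pct_ts = 0,
                                  vs_pct_ts = 100,
                                  ts_pct = 100,
                                  ash_pct_ts = 0,
                                  label = "",
                                  sum_tolerance = 0.5) {
  pct <- c(carbon = carbon_pct_ts, hydrogen = hydrogen_pct_ts,
           oxygen = oxygen_pct_ts, nitrogen = nitrogen_pct_ts,
           sulfur = sulfur_pct_ts, vs = vs_pct_ts, ts = ts_pct,
           ash = ash_pct_ts)
  if (any(!is.finite(pct))) stop("composition percentages must be finite")
  if (any(pct < 0 | pct > 100)) {
    bad <- names(pct)[pct < 0 | pct > 100]
    stop("percentages outside [0, 100]: ", paste(bad, collapse = ", "))
  }
  if (vs_pct_ts + ash_pct_ts > 100 + sum_tolerance) {
    stop("VS + ash exceeds 100% beyond tolerance (",
         round(vs_pct_ts + ash_pct_ts, 2), "%)")
  }
  chons <- carbon_pct_ts + hydrogen_pct_ts + oxygen_pct_ts +
    nitrogen_pct_ts + sulfur_pct_ts
  if (chons > 100 + sum_tolerance) {
    stop("C+H+O+N+S exceeds 100% beyond tolerance (", round(chons, 2), "%)")
  }
  structure(
    list(carbon_pct_ts = carbon_pct_ts, hydrogen_pct_ts = hydrogen_pct_ts,
         oxygen_pct_ts = oxygen_pct_ts, nitrogen_pct_ts = nitrogen_pct_ts,
         sulfur_pct_ts = sulfur_pct_ts, vs_pct_ts = vs_pct_ts,
         ts_pct = ts_pct, ash_pct_ts = ash_pct_ts, label = label),
    class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("Elemental composition", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  TS %.2f%% fresh, VS %.2f%% TS, ash %.2f%% TS\n",
              x$ts_pct, x$vs_pct_ts, x$ash_pct_ts))
  cat(sprintf("  C %.2f  H %.2f  O %.2f  N %.2f  S %.2f  (%% TS)\n",
              x$carbon_pct_ts, x$hydrogen_pct_ts, x$oxygen_pct_ts,
              x$nitrogen_pct_ts, x$sulfur_pct_ts))
  invisible(x)
}

#' Build a composition from an empirical formula
#'
#' Converts atom counts of an empirical C/H/O/N/S formula into the equivalent
#' mass-percent composition (all volatile, all solids), so pure compounds can
#' be run through the same stoichiometric pipeline as analysed feedstocks.
#'
#' @param c_atoms,h_atoms,o_atoms,n_atoms,s_atoms Atom counts per formula unit.
#' @param label Feedstock label.
#' @param atomic_masses Named vector of molar masses (see [integer_masses()]).
#' @return An \code{elemental_composition}.
#' @examples
#' formula_composition(6, 12, 6, label = "glucose")  # C6H12O6
#' @export
formula_composition <- function(c_atoms, h_atoms, o_atoms = 0, n_atoms = 0,
                                s_atoms = 0, label = "",
                                atomic_masses = integer_masses()) {
  m <- c(c_atoms, h_atoms, o_atoms, n_atoms, s_atoms) *
    atomic_masses[c("C", "H", "O", "N", "S")]
  mw <- sum(m)
  if (mw <= 0) stop("formula has zero molecular weight")
  p <- 100 * m / mw
  elemental_composition(p[["C"]], p[["H"]], p[["O"]], p[["N"]], p[["S"]],
                        vs_pct_ts = 100, ts_pct = 100, ash_pct_ts = 0,
                        label = label)
}

#' Table-value compositions for glucose
#'
#' Convenience constructor for the glucose molecular formula C6H12O6.
#' @return An \code{elemental_composition}.
#' @export
glucose_composition <- function() {
  formula_composition(6, 12, 6, label = "glucose (C6H12O6)")
}

#' Molar element shares per gram of feedstock
#'
#' Converts a mass-percent composition into moles of each element per gram of
#' total solids (\code{basis = "ts"}) or per gram of volatile solids
#' (\code{basis = "vs"}; divides additionally by VS/TS). These shares are the
#' c, h, o, n, s inputs of the Buswell-Mueller balance.
#'
#' @param comp An [elemental_composition()].
#' @param basis \code{"ts"} or \code{"vs"}.
#' @param atomic_masses Named molar-mass vector.
#' @return Named numeric vector (C, H, O, N, S) in mol per gram.
#' @examples
#' molar_shares(glucose_composition())  # C = 1/30 mol/g
#' @export
molar_shares <- function(comp, basis = c("vs", "ts"),
                         atomic_masses = integer_masses()) {
  stopifnot(inherits(comp, "elemental_composition"))
  basis <- match.arg(basis)
  if (comp$carbon_pct_ts <= 0) {
    stop("composition has no carbon; not a digestible feedstock")
  }
  frac <- c(C = comp$carbon_pct_ts, H = comp$hydrogen_pct_ts,
            O = comp$oxygen_pct_ts, N = comp$nitrogen_pct_ts,
            S = comp$sulfur_pct_ts) / 100
  shares <- frac / atomic_masses[names(frac)]
  if (basis == "vs") {
    if (comp$vs_pct_ts <= 0) {
      stop("per-VS basis requested but VS fraction is zero")
    }
    shares <- shares / (comp$vs_pct_ts / 100)
  }
  shares
}

#' Buswell-Mueller stoichiometric balance
#'
#' Balances the anaerobic conversion of an empirical CcHhOoNnSs substrate with
#' water into CH4, CO2, NH3 and H2S:
#' \deqn{water = c - h/4 - o/2 + 3n/4 + s/2}
#' \deqn{CH4 = c/2 + h/8 - o/4 - 3n/8 - s/4}
#' \deqn{CO2 = c/2 - h/8 + o/4 + 3n/8 + s/4}
#' With \code{include_ns = FALSE} the nitrogen and sulfur terms are dropped
#' (the CHO-only form). A negative CH4 coefficient (over-oxidized substrate)
#' is reported with \code{flagged = TRUE} rather than raised as an error, so
#' that screening of arbitrary compositions can proceed.
#'
#' @param shares Named numeric vector (C, H, O, N, S) of molar shares, any
#'   consistent scale (mol per gram or per formula unit).
#' @param include_ns Include the N and S terms.
#' @return List of reaction coefficients on the same scale as \code{shares}:
#'   \code{water}, \code{ch4}, \code{co2}, \code{nh3}, \code{h2s}, plus
#'   \code{flagged}.
#' @examples
#' buswell_balance(c(C = 6, H = 12, O = 6))  # glucose: 3 CH4 + 3 CO2
#' @export
buswell_balance <- function(shares, include_ns = TRUE) {
  s <- c(C = 0, H = 0, O = 0, N = 0, S = 0)
  s[names(shares)] <- shares
  if (s[["C"]] <= 0) stop("carbon share must be positive")
  n <- if (include_ns) s[["N"]] else 0
  su <- if (include_ns) s[["S"]] else 0
  c_ <- s[["C"]]; h <- s[["H"]]; o <- s[["O"]]
  ch4 <- c_ / 2 + h / 8 - o / 4 - 3 * n / 8 - su / 4
  co2 <- c_ / 2 - h / 8 + o / 4 + 3 * n / 8 + su / 4
  water <- c_ - h / 4 - o / 2 + 3 * n / 4 + su / 2
  flagged <- ch4 < 0
  if (flagged) {
    warning("negative CH4 coefficient: substrate is over-oxidized")
  }
  list(water = water, ch4 = ch4, co2 = co2, nh3 = n, h2s = su,
       flagged = flagged)
}

#' Theoretical ultimate methane and biogas potentials
#'
#' Applies the Buswell-Mueller balance to a feedstock composition and converts
#' the CH4 and CH4+CO2 mole yields per gram into gas volumes at a configurable
#' molar volume (default 22,400 mL/mol, ideal gas at 0 degC and 1 atm). The
#' per-VS basis (default) is what BMP practice reports: mL per g volatile
#' solids added.
#'
#' @param comp An [elemental_composition()].
#' @param molar_volume_ml Gas molar volume in mL/mol.
#' @param include_ns Include N and S terms of the balance.
#' @param basis \code{"vs"} (default) or \code{"ts"}.
#' @param atomic_masses Named molar-mass vector.
#' @return An object of class \code{buswell_result} with fields
#'   \code{water_coeff}, \code{ch4_coeff}, \code{co2_coeff}, \code{nh3_coeff},
#'   \code{h2s_coeff} (mol per gram on the chosen basis),
#'   \code{ubmp_ml_per_gvs}, \code{biogas_ml_per_gvs}, \code{methane_fraction},
#'   \code{molar_volume_ml}, \code{flagged}, \code{basis}, \code{label}.
#' @examples
#' ultimate_potentials(glucose_composition())  # biogas ~ 746.7 mL/g-VS
#' @export
ultimate_potentials <- function(comp, molar_volume_ml = 22400,
                                include_ns = TRUE, basis = c("vs", "ts"),
                                atomic_masses = integer_masses()) {
  basis <- match.arg(basis)
  if (molar_volume_ml <= 0) stop("molar volume must be positive")
  shares <- molar_shares(comp, basis = basis, atomic_masses = atomic_masses)
  bal <- buswell_balance(shares, include_ns = include_ns)
  ubmp <- bal$ch4 * molar_volume_ml
  biogas <- (bal$ch4 + bal$co2) * molar_volume_ml
  structure(
    list(water_coeff = bal$water, ch4_coeff = bal$ch4, co2_coeff = bal$co2,
         nh3_coeff = bal$nh3, h2s_coeff = bal$h2s,
         ubmp_ml_per_gvs = ubmp, biogas_ml_per_gvs = biogas,
         methane_fraction = bal$ch4 / (bal$ch4 + bal$co2),
         molar_volume_ml = molar_volume_ml, flagged = bal$flagged,
         basis = basis, label = comp$label),
    class = "buswell_result")
}

#' @export
print.buswell_result <- function(x, ...) {
  cat("Buswell-Mueller balance",
      if (nzchar(x$label)) paste0("for '", x$label, "'"), "\n")
  cat(sprintf("  uBMP   %.1f mL CH4/g-%s\n", x$ubmp_ml_per_gvs,
              toupper(x$basis)))
  cat(sprintf("  biogas %.1f mL/g-%s (CH4 fraction %.3f)\n",
              x$biogas_ml_per_gvs, toupper(x$basis), x$methane_fraction))
  if (isTRUE(x$flagged)) cat("  [flagged: negative CH4 coefficient]\n")
  invisible(x)
}

#' Ultimate biomethane yield of a loaded mass
#'
#' Scales an ultimate potential (mL CH4 per g VS) by the volatile-solids mass
#' actually loaded into the reactor.
#'
#' @param result A \code{buswell_result}, or a bare uBMP value in mL/g-VS.
#' @param mass_gvs Grams of volatile solids loaded; must be nonnegative.
#' @param source_label Optional label.
#' @return List with \code{ubmy_ml}, \code{mass_gvs}, \code{source_label},
#'   class \code{ultimate_yield}.
#' @examples
#' ultimate_yield(377.9, 2.6)  # ~982.5 mL CH4
#' @export
ultimate_yield <- function(result, mass_gvs, source_label = NULL) {
  if (mass_gvs < 0) stop("mass_gvs must be nonnegative")
  ubmp <- if (inherits(result, "buswell_result")) result$ubmp_ml_per_gvs
          else as.numeric(result)
  if (is.null(source_label)) {
    source_label <- if (inherits(result, "buswell_result")) result$label else ""
  }
  structure(list(ubmy_ml = ubmp * mass_gvs, mass_gvs = mass_gvs,
                 source_label = source_label),
            class = "ultimate_yield")
}

#' Total ultimate yield of a feed mixture
#'
#' @param yields List of [ultimate_yield()] objects, or a numeric vector of
#'   component uBMY volumes in mL.
#' @return Total uBMY in mL CH4.
#' @examples
#' mixture_ubmy(c(982.6, 3089.74))  # 4072.34
#' @export
mixture_ubmy <- function(yields) {
  if (length(yields) == 0) stop("empty list of yields")
  if (is.numeric(yields)) return(sum(yields))
  sum(vapply(yields, function(y) {
    if (inherits(y, "ultimate_yield")) y$ubmy_ml else as.numeric(y)
  }, numeric(1)))
}
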