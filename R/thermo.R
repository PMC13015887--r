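# Nearest-neighbor DNA/DNA hybridization thermodynamics.
#
# All sequences are 5'->3', alphabet {A,C,G,T}, case-insensitive.
# Energies: dH in kcal/mol, dS in cal/(mol K), dG in kcal/mol.

.R_KCAL <- 0.0019872  # gas constant, kcal/(mol K)
.R_CAL  <- 1.9872     # gas constant, cal/(mol K)

#' Nearest-neighbor parameter set
#'
#' Returns the stacked-dinucleotide enthalpy/entropy table, duplex-initiation
#' terms and monovalent-salt entropy correction used by all thermodynamic
#' calculations.  The default is the unified DNA/DNA parameter set of the
#' SantaLucia laboratory with the standard `0.368 * ln[Na+]` entropy
#' correction per phosphate.  The set is pluggable: supply a modified copy to
#' any function accepting a `params` argument.  Its identifier is propagated
#' into outputs so results are traceable to the table that produced them.
#'
#' @param name Identifier of the parameter set. Only
#'   `"santalucia1998-unified"` is built in.
#' @return An object of class `nn_params`: a list with elements `name`,
#'   `stack_dH` and `stack_dS` (named vectors over all 16 dinucleotide
#'   steps), `init_dH`/`init_dS` (terminal initiation terms, named `AT` and
#'   `GC`), and `salt_coef` (entropy correction coefficient per phosphate
#'   per `ln[Na+]`).
#' @examples
#' p <- nn_params()
#' p$stack_dH[["AA"]]
#' @export
nn_params <- function(name = "santalucia1998-unified") {
  if (!identical(name, "santalucia1998-unified")) {
    stop("unknown nearest-neighbor parameter set: ", name)
  }
  stack_dH <- c(
    AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
    CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
    CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
    CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
  )
  stack_dS <- c(
    AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
    CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
    CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
    CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
  )
  obj <- list(
    name = name,
    stack_dH = stack_dH,
    stack_dS = stack_dS,
    init_dH = c(AT = 2.3, GC = 0.1),
    init_dS = c(AT = 4.1, GC = -2.8),
    salt_coef = 0.368
  )
  stopifnot(
    length(obj$stack_dH) == 16L, length(obj$stack_dS) == 16L,
    all(is.finite(obj$stack_dH)), all(is.finite(obj$stack_dS))
  )
  class(obj) <- "nn_params"
  obj
}

#' Reaction conditions
#'
#' Bundles the physical conditions of an anneal/extension step.  The
#' defaults mirror a typical two-step qPCR protocol: 60 degrees C
#' annealing/extension for 30 s in 0.18 M monovalent salt with 0.4 uM of
#' each primer and template quantified in copies per microliter (converted
#' to molarity via `reaction_volume_ul`).
#'
#' @param temperature Annealing/extension temperature, degrees Celsius
#'   (must lie in `[0, 100]`).
#' @param monovalent_salt Monovalent cation concentration, mol/L (> 0).
#' @param extension_time Anneal/extension window, seconds (>= 0).
#' @param primer_conc Programmable-primer concentration, mol/L (> 0).
#' @param template_copies_per_ul Initial template concentration, copies/uL.
#' @param reaction_volume_ul Reaction volume used for the copies-to-molarity
#'   conversion, uL.
#' @return An object of class `reaction_conditions`.
#' @examples
#' reaction_conditions(temperature = 60, monovalent_salt = 0.18)
#' @export
reaction_conditions <- function(temperature = 60,
                                monovalent_salt = 0.18,
                                extension_time = 30,
                                primer_conc = 4e-7,
                                template_copies_per_ul = 6000,
                                reaction_volume_ul = 10) {
  if (!is.finite(temperature) || temperature < 0 || temperature > 100) {
    stop("temperature must lie in [0, 100] degrees C")
  }
  if (!is.finite(monovalent_salt) || monovalent_salt <= 0) {
    stop("monovalent_salt must be positive (mol/L)")
  }
  if (extension_time < 0) stop("extension_time must be >= 0")
  if (primer_conc <= 0) stop("primer_conc must be positive (mol/L)")
  if (template_copies_per_ul < 0) stop("template_copies_per_ul must be >= 0")
  obj <- list(
    temperature = temperature,
    monovalent_salt = monovalent_salt,
    extension_time = extension_time,
    primer_conc = primer_conc,
    template_copies_per_ul = template_copies_per_ul,
    reaction_volume_ul = reaction_volume_ul
  )
  class(obj) <- "reaction_conditions"
  obj
}

# template molarity implied by the copies/uL convention
template_molarity <- function(conditions) {
  copies <- conditions$template_copies_per_ul * conditions$reaction_volume_ul
  copies / 6.02214076e23 / (conditions$reaction_volume_ul * 1e-6)
}

.clean_seq <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty DNA string")
  }
  s <- toupper(x)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, bases[bad[1]], bad[1]))
  }
  s
}

#' Duplex thermodynamics of a perfect-match hybrid
#'
#' Computes the standard enthalpy, entropy, free energy and melting
#' temperature of the duplex formed by a DNA sequence and its exact reverse
#' complement, by summing nearest-neighbor stack terms plus terminal
#' initiation terms.  The monovalent-salt entropy correction
#' (`salt_coef * (N-1) * ln[Na+]`, one term per phosphate stack) is applied
#' before evaluating `dG = dH - T*dS/1000` at the stated temperature.  The
#' melting temperature uses the two-state formula under primer excess,
#' `Tm = 1000*dH / (dS + R*ln(C_primer))`.
#'
#' @param binding_region DNA string, 5'->3'.
#' @param conditions A [reaction_conditions()] object.
#' @param params A [nn_params()] table.
#' @return An object of class `duplex_thermo`: list with `dH` (kcal/mol),
#'   `dS` (cal/(mol K), salt-corrected), `dG` (kcal/mol at
#'   `conditions$temperature`), `Tm` (deg C), `reference_temperature`
#'   (deg C), `sequence` and `param_set`.
#' @examples
#' duplex_thermo("ATGCAATT", reaction_conditions(37, 1))
#' @export
duplex_thermo <- function(binding_region,
                          conditions = reaction_conditions(),
                          params = nn_params()) {
  s <- .clean_seq(binding_region, "binding_region")
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(bases)
  dH <- 0
  dS <- 0
  if (n >= 2L) {
    steps <- paste0(bases[-n], bases[-1])
    dH <- sum(params$stack_dH[steps])
    dS <- sum(params$stack_dS[steps])
  }
  term <- function(b) if (b %in% c("A", "T")) "AT" else "GC"
  dH <- dH + params$init_dH[[term(bases[1])]] + params$init_dH[[term(bases[n])]]
  dS <- dS + params$init_dS[[term(bases[1])]] + params$init_dS[[term(bases[n])]]
  # salt correction: one entropy term per phosphate stack
  dS <- dS + params$salt_coef * (n - 1) * log(conditions$monovalent_salt)
  tK <- conditions$temperature + 273.15
  dG <- dH - tK * dS / 1000
  tm <- 1000 * dH / (dS + .R_CAL * log(conditions$primer_conc)) - 273.15
  obj <- list(
    dH = dH, dS = dS, dG = dG, Tm = tm,
    reference_temperature = conditions$temperature,
    sequence = s, param_set = params$name
  )
  class(obj) <- "duplex_thermo"
  obj
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf(
    "duplex %s [%s]\n dH = %.2f kcal/mol  dS = %.2f cal/(mol K)\n dG(%g C) = %.3f kcal/mol  Tm = %.1f C\n",
    x$sequence, x$param_set, x$dH, x$dS, x$reference_temperature, x$dG, x$Tm
  ))
  invisible(x)
}

#' Free energy of a 5' tag region
#'
#' The tag is the 5' extension of a tag primer, non-complementary to the
#' original template; its perfect duplex free energy (against product-derived
#' long templates) uses the same engine as [duplex_thermo()].  The empty-tag
#' convention returns 0 kcal/mol: a conventional primer is a tag primer
#' whose tag free energy is zero.
#'
#' @param tag DNA string or `""` / `NULL` for a conventional primer.
#' @inheritParams duplex_thermo
#' @return Tag duplex dG in kcal/mol (scalar).
#' @export
tag_free_energy <- function(tag,
                            conditions = reaction_conditions(),
                            params = nn_params()) {
  if (is.null(tag) || (is.character(tag) && length(tag) == 1L && !nzchar(tag))) {
    return(0)
  }
  duplex_thermo(tag, conditions, params)$dG
}

#' Two-state equilibrium binding probability
#'
#' Fraction of template bound at equilibrium for the bimolecular reaction
#' primer + template <-> duplex with `K = exp(-dG/RT)`.  The exact quadratic
#' mass-action solution is used, so the primer-excess assumption is not
#' required (though it holds in every protocol shipped here).  The result is
#' monotone decreasing in `dG`: at the concentration-matched melting
#' condition (`dG = RT*ln(primer_conc)`) the bound fraction is 1/2 in the
#' primer-excess limit.
#'
#' @param dG Duplex standard free energy, kcal/mol.
#' @param temperature Temperature, degrees C.
#' @param primer_conc Total primer concentration, mol/L (> 0).
#' @param template_conc Total template concentration, mol/L (>= 0; the
#'   default 0 gives the primer-excess limit exactly).
#' @return Probability in `[0, 1]` that a template molecule is bound.
#' @examples
#' binding_probability(-12, 60, 4e-7)
#' @export
binding_probability <- function(dG, temperature, primer_conc,
                                template_conc = 0) {
  if (!is.finite(primer_conc) || primer_conc <= 0) {
    stop("primer_conc must be positive")
  }
  if (!is.finite(template_conc) || template_conc < 0) {
    stop("template_conc must be >= 0")
  }
  tK <- temperature + 273.15
  K <- exp(-dG / (.R_KCAL * tK))
  P0 <- primer_conc
  T0 <- template_conc
  if (T0 == 0) {
    # primer-excess limit of the mass-action solution
    return(K * P0 / (1 + K * P0))
  }
  # exact solve of K*(P0-x)*(T0-x) = x for the bound concentration x,
  # in the cancellation-stable smaller-root form
  b <- K * (P0 + T0) + 1
  x <- 2 * K * P0 * T0 / (b + sqrt(b * b - 4 * K * K * P0 * T0))
  min(max(x / T0, 0), 1)
}
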